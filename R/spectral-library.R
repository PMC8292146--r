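#' Spectral library of fluorophore emission profiles
#'
#' A spectral library holds, for each fluorophore, its emission weight in
#' every acquisition band of the multispectral system. The library is the
#' basis for linear unmixing: each multispectral pixel is modelled as a
#' non-negative combination of these spectra.
#'
#' Spectra are max-normalized (peak weight 1) rather than unit-sum, so that
#' unmixed abundances inherit the intensity units of the input pixels.
#'
#' @param spectra numeric matrix, bands x fluorophores, all weights >= 0;
#'   column names are the fluorophore labels.
#' @param band_centers_nm optional numeric vector of band center wavelengths
#'   (one per row), kept as metadata only.
#' @return An object of class `spectral_library`.
#' @export
spectral_library <- function(spectra, band_centers_nm = NULL) {
  spectra <- as.matrix(spectra)
  stop_if_not(!is.null(colnames(spectra)) && all(nzchar(colnames(spectra))),
              "spectra must have fluorophore column names")
  stop_if_not(all(is.finite(spectra)) && all(spectra >= 0),
              "spectral weights must be finite and non-negative")
  peaks <- apply(spectra, 2, max)
  stop_if_not(all(peaks > 0), "every fluorophore spectrum must be non-zero")
  spectra <- sweep(spectra, 2, peaks, "/")
  if (qr(spectra)$rank < ncol(spectra))
    stop("spectral library matrix is rank-deficient; fluorophore spectra are not distinguishable",
         call. = FALSE)
  if (!is.null(band_centers_nm))
    stop_if_not(length(band_centers_nm) == nrow(spectra),
                "band_centers_nm must have one entry per band")
  structure(list(spectra = spectra, band_centers_nm = band_centers_nm),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("spectral_library:", ncol(x$spectra), "fluorophores x",
      nrow(x$spectra), "bands\n")
  cat("  fluorophores:", paste(colnames(x$spectra), collapse = ", "), "\n")
  invisible(x)
}

n_fluorophores <- function(lib) ncol(lib$spectra)
n_bands <- function(lib) nrow(lib$spectra)
fluorophore_labels <- function(lib) colnames(lib$spectra)

#' Default Opal-series spectral library
#'
#' Builds a synthetic spectral library emulating a DAPI + Opal tyramide
#' fluorophore panel plus a flat autofluorescence channel, with Gaussian
#' emission profiles centered at the nominal emission maxima of each
#' fluorophore, sampled on an evenly spaced band axis. The Opal 520/540 pair
#' is deliberately close in wavelength, reproducing the spectral proximity
#' that causes cross-talk between strongly and weakly expressed markers
#' sharing a filter cube.
#'
#' @param band_centers_nm acquisition band centers in nanometers.
#' @param emission_sd_nm standard deviation of the Gaussian emission profile.
#' @param include_af include a flat autofluorescence spectrum.
#' @return A [spectral_library].
#' @export
default_spectral_library <- function(band_centers_nm = seq(440, 710, by = 22.5),
                                     emission_sd_nm = 18,
                                     include_af = TRUE) {
  peaks <- c(DAPI = 461, Opal520 = 520, Opal540 = 540, Opal570 = 570,
             Opal620 = 620, Opal650 = 650, Opal690 = 690)
  spectra <- sapply(peaks, function(p)
    exp(-(band_centers_nm - p)^2 / (2 * emission_sd_nm^2)))
  if (include_af)
    spectra <- cbind(spectra, AF = rep(1, length(band_centers_nm)))
  spectral_library(spectra, band_centers_nm = band_centers_nm)
}

#' Read / write a spectral library as JSON
#'
#' The on-disk format is a JSON object `{fluorophore: [band weights], ...}`
#' with an optional `"_band_centers_nm"` entry.
#'
#' @param lib a [spectral_library].
#' @param path file path.
#' @return `write_spectral_library` returns `path` invisibly;
#'   `read_spectral_library` returns a [spectral_library].
#' @export
write_spectral_library <- function(lib, path) {
  obj <- lapply(seq_len(n_fluorophores(lib)),
                function(j) unname(lib$spectra[, j]))
  names(obj) <- fluorophore_labels(lib)
  if (!is.null(lib$band_centers_nm))
    obj[["_band_centers_nm"]] <- lib$band_centers_nm
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- obj[["_band_centers_nm"]]
  obj[["_band_centers_nm"]] <- NULL
  spectral_library(do.call(cbind, obj), band_centers_nm = bands)
}
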