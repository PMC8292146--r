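#' Mann-Whitney U test for two independent samples
#'
#' Exact two-sided p-value (enumeration of the U distribution) when the
#' combined sample size is at most 20 and the data carry no ties; a normal
#' approximation with tie correction and continuity correction otherwise.
#' Cohort comparisons in the motivating study involve groups of 9 and 13
#' patients, where the choice between exact and approximate matters for
#' borderline p-values.
#'
#' @param group_a,group_b numeric vectors, each non-empty; `NA`s dropped
#'   with a message.
#' @return List: `U` (statistic for `group_a`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  group_a <- drop_na_logged(group_a, "group_a")
  group_b <- drop_na_logged(group_b, "group_b")
  stop_if_not(length(group_a) >= 1 && length(group_b) >= 1,
              "both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- (length(group_a) + length(group_b) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)")
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value from the t approximation.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return List: `rho`, `p`, `n`, `defined` (`FALSE` with `rho = NA` when
#'   either input is constant).
#' @export
spearman_correlation <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must be paired")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  stop_if_not(length(x) >= 3, "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x),
       defined = TRUE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the standard convention); if every
#' difference is zero the test is flagged as undefined rather than run.
#'
#' @param values_t1,values_t2 paired numeric vectors.
#' @return List: `W`, `p`, `n_nonzero`, `defined`.
#' @export
paired_wilcoxon <- function(values_t1, values_t2) {
  stop_if_not(length(values_t1) == length(values_t2),
              "paired vectors must have equal length")
  d <- values_t2 - values_t1
  d <- d[is.finite(d)]
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(W = NA_real_, p = NA_real_, n_nonzero = 0, defined = FALSE))
  ht <- suppressWarnings(wilcox.test(d[d != 0], mu = 0))
  list(W = unname(ht$statistic), p = ht$p.value, n_nonzero = nz,
       defined = TRUE)
}

#' Independent-samples t test
#'
#' Welch's t test (unequal variances), two-sided.
#'
#' @param group_a,group_b numeric vectors with >= 2 finite values each.
#' @return List: `t`, `p`, `df`.
#' @export
independent_t <- function(group_a, group_b) {
  group_a <- drop_na_logged(group_a, "group_a")
  group_b <- drop_na_logged(group_b, "group_b")
  stop_if_not(length(group_a) >= 2 && length(group_b) >= 2,
              "each group needs at least 2 values")
  ht <- t.test(group_a, group_b)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided by summing the probabilities of all tables at most as likely
#' as the observed one (the standard convention of [stats::fisher.test()]).
#'
#' @param tab 2 x 2 integer matrix.
#' @return List: `odds_ratio` (conditional MLE), `p`.
#' @export
fishers_exact <- function(tab) {
  tab <- as.matrix(tab)
  stop_if_not(all(dim(tab) == c(2, 2)), "need a 2 x 2 table")
  ht <- fisher.test(tab)
  list(odds_ratio = unname(ht$estimate), p = ht$p.value)
}

drop_na_logged <- function(x, label) {
  bad <- !is.finite(x)
  if (any(bad))
    message(sum(bad), " missing value(s) dropped from ", label)
  x[!bad]
}

#' Per-group summaries of a cohort quantification table
#'
#' Densities and percentages are summarized as median (min-max); ratio
#' variables as mean (SD) — the conventional presentation for skewed cell
#' densities versus roughly symmetric per-patient ratios. Missing values
#' are dropped per variable with a message, never silently.
#'
#' @param table data frame with one row per patient.
#' @param group_col name of the binary group column.
#' @param density_cols,ratio_cols character vectors of column names.
#' @return Long data frame: group, variable, kind, n, and the summary
#'   columns (`median`, `min`, `max` or `mean`, `sd`).
#' @export
group_summaries <- function(table, group_col = "group",
                            density_cols = character(),
                            ratio_cols = character()) {
  stop_if_not(group_col %in% names(table), "group column not found")
  groups <- unique(as.character(table[[group_col]]))
  stop_if_not(length(groups) >= 1 && length(groups) <= 2,
              "group labels must be binary")
  rows <- list()
  for (g in groups) {
    sub <- table[table[[group_col]] == g, , drop = FALSE]
    for (v in density_cols) {
      x <- drop_na_logged(sub[[v]], paste0(v, " [", g, "]"))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, kind = "density", n = length(x),
        median = median(x), min = min(x), max = max(x),
        mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
    }
    for (v in ratio_cols) {
      x <- drop_na_logged(sub[[v]], paste0(v, " [", g, "]"))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, variable = v, kind = "ratio", n = length(x),
        median = NA_real_, min = NA_real_, max = NA_real_,
        mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison over a cohort table
#'
#' Runs the Mann-Whitney U test per density/percentage column and the
#' independent t test per ratio column between the two groups, optionally
#' adding Benjamini-Hochberg adjusted p-values (the primary output is
#' unadjusted, matching conventional single-comparison reporting).
#'
#' @inheritParams group_summaries
#' @param adjust add a `p_adj` column (Benjamini-Hochberg).
#' @return Data frame: variable, test, statistic, p (and `p_adj`).
#' @export
compare_groups <- function(table, group_col = "group",
                           density_cols = character(),
                           ratio_cols = character(), adjust = FALSE) {
  groups <- unique(as.character(table[[group_col]]))
  stop_if_not(length(groups) == 2, "need exactly two groups")
  a <- table[table[[group_col]] == groups[1], , drop = FALSE]
  b <- table[table[[group_col]] == groups[2], , drop = FALSE]
  rows <- list()
  for (v in density_cols) {
    r <- mann_whitney_u(a[[v]], b[[v]])
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "mann-whitney", statistic = r$U, p = r$p,
      stringsAsFactors = FALSE)
  }
  for (v in ratio_cols) {
    r <- independent_t(a[[v]], b[[v]])
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, test = "t", statistic = r$t, p = r$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
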