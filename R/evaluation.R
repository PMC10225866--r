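#' Heteroscedasticity-robust regression slope of estimate on truth
#'
#' OLS regression (with intercept) of estimated on true richness; the
#' slope measures richness-dependent bias (slope < 1: diverse
#' communities underestimated more) and its robust standard error
#' measures precision. Communities are independent draws, so the
#' autocorrelation lag is zero and a pure heteroscedasticity-
#' consistent (HC1) covariance is used.
#'
#' @param true,est numeric vectors of true and estimated richness.
#' @return one-row tibble: `slope`, `slope_sd` (robust), `slope_sd_ols`
#'   (classical, for comparison).
#' @export
slope_hac <- function(true, est) {
  if (length(true) < 3) abort("need at least 3 points")
  if (var(true) == 0) abort("true richness is constant")
  fit <- lm(est ~ true)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  tibble::tibble(slope = unname(coef(fit)[2]),
                 slope_sd = sqrt(vc[2, 2]),
                 slope_sd_ols = summary(fit)$coefficients[2, 2])
}

#' Accuracy against the 1:1 line (R-squared star)
#'
#' `1 - sum((est - true)^2) / sum((true - mean(true))^2)`: the share
#' of truth variance explained by taking the estimates at face value.
#' Unlike a fitted regression R-squared it penalizes bias; large
#' errors drive it negative (worse than reporting the average).
#'
#' @inheritParams slope_hac
#' @return a single numeric value, at most 1.
#' @export
r2_star <- function(true, est) {
  1 - sum((est - true)^2) / sum((true - mean(true))^2)
}

#' Draw community pairs for difference detection
#'
#' Random pairs whose true richness differs by at most `max_diff` but
#' is not identical. Uses the current RNG state.
#'
#' @param true vector of true richness values.
#' @param max_diff maximum absolute richness difference.
#' @param n_pairs number of pairs.
#' @return two-column integer matrix of community indices.
#' @export
draw_detection_pairs <- function(true, max_diff, n_pairs = 2000) {
  n <- length(true)
  got_i <- integer(0); got_j <- integer(0)
  tries <- 0L
  while (length(got_i) < n_pairs) {
    tries <- tries + 1L
    if (tries > 200L) abort("no qualifying pairs within the difference band")
    m <- max(4L * n_pairs, 1000L)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    d <- true[i] - true[j]
    ok <- d != 0 & abs(d) <= max_diff
    got_i <- c(got_i, i[ok]); got_j <- c(got_j, j[ok])
  }
  cbind(i = got_i[seq_len(n_pairs)], j = got_j[seq_len(n_pairs)])
}

#' Pairwise richness-difference detection accuracy
#'
#' Fraction of community pairs (true richness differing by at most
#' `max_diff`, never identical) for which the estimator orders the
#' two communities in the true direction. Estimate ties count as
#' failures by default (an estimator that cannot separate the pair
#' has not detected the difference); `ties = "half"` scores them 0.5.
#' Above 0.5 beats a coin flip.
#'
#' @inheritParams slope_hac
#' @param max_diff maximum absolute true-richness difference (2, 10
#'   and 20 are the benchmark thresholds).
#' @param n_pairs pairs to draw (default 2000).
#' @param pairs optional precomputed pair matrix from
#'   [draw_detection_pairs()] (lets several estimators share pairs).
#' @param ties `"fail"` (default) or `"half"`.
#' @return a single numeric accuracy in `[0, 1]`.
#' @export
detection_accuracy <- function(true, est, max_diff, n_pairs = 2000,
                               pairs = NULL, ties = c("fail", "half")) {
  ties <- match.arg(ties)
  if (is.null(pairs)) pairs <- draw_detection_pairs(true, max_diff, n_pairs)
  dt <- true[pairs[, 1]] - true[pairs[, 2]]
  de <- est[pairs[, 1]] - est[pairs[, 2]]
  correct <- sign(de) == sign(dt)
  if (ties == "half") {
    mean(correct + 0.5 * (de == 0))
  } else {
    mean(correct)
  }
}

#' Six-measure performance report for an ensemble
#'
#' For every estimator column of a [run_scenario()] ensemble computes
#' the six benchmark measures: regression slope of estimate on truth
#' and its robust s.d. ([slope_hac()]), accuracy against the 1:1 line
#' ([r2_star()]), and difference-detection accuracy at thresholds 2,
#' 10 and 20 ([detection_accuracy()]). The same random pairs are used
#' for every estimator at a given threshold, so detection columns are
#' directly comparable.
#'
#' @param ensemble tibble with a `true_richness` column and one column
#'   per estimator.
#' @param estimators estimator column names; defaults to every column
#'   after the ensemble metadata.
#' @param n_pairs detection pairs per threshold (default 2000).
#' @param seed RNG seed for pair drawing.
#' @return tibble with one row per estimator: `method`, `slope`,
#'   `slope_sd`, `r2_star`, `det2`, `det10`, `det20`.
#' @export
performance_report <- function(ensemble, estimators = NULL,
                               n_pairs = 2000, seed = 1) {
  meta <- c("community", "true_richness", "k", "m_tilde", "P_tilde",
            "n_tilde", "S_obs", "observed_matrix", "observed_data",
            "true_stats")
  if (is.null(estimators)) {
    estimators <- setdiff(names(ensemble)[!vapply(ensemble, is.list,
                                                  logical(1))], meta)
  }
  true <- ensemble$true_richness
  set.seed(seed)
  pairs <- lapply(c(2, 10, 20), function(d) {
    draw_detection_pairs(true, d, n_pairs)
  })
  rows <- purrr::map(estimators, function(m) {
    est <- ensemble[[m]]
    sl <- slope_hac(true, est)
    tibble::tibble(
      method = m, slope = sl$slope, slope_sd = sl$slope_sd,
      r2_star = r2_star(true, est),
      det2 = detection_accuracy(true, est, 2, pairs = pairs[[1]]),
      det10 = detection_accuracy(true, est, 10, pairs = pairs[[2]]),
      det20 = detection_accuracy(true, est, 20, pairs = pairs[[3]]))
  })
  dplyr::bind_rows(rows)
}

#' Standardized performance scores across estimators
#'
#' Converts the six measures into "bigger is better" performances —
#' `1 - |slope - 1|`, `-slope_sd`, `r2_star`, and the three detection
#' accuracies — then z-scores each column across the supplied
#' estimator set (score +1 means one s.d. better than the average
#' estimator). A column with zero spread scores 0 for everyone. The
#' overall score is the mean of the six.
#'
#' @param report tibble from [performance_report()].
#' @return tibble: `method`, the six scores (`score_slope`,
#'   `score_slope_sd`, `score_r2_star`, `score_det2`, `score_det10`,
#'   `score_det20`) and `overall`.
#' @export
standardized_scores <- function(report) {
  perf <- cbind(
    score_slope = 1 - abs(report$slope - 1),
    score_slope_sd = -report$slope_sd,
    score_r2_star = report$r2_star,
    score_det2 = report$det2,
    score_det10 = report$det10,
    score_det20 = report$det20)
  z <- apply(perf, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, colnames(perf)))
  out <- tibble::as_tibble(z)
  out$method <- report$method
  out$overall <- rowMeans(z)
  dplyr::relocate(out, "method")
}

#' Rolling mean and s.d. of estimates by true richness
#'
#' For each true-richness value present, the mean and s.d. of
#' estimates from communities whose truth lies within a centred
#' window (width 10 by default, truncated at the range edges). These
#' across-community bounds are the reference the within-community
#' bootstrap s.d. is compared against.
#'
#' @inheritParams slope_hac
#' @param window window width (centred; communities with
#'   `|truth - centre| <= window/2` are included).
#' @return tibble: `true_richness`, `mean`, `sd`, `n`.
#' @export
rolling_bounds <- function(true, est, window = 10) {
  centres <- sort(unique(true))
  rows <- purrr::map(centres, function(t0) {
    sel <- abs(true - t0) <= window / 2
    tibble::tibble(true_richness = t0, mean = mean(est[sel]),
                   sd = if (sum(sel) > 1) sd(est[sel]) else 0,
                   n = sum(sel))
  })
  dplyr::bind_rows(rows)
}
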