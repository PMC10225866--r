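#' Binomial thinning of counts (local downsampling)
#'
#' Retains each recorded individual independently with probability
#' `m_down`, emulating a survey in which only that fraction of
#' individuals is observed at every selected patch.
#'
#' @param x abundance matrix.
#' @param m_down retention probability in (0, 1].
#' @return thinned abundance matrix of the same shape.
#' @export
thin_counts <- function(x, m_down) {
  x <- as_abundance(x)
  if (m_down <= 0 || m_down > 1) abort("m_down must be in (0, 1]")
  if (m_down == 1) return(x)
  out <- matrix(rbinom(length(x), as.vector(x), m_down),
                nrow(x), ncol(x), dimnames = dimnames(x))
  as_abundance(out)
}

#' Spatial subsampling / local downsampling experiment
#'
#' Emulates reduced survey effort on a multi-year dataset: per
#' replicate a subset of patches is drawn without replacement (the
#' same subset reused every year for census-style designs, redrawn
#' per year for survey-style ones), counts are optionally thinned to
#' a fraction `m_down` of individuals, and every estimator is applied
#' to each year.
#'
#' @param yearly named list of abundance matrices, one per time label
#'   (years must share a patch universe when
#'   `fixed_patches_across_years`).
#' @param n_patches patches to retain.
#' @param m_down fraction of individuals observed (default 1 = no
#'   downsampling).
#' @param replicates number of replicates (default 40).
#' @param fixed_patches_across_years reuse one patch subset across
#'   all years within a replicate (default TRUE, census-style).
#' @param estimators estimator names (see [estimate_richness()]).
#' @param seed RNG seed; reproduces the whole experiment table.
#' @return tibble: `replicate`, `time`, `method`, `estimate`, `S`.
#' @export
subsample_experiment <- function(yearly, n_patches, m_down = 1,
                                 replicates = 40,
                                 fixed_patches_across_years = TRUE,
                                 estimators = c("observed", "chao1",
                                                "chao2", "omega"),
                                 seed = 1) {
  yearly <- lapply(yearly, as_abundance)
  times <- names(yearly) %||% as.character(seq_along(yearly))
  k_avail <- vapply(yearly, ncol, integer(1))
  if (any(n_patches > k_avail)) {
    abort(sprintf("n_patches (%d) exceeds available patches (%d)",
                  n_patches, min(k_avail)))
  }
  set.seed(seed)
  rows <- vector("list", replicates * length(yearly))
  idx <- 0L
  for (r in seq_len(replicates)) {
    shared <- if (fixed_patches_across_years) {
      sample.int(k_avail[1], n_patches, replace = FALSE)
    }
    for (y in seq_along(yearly)) {
      patches <- if (fixed_patches_across_years) shared
        else sample.int(k_avail[y], n_patches, replace = FALSE)
      sub <- yearly[[y]][, patches, drop = FALSE]
      if (m_down < 1) sub <- thin_counts(sub, m_down)
      vals <- suppressWarnings(.point_estimates(sub, estimators))
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        replicate = r, time = times[y], method = estimators,
        estimate = unname(vals), S = sum(rowSums(sub) > 0))
    }
  }
  dplyr::bind_rows(rows)
}

#' Temporal trend of richness estimates
#'
#' OLS regression of point estimates on time; the slope is the
#' detected trend (species per unit time) and the p-value tests the
#' null of no trend.
#'
#' @param time numeric time axis (year or census index), at least 3
#'   points.
#' @param estimate richness estimates at those times.
#' @return one-row tibble: `slope`, `se`, `p_value`, `intercept`.
#' @examples
#' trend_regression(1:4, c(10, 8, 6, 4))
#' @export
trend_regression <- function(time, estimate) {
  if (length(time) < 3) abort("need at least 3 time points")
  if (var(estimate) == 0) {
    return(tibble::tibble(slope = 0, se = 0, p_value = 1,
                          intercept = estimate[1]))
  }
  fit <- lm(estimate ~ time)
  cf <- summary(fit)$coefficients
  tibble::tibble(slope = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4],
                 intercept = cf[1, 1])
}

#' Subsampled estimates as a percentage of the full-data estimate
#'
#' `100 * mean(subsample estimate) / full estimate` per estimator
#' (and per time label when both tables carry one): a
#' multi-dimensional rarefaction summary, 100% meaning the estimator
#' has reached its asymptote at that effort.
#'
#' @param sub tibble of subsampled estimates with columns `method`,
#'   `estimate` and optionally `time` (e.g. from
#'   [subsample_experiment()]).
#' @param full tibble of full-data estimates with columns `method`,
#'   `estimate` and optionally `time`.
#' @return tibble: `method` (and `time`), `percent_of_full`.
#' @export
percent_of_full <- function(sub, full) {
  by_time <- "time" %in% names(sub) && "time" %in% names(full)
  keys <- if (by_time) c("method", "time") else "method"
  sub_mean <- dplyr::summarise(
    dplyr::group_by(sub, dplyr::across(dplyr::all_of(keys))),
    sub_estimate = mean(.data$estimate), .groups = "drop")
  full <- dplyr::rename(full[, c(keys, "estimate")],
                        full_estimate = "estimate")
  joined <- dplyr::inner_join(sub_mean, full, by = keys)
  joined$percent_of_full <- 100 * joined$sub_estimate / joined$full_estimate
  joined[, c(keys, "percent_of_full")]
}
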