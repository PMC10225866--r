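# fast all-estimator evaluation on a raw count matrix -----------------
# (no validation/tibble overhead; used by run_scenario and bootstrap)
.point_estimates <- function(mat, methods, fallback_threshold = 0.1) {
  pooled <- rowSums(mat)
  keep <- pooled > 0
  S <- sum(keep)
  k <- ncol(mat)
  out <- setNames(numeric(length(methods)), methods)
  if (S == 0) return(out)  # estimate 0 for every method on empty surveys
  pooled <- pooled[keep]
  occ <- rowSums(mat[keep, , drop = FALSE] > 0)
  mn <- pooled / k
  P <- occ / k
  f1 <- sum(pooled == 1); f2 <- sum(pooled == 2)
  q1 <- sum(occ == 1); q2 <- sum(occ == 2)
  for (m in methods) {
    out[[m]] <- switch(
      m,
      observed = S,
      chao1 = S + f1 * (f1 - 1) / (2 * (f2 + 1)),
      chao1_classic = if (f2 == 0) S + f1 * (f1 - 1) / 2 else
        S + f1^2 / (2 * f2),
      chao2 = if (k < 2) S else
        S + (k - 1) / k * q1 * (q1 - 1) / (2 * (q2 + 1)),
      chao2_classic = if (k < 2) S else if (q2 == 0)
        S + (k - 1) / k * q1 * (q1 - 1) / 2 else
        S + (k - 1) / k * q1^2 / (2 * q2),
      ace = ace(mat)$estimate,
      jackknife1_abund = S + f1,
      jackknife2_incid = if (k < 2) S else
        S + q1 * (2 * k - 3) / k - q2 * (k - 2)^2 / (k * (k - 1)),
      omega = .omega_exact(mn, P, k),
      omega_T = {
        v_mn <- if (S > 1) var(mn) else 0
        v_P <- if (S > 1) var(P) else 0
        c_mnP <- if (S > 1) cov(mn, P) else 0
        as.numeric(.omega_taylor(S, mean(mn), mean(P), v_mn, v_P, c_mnP,
                                 k, fallback_threshold))
      },
      omega_0 = .omega_zero(S, mean(mn), mean(P), k),
      abort(paste0("unknown estimator: ", m))
    )
  }
  out
}

.default_methods <- c("observed", "chao1", "chao2", "ace",
                      "jackknife1_abund", "jackknife2_incid",
                      "omega", "omega_T", "omega_0")

# classic ratio-form Chao variants are available on request (their
# precision differs sharply from the bias-corrected defaults on sparse
# surveys); not part of the default panel
.extra_methods <- c("chao1_classic", "chao2_classic")

#' Estimate species richness by a panel of asymptotic estimators
#'
#' One call takes a spatial abundance matrix and returns point
#' estimates for observed richness, Chao1, Chao2, ACE,
#' Jackknife1-abundance, Jackknife2-incidence and the omega family
#' (exact, Taylor, mean-field), optionally with block-bootstrap
#' precision summaries. Incidence-based estimators convert counts to
#' presence/absence internally. The Gamma-Poisson correction of Chao1
#' is not implemented (its closed form is defined in literature not
#' restated here and is outside this package's scope).
#'
#' @param x abundance matrix (species x patch counts); see
#'   [as_abundance()].
#' @param methods character vector of estimator names, a subset of
#'   `c("observed", "chao1", "chao2", "ace", "jackknife1_abund",
#'   "jackknife2_incid", "omega", "omega_T", "omega_0")`; the classic
#'   ratio-form Chao variants are additionally available as
#'   `"chao1_classic"` and `"chao2_classic"`.
#' @param bootstrap if `TRUE`, run [block_bootstrap()] per method and
#'   append `sd`, `cv` (variance/mean) and `cv_sd_mean` (sd/mean)
#'   columns.
#' @param B bootstrap replicates (default 2000, the full-data
#'   convention; use 50 inside subsample replicates).
#' @param seed RNG seed for the bootstrap.
#' @return a tibble with one row per method: `method`, `estimate`,
#'   `S`, and bootstrap columns when requested.
#' @examples
#' fig <- rbind(black = c(2, 1, 0), shark = c(0, 0, 1), grey = c(1, 0, 0))
#' estimate_richness(fig)
#' @export
estimate_richness <- function(x, methods = .default_methods,
                              bootstrap = FALSE, B = 2000, seed = 1) {
  x <- as_abundance(x)
  methods <- match.arg(methods, c(.default_methods, .extra_methods),
                       several.ok = TRUE)
  vals <- .point_estimates(x, methods)
  out <- tibble::tibble(method = methods, estimate = unname(vals),
                        S = observed_richness(x)$S)
  if (bootstrap) {
    boots <- purrr::map(methods, function(m) {
      glance(block_bootstrap(x, m, B = B, seed = seed))
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(boots)[
      , c("sd", "cv", "cv_sd_mean")])
  }
  out
}
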