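# internal fast paths ------------------------------------------------

# exact estimator from per-species stats vectors
.omega_exact <- function(mn, P, k) {
  S <- length(mn)
  S / mean(.dcomm(mn, P, k))
}

# mean-field estimator from moments
.omega_zero <- function(S, mean_mn, mean_P, k) {
  S / .dcomm(mean_mn, mean_P, k)
}

# Taylor estimator; returns value with attributes denom & fallback
.omega_taylor <- function(S, mean_mn, mean_P, var_mn, var_P, cov_mnP, k,
                          fallback_threshold = 0.1) {
  cs <- taylor_coefficients(mean_mn, mean_P, k)
  denom <- .dcomm(mean_mn, mean_P, k) +
    cs[["c1"]] * var_mn + cs[["c2"]] * var_P + cs[["c3"]] * cov_mnP
  fallback <- denom < fallback_threshold
  value <- if (fallback) .omega_zero(S, mean_mn, mean_P, k) else S / denom
  structure(value, denominator = denom, fallback = fallback)
}

# resolve a matrix or a species_stats tibble to stats
.resolve_stats <- function(x) {
  if (is.data.frame(x) && all(c("mn", "P", "k") %in% names(x))) x
  else species_stats(x)
}

.estimate_row <- function(method, value, S, ...) {
  tibble::tibble(method = method, estimate = as.numeric(value), S = S, ...)
}

# user-facing estimators ----------------------------------------------

#' Exact bias-corrected richness estimator (omega)
#'
#' Divides observed richness `S` by the mean community-level
#' observation probability across observed species, each species
#' evaluated at its own observable abundance and occupancy
#' ([d_community()]). Because every detection probability is below 1,
#' the estimate is always at least `S`.
#'
#' @param x abundance matrix, or a [species_stats()] tibble.
#' @return one-row tibble: `method`, `estimate`, `S`,
#'   `mean_detection`.
#' @examples
#' fig <- rbind(black = c(2, 1, 0), shark = c(0, 0, 1), grey = c(1, 0, 0))
#' omega(fig)
#' @export
omega <- function(x) {
  st <- .resolve_stats(x)
  d <- mean(.dcomm(st$mn, st$P, st$k[1]))
  .estimate_row("omega", nrow(st) / d, nrow(st), mean_detection = d)
}

#' Mean-field richness estimator (omega_0)
#'
#' Evaluates the community detection probability once, at the
#' cross-species mean observable abundance and occupancy, as if all
#' species shared the same spatial characteristics. Numerically the
#' most stable member of the omega family and the fallback target of
#' [omega_taylor()].
#'
#' @inheritParams omega
#' @return one-row tibble: `method`, `estimate`, `S`, `denominator`.
#' @export
omega_zero <- function(x) {
  m <- moment_summary(.resolve_stats(x))
  d <- .dcomm(m$mean_mn, m$mean_P, m$k)
  .estimate_row("omega_0", m$S / d, m$S, denominator = d)
}

#' Second-order Taylor richness estimator (omega_T)
#'
#' Approximates the mean observation probability by a second-order
#' Taylor expansion around the cross-species means: the mean-field
#' detection plus variance and covariance corrections weighted by
#' [taylor_coefficients()]. Cross-species variance in `mn` is hard to
#' estimate from few observed species and can push the expansion very
#' low or negative, so when the expanded denominator falls below
#' `fallback_threshold` (10% estimated observation probability) the
#' estimator switches to [omega_zero()] and flags the fallback.
#'
#' @inheritParams omega
#' @param fallback_threshold denominator value below which the
#'   mean-field estimate is returned instead (default 0.1).
#' @return one-row tibble: `method`, `estimate`, `S`, `denominator`
#'   (the expanded denominator, even when the fallback fired),
#'   `fallback` (logical), and `above_one` flagging denominators
#'   above 1 (possible via a positive covariance term; the estimate is
#'   then slightly below `S` and reported as-is).
#' @export
omega_taylor <- function(x, fallback_threshold = 0.1) {
  m <- moment_summary(.resolve_stats(x))
  v <- .omega_taylor(m$S, m$mean_mn, m$mean_P, m$var_mn, m$var_P,
                     m$cov_mnP, m$k, fallback_threshold)
  .estimate_row("omega_T", v, m$S,
                denominator = attr(v, "denominator"),
                fallback = attr(v, "fallback"),
                above_one = attr(v, "denominator") > 1)
}

#' Idealized (survivorship-bias-free) omega estimators
#'
#' In simulations the spatial statistics of *all* truly present
#' species are known, so the survivorship bias of moments computed
#' over observed species only can be eliminated: the same formulas are
#' evaluated with true per-species statistics while `S` stays the
#' observed richness. These corrected estimators quantify the ceiling
#' performance of the omega family; they cannot be used on real data.
#'
#' @param true_stats tibble with columns `mn`, `P`, `k` over all truly
#'   present species (e.g. `sim$true_stats` from
#'   [simulate_community()]).
#' @param S_observed observed richness of the survey (may be 0, in
#'   which case the estimate is 0).
#' @param variant `"exact"`, `"taylor"` or `"zero"`.
#' @param fallback_threshold see [omega_taylor()]; applies to the
#'   taylor variant identically.
#' @return one-row tibble as for the uncorrected counterparts, with
#'   method names `omega_C`, `omega_TC`, `omega_0C`.
#' @export
omega_corrected <- function(true_stats, S_observed,
                            variant = c("exact", "taylor", "zero"),
                            fallback_threshold = 0.1) {
  variant <- match.arg(variant)
  if (is.null(true_stats) || !all(c("mn", "P", "k") %in% names(true_stats))) {
    abort("true per-species statistics (mn, P, k) are required")
  }
  if (S_observed == 0) {
    return(.estimate_row(switch(variant, exact = "omega_C",
                                taylor = "omega_TC", zero = "omega_0C"),
                         0, 0L))
  }
  k <- true_stats$k[1]
  if (variant == "exact") {
    d <- mean(.dcomm(true_stats$mn, true_stats$P, k))
    return(.estimate_row("omega_C", S_observed / d, S_observed,
                         mean_detection = d))
  }
  m <- moment_summary(true_stats)
  if (variant == "zero") {
    d <- .dcomm(m$mean_mn, m$mean_P, k)
    return(.estimate_row("omega_0C", S_observed / d, S_observed,
                         denominator = d))
  }
  v <- .omega_taylor(S_observed, m$mean_mn, m$mean_P, m$var_mn, m$var_P,
                     m$cov_mnP, k, fallback_threshold)
  .estimate_row("omega_TC", v, S_observed,
                denominator = attr(v, "denominator"),
                fallback = attr(v, "fallback"))
}
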