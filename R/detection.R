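#' Observation probability within an occupied patch
#'
#' The local observation process is Poisson sampling with mean equal
#' to the observable abundance per occupied patch, `mn / P`: the
#' probability of recording a species at least once in a patch it
#' occupies is one minus the Poisson failure rate.
#'
#' @param mn observable mean abundance per patch (catchability times
#'   density, community scale), `>= 0`.
#' @param P occupancy, the fraction of patches occupied, in `(0, 1]`.
#' @return `1 - exp(-mn / P)`, in `[0, 1)`. Vectorized.
#' @examples
#' d_occupied(1, 2 / 3)
#' @export
d_occupied <- function(mn, P) {
  if (any(P <= 0)) abort("P must be > 0")
  if (any(mn < 0)) abort("mn must be >= 0")
  1 - exp(-mn / P)
}

#' Observation probability per random patch
#'
#' A random patch is occupied with probability `P`; detection there
#' follows [d_occupied()]. Unoccupied patches yield nothing.
#'
#' @inheritParams d_occupied
#' @return `P * (1 - exp(-mn / P))`, in `[0, 1)`. Vectorized.
#' @export
d_patch <- function(mn, P) {
  if (any(P <= 0 | P > 1)) abort("P must be in (0, 1]")
  P * d_occupied(mn, P)
}

#' Observation probability across a k-patch survey
#'
#' With `k` independently sampled patches, a species is recorded at
#' least once unless it is missed in every patch.
#'
#' @inheritParams d_occupied
#' @param k number of patches sampled, `>= 1`. Non-integer `k` is
#'   accepted (effective-sample-size use); the rest of the package
#'   always passes integers.
#' @return `1 - (1 - d_patch(mn, P))^k`, in `[0, 1)`. Vectorized.
#' @examples
#' d_community(1, 2 / 3, 3)
#' @export
d_community <- function(mn, P, k) {
  if (any(k < 1)) abort("k must be >= 1")
  1 - (1 - d_patch(mn, P))^k
}

# fast path: no argument checking, used in simulation loops
.dcomm <- function(mn, P, k) 1 - (1 - P * (1 - exp(-mn / P)))^k

#' Second-order Taylor coefficients of the community detection probability
#'
#' Closed-form second partial derivatives of [d_community()] with
#' respect to observable abundance `mn` and occupancy `P`, evaluated
#' at a point (typically the cross-species means). They weight the
#' variance and covariance corrections in the Taylor richness
#' estimator: `c1 = 0.5 * d2D/dmn2`, `c2 = 0.5 * d2D/dP2`,
#' `c3 = d2D/dmn dP`. `c1` and `c2` are negative throughout the
#' domain, so cross-species variance always lowers the mean
#' observation probability; `c3` can take either sign.
#'
#' @inheritParams d_community
#' @return named numeric vector `c(c1, c2, c3)`.
#' @examples
#' taylor_coefficients(5 / 9, 4 / 9, 3)
#' @export
taylor_coefficients <- function(mn, P, k) {
  if (P <= 0 || P > 1) abort("P must be in (0, 1]")
  if (mn < 0) abort("mn must be >= 0")
  if (k < 1) abort("k must be >= 1")
  e <- exp(-mn / P)
  g <- P * (1 - e)          # per-patch detection
  f <- 1 - g                # per-patch failure
  g_u <- e                  # dg/dmn
  g_p <- 1 - e - (mn / P) * e
  g_uu <- -e / P
  g_pp <- -(mn^2 / P^3) * e
  g_up <- (mn / P^2) * e
  # D = 1 - f^k; D_xy = k * (-(k-1) f^(k-2) g_x g_y + f^(k-1) g_xy)
  d_uu <- k * (-(k - 1) * f^(k - 2) * g_u^2 + f^(k - 1) * g_uu)
  d_pp <- k * (-(k - 1) * f^(k - 2) * g_p^2 + f^(k - 1) * g_pp)
  d_up <- k * (-(k - 1) * f^(k - 2) * g_u * g_p + f^(k - 1) * g_up)
  c(c1 = d_uu / 2, c2 = d_pp / 2, c3 = d_up)
}
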