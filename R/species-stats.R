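#' Per-species spatial abundance statistics
#'
#' For every observed species (positive row total) computes the two
#' state variables of the observation model: observable mean abundance
#' `mn` (row total / k, individuals per sampled patch) and occupancy
#' `P` (occupied patches / k). The number of patches sampled `k` is a
#' single community-level integer shared by all species.
#'
#' @param x abundance matrix (species x patch).
#' @return a tibble with columns `species`, `mn`, `P`, `k`; one row
#'   per observed species. `mn >= 1/k` and `P >= 1/k` by construction.
#' @examples
#' fig <- rbind(black = c(2, 1, 0), shark = c(0, 0, 1), grey = c(1, 0, 0))
#' species_stats(fig)
#' @export
species_stats <- function(x) {
  x <- as_abundance(x)
  k <- ncol(x)
  tot <- rowSums(x)
  occ <- rowSums(x > 0)
  keep <- tot > 0
  if (!any(keep)) abort("no observed species")
  tibble::tibble(
    species = rownames(x)[keep],
    mn = unname(tot[keep]) / k,
    P = unname(occ[keep]) / k,
    k = k
  )
}

#' Cross-species moments of the spatial statistics
#'
#' Sample means, variances and the covariance of `mn` and `P` across
#' the species in a [species_stats()] table (or any tibble with `mn`,
#' `P`, `k` columns). These moments feed the Taylor and mean-field
#' richness estimators. Variances and covariance use the (n - 1)
#' normalization and are defined as 0 for a single species.
#'
#' @param stats tibble from [species_stats()].
#' @return one-row tibble: `S`, `mean_mn`, `mean_P`, `var_mn`,
#'   `var_P`, `cov_mnP`, `k`.
#' @export
moment_summary <- function(stats) {
  if (nrow(stats) < 1) abort("no observed species")
  S <- nrow(stats)
  one <- S == 1L
  tibble::tibble(
    S = S,
    mean_mn = mean(stats$mn),
    mean_P = mean(stats$P),
    var_mn = if (one) 0 else var(stats$mn),
    var_P = if (one) 0 else var(stats$P),
    cov_mnP = if (one) 0 else cov(stats$mn, stats$P),
    k = stats$k[1]
  )
}
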