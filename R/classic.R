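# frequency counts shared by the classic estimators -------------------

#' Abundance and incidence frequency counts
#'
#' Singleton/doubleton summaries underlying the classic estimators:
#' `f1`, `f2` are the numbers of species with pooled abundance exactly
#' 1 and 2; `q1`, `q2` the numbers present in exactly 1 and 2 patches.
#'
#' @param x abundance matrix.
#' @return one-row tibble: `S`, `k`, `f1`, `f2`, `q1`, `q2`.
#' @export
frequency_counts <- function(x) {
  x <- as_abundance(x)
  pooled <- rowSums(x)
  occ <- rowSums(x > 0)
  tibble::tibble(
    S = sum(pooled > 0), k = ncol(x),
    f1 = sum(pooled == 1), f2 = sum(pooled == 2),
    q1 = sum(occ == 1), q2 = sum(occ == 2)
  )
}

#' Observed richness
#'
#' @param x abundance matrix.
#' @return one-row tibble (`method = "observed"`); the estimate is the
#'   number of species with at least one record.
#' @export
observed_richness <- function(x) {
  S <- sum(rowSums(as_abundance(x)) > 0)
  .estimate_row("observed", S, S)
}

#' Chao1 abundance-based richness estimator
#'
#' Turing-style estimator relating unobserved species to the observed
#' singleton/doubleton counts of pooled abundances. The default
#' bias-corrected form `S + f1(f1-1) / (2(f2+1))` is defined even with
#' no doubletons; the classic ratio form `S + f1^2 / (2 f2)` (with the
#' bias-corrected value substituted when `f2 = 0`) is available via
#' `variant`.
#'
#' @param x abundance matrix.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return one-row tibble: `method`, `estimate`, `S`.
#' @export
chao1 <- function(x, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  fc <- frequency_counts(x)
  add <-
    if (variant == "bias_corrected" || fc$f2 == 0) {
      fc$f1 * (fc$f1 - 1) / (2 * (fc$f2 + 1))
    } else {
      fc$f1^2 / (2 * fc$f2)
    }
  .estimate_row("chao1", fc$S + add, fc$S)
}

#' Chao2 incidence-based richness estimator
#'
#' Same rationale as [chao1()] but on incidences: `q1`, `q2` are
#' species found in exactly one / two patches. Bias-corrected form
#' `S + ((k-1)/k) q1(q1-1) / (2(q2+1))`. Requires at least two
#' patches; with `k < 2` the observed richness is returned with a
#' warning.
#'
#' @inheritParams chao1
#' @export
chao2 <- function(x, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  fc <- frequency_counts(x)
  if (fc$k < 2) {
    warn("chao2 requires k >= 2 patches; returning observed richness")
    return(.estimate_row("chao2", fc$S, fc$S))
  }
  fac <- (fc$k - 1) / fc$k
  add <-
    if (variant == "bias_corrected" || fc$q2 == 0) {
      fac * fc$q1 * (fc$q1 - 1) / (2 * (fc$q2 + 1))
    } else {
      fac * fc$q1^2 / (2 * fc$q2)
    }
  .estimate_row("chao2", fc$S + add, fc$S)
}

#' Abundance-based coverage estimator (ACE)
#'
#' Splits species into rare (pooled abundance at most `rare_cutoff`,
#' literature default 10) and abundant groups; estimates the sample
#' coverage of the rare group from its singletons and corrects the
#' rare richness by that coverage and a coefficient of variation term:
#' `S_abund + S_rare / C + (f1 / C) * gamma^2` with
#' `C = 1 - f1 / N_rare` and
#' `gamma^2 = max(S_rare * sum(i(i-1) f_i) / (C * N_rare * (N_rare - 1)) - 1, 0)`.
#' When every rare species is a singleton the coverage is 0 and the
#' estimator falls back to [chao1()] with a warning.
#'
#' @param x abundance matrix.
#' @param rare_cutoff pooled-abundance threshold for the rare group.
#' @return one-row tibble: `method`, `estimate`, `S`.
#' @export
ace <- function(x, rare_cutoff = 10) {
  x <- as_abundance(x)
  pooled <- rowSums(x)
  pooled <- pooled[pooled > 0]
  S <- length(pooled)
  rare <- pooled[pooled <= rare_cutoff]
  s_rare <- length(rare)
  s_abund <- S - s_rare
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  if (s_rare == 0 || n_rare <= 1) {
    return(.estimate_row("ace", S, S))
  }
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warn("all rare species are singletons (coverage 0); falling back to chao1")
    est <- chao1(x)
    return(.estimate_row("ace", est$estimate, S))
  }
  ifi <- sum(vapply(seq_len(rare_cutoff), function(i) {
    i * (i - 1) * sum(rare == i)
  }, numeric(1)))
  gamma2 <- max(s_rare * ifi / (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  .estimate_row("ace", s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2, S)
}

#' First-order jackknife richness estimator (abundance form)
#'
#' `S + f1`: every singleton hints at one unseen species.
#'
#' @param x abundance matrix.
#' @export
jackknife1_abundance <- function(x) {
  fc <- frequency_counts(x)
  .estimate_row("jackknife1_abund", fc$S + fc$f1, fc$S)
}

#' Second-order jackknife richness estimator (incidence form)
#'
#' `S + q1 (2k - 3) / k - q2 (k - 2)^2 / (k (k - 1))`. Requires at
#' least two patches; with `k < 2` observed richness is returned with
#' a warning. Can drop below `S` at extreme doubleton counts; the
#' value is reported as-is.
#'
#' @param x abundance matrix.
#' @export
jackknife2_incidence <- function(x) {
  fc <- frequency_counts(x)
  if (fc$k < 2) {
    warn("jackknife2 requires k >= 2 patches; returning observed richness")
    return(.estimate_row("jackknife2_incid", fc$S, fc$S))
  }
  k <- fc$k
  est <- fc$S + fc$q1 * (2 * k - 3) / k - fc$q2 * (k - 2)^2 / (k * (k - 1))
  .estimate_row("jackknife2_incid", est, fc$S)
}
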