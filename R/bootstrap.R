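#' Dependence-aware block bootstrap for richness estimators
#'
#' Individual records are not independent within species or patches
#' (organisms cluster), so naive individual-level resampling
#' understates uncertainty. This block bootstrap resamples whole
#' patches, then whole species. Per replicate: (1) draw `k` patches
#' with replacement from the survey; (2) let `R` be the point
#' estimate of `estimator` on the *original* matrix, rounded to the
#' nearest integer — the best available guess of true richness, used
#' instead of the downward-biased observed `S`; (3) from the species
#' still present in the patch-resampled matrix, draw `R` species with
#' replacement, each drawn copy becoming a distinct pseudospecies row;
#' (4) apply the estimator to this pseudo-community. The spread of the
#' `B` replicate values measures the estimator's precision on data
#' like these.
#'
#' Degenerate replicates (no species left after patch resampling, or
#' estimator failure) are redrawn, with a cap of `10 * B` total
#' attempts.
#'
#' @param x abundance matrix.
#' @param estimator an estimator name accepted by
#'   [estimate_richness()], or any function mapping a count matrix to
#'   a single numeric richness value.
#' @param B number of bootstrap replicates (`>= 1`); the package
#'   convention is 2000 on full data, 50 within subsample replicates.
#' @param seed RNG seed; `(seed, B)` fully determine the result.
#' @return an object of class `richness_boot` with fields `method`,
#'   `B`, `seed`, `point` (original point estimate), `estimates`
#'   (length-B numeric), `sd`, `cv` (variance/mean, the printed
#'   convention here) and `cv_sd_mean` (the conventional sd/mean).
#'   Use [tidy()] for per-replicate rows, [glance()] for a one-row
#'   summary.
#' @examples
#' fig <- rbind(black = c(2, 1, 0), shark = c(0, 0, 1), grey = c(1, 0, 0))
#' glance(block_bootstrap(fig, "omega", B = 50, seed = 1))
#' @export
block_bootstrap <- function(x, estimator, B = 2000, seed = 1) {
  x <- as_abundance(x)
  if (B < 1) abort("B must be >= 1")
  if (is.character(estimator)) {
    name <- estimator
    est_fun <- function(m) .point_estimates(m, name)[[1]]
  } else {
    name <- deparse(substitute(estimator))[1]
    est_fun <- estimator
  }
  if (sum(rowSums(x) > 0) == 0) abort("no observed species")
  k <- ncol(x)
  point <- est_fun(x)
  R <- max(1L, round(point))
  set.seed(seed)
  estimates <- numeric(B)
  attempts <- 0L
  b <- 1L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B) {
      abort("bootstrap failed: too many degenerate replicates")
    }
    patches <- sample.int(k, k, replace = TRUE)
    resampled <- x[, patches, drop = FALSE]
    pool <- which(rowSums(resampled) > 0)
    if (length(pool) == 0L) next
    rows <- sample(pool, R, replace = TRUE)
    pseudo <- resampled[rows, , drop = FALSE]
    rownames(pseudo) <- paste0("pseudo", seq_len(R))
    val <- tryCatch(suppressWarnings(est_fun(pseudo)),
                    error = function(e) NA_real_)
    if (!is.finite(val)) next
    estimates[b] <- val
    b <- b + 1L
  }
  m <- mean(estimates)
  structure(
    list(method = name, B = B, seed = seed, point = point,
         estimates = estimates,
         sd = if (B >= 2) sd(estimates) else NA_real_,
         cv = if (B >= 2) var(estimates) / m else NA_real_,
         cv_sd_mean = if (B >= 2) sd(estimates) / m else NA_real_),
    class = "richness_boot")
}

#' @export
print.richness_boot <- function(x, ...) {
  cat(sprintf(
    "Block bootstrap: %s (B = %d, seed = %d)\n  point %.3f, mean %.3f, sd %.3f, cv (var/mean) %.4f\n",
    x$method, x$B, x$seed, x$point, mean(x$estimates), x$sd, x$cv))
  invisible(x)
}

#' @rdname block_bootstrap
#' @param x a `richness_boot` object.
#' @param ... unused.
#' @method tidy richness_boot
#' @export
tidy.richness_boot <- function(x, ...) {
  tibble::tibble(method = x$method, replicate = seq_len(x$B),
                 estimate = x$estimates)
}

#' @rdname block_bootstrap
#' @method glance richness_boot
#' @export
glance.richness_boot <- function(x, ...) {
  tibble::tibble(method = x$method, B = x$B, point = x$point,
                 mean = mean(x$estimates), sd = x$sd, cv = x$cv,
                 cv_sd_mean = x$cv_sd_mean)
}

#' @rdname block_bootstrap
#' @param object a `richness_boot` object (for `autoplot`).
#' @method autoplot richness_boot
#' @export
autoplot.richness_boot <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$point, colour = "red") +
    ggplot2::labs(x = paste0(object$method, " bootstrap estimate"),
                  y = "replicates")
}
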