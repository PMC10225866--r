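# Three-species / three-patch worked example: the black fish occupies
# two patches (counts 2 + 1), shark and grey fish one patch each.
fig1_matrix <- function() {
  rbind(black_fish = c(2L, 1L, 0L),
        shark = c(0L, 0L, 1L),
        grey_fish = c(1L, 0L, 0L))
}

# seeded random count matrix for permutation/invariant checks
random_counts <- function(S, k, lambda = 1.5, seed = 1) {
  set.seed(seed)
  matrix(rpois(S * k, lambda), S, k)
}

# independent central-finite-difference oracle for the Taylor
# coefficients (relative step 1e-5 on the community detection
# probability, written out directly so the stencil can cross P = 1)
fd_coefficients <- function(mn, P, k, rel = 1e-5) {
  h1 <- mn * rel
  h2 <- P * rel
  D <- function(u, p) 1 - (1 - p * (1 - exp(-u / p)))^k
  c1 <- (D(mn + h1, P) - 2 * D(mn, P) + D(mn - h1, P)) / h1^2 / 2
  c2 <- (D(mn, P + h2) - 2 * D(mn, P) + D(mn, P - h2)) / h2^2 / 2
  c3 <- (D(mn + h1, P + h2) - D(mn + h1, P - h2) -
           D(mn - h1, P + h2) + D(mn - h1, P - h2)) / (4 * h1 * h2)
  c(c1 = c1, c2 = c2, c3 = c3)
}

# roundoff floor of the finite-difference stencils: second differences
# divide ~machine-epsilon cancellation error by h^2, so agreement can
# only be asserted down to that noise level
fd_noise <- function(mn, P, rel = 1e-5) {
  eps <- .Machine$double.eps
  h1 <- mn * rel
  h2 <- P * rel
  c(c1 = 8 * eps / h1^2, c2 = 8 * eps / h2^2, c3 = 8 * eps / (h1 * h2))
}

expect_fd_agreement <- function(mn, P, k, rel_tol = 1e-4) {
  cf <- taylor_coefficients(mn, P, k)
  fd <- fd_coefficients(mn, P, k)
  tol <- rel_tol * abs(fd) + fd_noise(mn, P)
  testthat::expect_true(
    all(abs(cf - fd) <= tol),
    label = sprintf("closed-form vs finite-difference at mn=%g P=%g k=%g",
                    mn, P, k))
  invisible(cf)
}

# benchmark ensembles are expensive; build each scenario once per test
# run and share across test files
.ens_cache <- new.env(parent = emptyenv())

scenario_ensemble <- function(name, n = 2000) {
  key <- paste0("s", name, "_", n)
  if (!exists(key, envir = .ens_cache)) {
    cfg <- scenario_preset(name, n_communities = n)
    seed <- 948000 + match(name, c("I", "II", "III", "IV"))
    assign(key, run_scenario(cfg, seed = seed), envir = .ens_cache)
  }
  get(key, envir = .ens_cache)
}
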