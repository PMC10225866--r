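test_that("community-level draws follow the jitter formulas", {
  cfg <- scenario_config(E_m = 1, E_P = 1, E_n = 10, k_range = c(3, 3),
                         N = 10)
  set.seed(1)
  for (i in 1:5) {
    cp <- draw_community_params(cfg)
    expect_equal(cp$m_tilde, 1)   # variance term vanishes at E = 1
    expect_equal(cp$P_tilde, 1)
    expect_identical(cp$k, 3L)
  }
  # mean of the abundance draw converges on E_n
  cfg2 <- scenario_config(E_m = 0.5, E_P = 0.5, E_n = 10,
                          k_range = c(2, 10), N = 100)
  set.seed(2)
  draws <- replicate(4000, draw_community_params(cfg2)$n_tilde)
  expect_equal(mean(draws), 10, tolerance = 0.1)
  expect_true(all(draws >= 0 & draws <= 20))
  # jittered means stay inside E +/- E(1-E)/2
  set.seed(3)
  ms <- replicate(2000, draw_community_params(cfg2)$m_tilde)
  expect_true(all(abs(ms - 0.5) <= 0.125 + 1e-12))
})

test_that("species abundances follow the floored, rescaled lognormal", {
  # large n_tilde: the floor never binds and the rescale factor is 1
  set.seed(4)
  sp <- draw_species_params(0.5, 1, 5000, richness = 500)
  expect_true(all(sp$n >= 1))
  set.seed(4)
  runif(2 * 500)  # the m and P jitters consume uniforms first
  ref <- rlnorm(500, log(5000) - 0.5, 1)  # same draws, P_tilde = 1
  expect_equal(sp$n, ref, tolerance = 1e-12)

  # lognormal with underlying mean log(n) - 0.5, sd 1 has mean n
  set.seed(5)
  sp2 <- draw_species_params(0.5, 1, 20, richness = 20000)
  expect_equal(mean(sp2$n), 20, tolerance = 0.05 * 20)

  # per-species jitters stay in range and at E = 1 are exact
  sp3 <- draw_species_params(1, 1, 10, richness = 50)
  expect_true(all(sp3$m == 1) && all(sp3$P == 1))
})

test_that("patch population follows occupancy-gated Poisson counts", {
  set.seed(6)
  pp <- populate_patches(P = c(0, 1), n = c(5, 5), N = 2000)
  expect_true(all(pp$counts[1, ] == 0))        # never occupied
  expect_true(all(pp$occupancy[2, ]))          # always occupied
  expect_equal(mean(pp$counts[2, ]), 5, tolerance = 0.2)
  expect_equal(mean(pp$counts[2, ] > 0), 1 - exp(-5), tolerance = 0.02)

  set.seed(7)
  pp2 <- populate_patches(P = 0.3, n = 2, N = 5000)
  expect_equal(mean(pp2$occupancy[1, ]), 0.3, tolerance = 0.03)
})

test_that("the survey samples patches without replacement and drops the unseen", {
  set.seed(8)
  occ <- matrix(TRUE, 3, 20)
  ob <- observe_survey(occ, m = c(0, 2, 1), n = c(5, 5, 5), k = 10)
  expect_identical(length(unique(ob$sampled)), 10L)
  # zero catchability species can never appear
  expect_false("sp1" %in% rownames(ob$observed))
  expect_error(observe_survey(occ, 1, 1, k = 21), "k must be")

  # unoccupied everywhere: nothing observed
  set.seed(9)
  ob2 <- observe_survey(matrix(FALSE, 2, 10), m = c(1, 1), n = c(5, 5),
                        k = 5)
  expect_identical(nrow(ob2$observed), 0L)
})

test_that("observed richness never exceeds true richness", {
  cfg <- scenario_preset("III", n_communities = 1)
  set.seed(10)
  for (i in 1:40) {
    sim <- simulate_community(cfg)
    expect_lte(sim$S_obs, sim$true_richness)
    expect_identical(nrow(sim$true_stats), sim$true_richness)
  }
  sim5 <- simulate_community(cfg, richness = 5)
  expect_identical(sim5$true_richness, 5L)
})

test_that("ensembles are reproducible and carry estimator columns", {
  cfg <- scenario_preset("II", n_communities = 30)
  a <- run_scenario(cfg, seed = 99)
  b <- run_scenario(cfg, seed = 99)
  expect_identical(a, b)
  expect_identical(nrow(a), 30L)
  expect_true(all(c("true_richness", "S_obs", "omega", "omega_C",
                    "chao1") %in% names(a)))
  expect_true(all(a$S_obs <= a$true_richness))
  expect_true(all(a$true_richness >= 1 & a$true_richness <= 100))
})

test_that("near-perfect surveys recover the truth for every estimator", {
  cfg <- scenario_config(E_m = 1, E_P = 1, E_n = 50,
                         k_range = c(100, 100), N = 100,
                         n_communities = 25)
  ens <- run_scenario(cfg, seed = 12)
  expect_true(all(ens$S_obs == ens$true_richness))
  expect_equal(ens$omega, ens$true_richness, tolerance = 1e-6)
  expect_equal(ens$observed, ens$true_richness, tolerance = 1e-9)
  expect_equal(ens$omega_C, ens$true_richness, tolerance = 1e-6)
  expect_equal(ens$chao1, ens$true_richness, tolerance = 1e-9)
})
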