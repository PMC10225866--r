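# helper: one species per pooled abundance, spread so occupancy counts
# are controlled too (each species' individuals all in distinct patches)
pooled_matrix <- function(abundances, k = max(abundances)) {
  m <- matrix(0L, length(abundances), k)
  for (i in seq_along(abundances)) {
    a <- abundances[i]
    if (a > 0) m[i, seq_len(min(a, k))] <- as.integer(
      c(rep(1L, min(a, k) - 1), a - min(a, k) + 1))
  }
  m
}

test_that("observed richness counts species with positive totals", {
  expect_identical(observed_richness(fig1_matrix())$estimate, 3)
  expect_identical(observed_richness(matrix(0L, 2, 2))$estimate, 0)
  with_zero <- rbind(fig1_matrix(), extra = c(0L, 0L, 0L))
  expect_identical(observed_richness(with_zero)$estimate, 3)
})

test_that("chao1 follows singleton/doubleton counts of pooled abundances", {
  # S = 3, f1 = 2, f2 = 1 -> 3 + 2*1/(2*2) = 3.5
  expect_equal(chao1(pooled_matrix(c(1, 1, 2)))$estimate, 3.5)
  # worked-example pooled abundances (3, 1, 1): f1 = 2, f2 = 0 -> 4
  expect_equal(chao1(fig1_matrix())$estimate, 4)
  # no singletons: estimate equals observed richness
  expect_equal(chao1(pooled_matrix(c(3, 5, 2)))$estimate, 3)
  # classic ratio form
  expect_equal(chao1(pooled_matrix(c(1, 1, 2)), "classic")$estimate,
               3 + 4 / 2)
})

test_that("chao2 follows incidence singletons with the (k-1)/k factor", {
  # occupancy pattern of the worked example: q1 = 2, q2 = 1, k = 3
  expect_equal(chao2(fig1_matrix())$estimate, 3 + (2 / 3) * 2 / 4)
  # no incidence singletons
  m <- rbind(c(1L, 1L, 0L), c(0L, 2L, 3L))
  expect_equal(chao2(m)$estimate, 2)
  expect_warning(est <- chao2(matrix(c(1L, 2L), 2, 1)), "k >= 2")
  expect_equal(est$estimate, 2)
})

test_that("ace matches a hand evaluation and its boundary cases", {
  # abundances (1, 1, 2, 15): S_abund = 1, S_rare = 3, N_rare = 4,
  # f1 = 2, C = 0.5, gamma2 = max(3*2/(0.5*4*3) - 1, 0) = 0
  # -> 1 + 3/0.5 + (2/0.5)*0 = 7
  expect_equal(ace(pooled_matrix(c(1, 1, 2, 15)))$estimate, 7)
  # all species abundant: ACE = S
  expect_equal(ace(pooled_matrix(c(12, 20, 15)))$estimate, 3)
  # rare species but no singletons: coverage 1, ACE = S
  m <- pooled_matrix(c(2, 3, 40))
  expect_equal(ace(m)$estimate, 3)
  # every rare species a singleton: coverage 0, falls back to chao1
  expect_warning(est <- ace(pooled_matrix(c(1, 1, 30))), "chao1")
  expect_equal(est$estimate, chao1(pooled_matrix(c(1, 1, 30)))$estimate)
})

test_that("jackknife estimators follow their closed forms", {
  expect_equal(jackknife1_abundance(fig1_matrix())$estimate, 5)  # S + f1
  expect_equal(jackknife1_abundance(pooled_matrix(c(2, 3)))$estimate, 2)
  # adding a new singleton species raises the estimate by exactly 2
  base <- pooled_matrix(c(1, 4, 6))
  plus <- rbind(base, c(1L, rep(0L, ncol(base) - 1)))
  expect_equal(jackknife1_abundance(plus)$estimate,
               jackknife1_abundance(base)$estimate + 2)

  # S = 3, k = 3, q1 = 2, q2 = 1 -> 3 + 2*(3/3) - 1*(1/6)
  expect_equal(jackknife2_incidence(fig1_matrix())$estimate,
               3 + 2 - 1 / 6)
  # q1 = q2 = 0
  m <- rbind(c(1L, 1L, 2L), c(3L, 1L, 1L))
  expect_equal(jackknife2_incidence(m)$estimate, 2)
  # k = 2: the q2 term vanishes, leaving S + q1/2
  m2 <- rbind(c(1L, 0L), c(2L, 3L))
  expect_equal(jackknife2_incidence(m2)$estimate, 2 + 1 * (2 * 2 - 3) / 2)
})

test_that("estimators are permutation invariant and use the right data view", {
  m <- random_counts(15, 6, lambda = 0.6, seed = 9)
  shuffled <- m[sample(nrow(m)), sample(ncol(m))]
  for (f in list(chao1, chao2, ace, jackknife1_abundance,
                 jackknife2_incidence)) {
    expect_equal(f(shuffled)$estimate, f(m)$estimate)
  }
  # chao1 depends only on pooled abundances: moving individuals
  # between patches changes nothing
  moved <- cbind(rowSums(m), matrix(0L, nrow(m), 5))
  expect_equal(chao1(moved)$estimate, chao1(m)$estimate)
  # chao2 depends only on incidence: doubling counts changes nothing
  expect_equal(chao2(m * 2L)$estimate, chao2(m)$estimate)
})

test_that("the full estimator panel runs on one call", {
  out <- estimate_richness(fig1_matrix())
  expect_identical(nrow(out), 9L)
  expect_true(all(out$estimate[out$method != "omega_T"] >= 3))
  expect_setequal(
    out$method,
    c("observed", "chao1", "chao2", "ace", "jackknife1_abund",
      "jackknife2_incid", "omega", "omega_T", "omega_0"))
  with_boot <- estimate_richness(fig1_matrix(), methods = c("observed",
                                                            "omega"),
                                 bootstrap = TRUE, B = 25, seed = 4)
  expect_true(all(c("sd", "cv", "cv_sd_mean") %in% names(with_boot)))
  expect_true(all(is.finite(with_boot$sd)))
})
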