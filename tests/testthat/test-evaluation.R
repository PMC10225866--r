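test_that("regression slope and robust s.d. behave on exact relations", {
  true <- rep(1:50, 2)
  # exact fits trip base R's perfect-fit note; the values are the point
  exact <- suppressWarnings(slope_hac(true, true))
  expect_equal(exact$slope, 1)
  expect_equal(exact$slope_sd, 0)
  expect_equal(suppressWarnings(slope_hac(true, 2 * true))$slope, 2)
  expect_error(slope_hac(rep(5, 10), 1:10), "constant")
  expect_error(slope_hac(1:2, 1:2), "at least 3")
})

test_that("robust slope s.d. exceeds the classical one under heteroscedasticity", {
  set.seed(21)
  true <- 1:300
  est <- true + rnorm(300, sd = 0.2 * true)  # noise grows with truth
  sl <- slope_hac(true, est)
  expect_gt(sl$slope_sd, sl$slope_sd_ols)
})

test_that("accuracy against the 1:1 line penalizes bias and large errors", {
  true <- c(10, 20, 30, 40, 50)
  expect_equal(r2_star(true, true), 1)
  expect_equal(r2_star(true, rep(mean(true), 5)), 0)
  expect_lt(r2_star(true, c(500, 1, 900, 2, 700)), 0)
  # contrast with regression R2: a biased but linear estimator keeps
  # regression R2 at 1 while r2_star drops
  expect_lt(r2_star(true, 0.5 * true), 1)
})

test_that("difference detection scores sign agreement within the band", {
  true <- rep(1:60, each = 4)
  set.seed(31)
  expect_equal(detection_accuracy(true, true, 2, n_pairs = 500), 1)
  # constant estimator: all ties, zero accuracy under the tie rule
  expect_equal(detection_accuracy(true, rep(7, length(true)), 10,
                                  n_pairs = 500), 0)
  expect_equal(detection_accuracy(true, rep(7, length(true)), 10,
                                  n_pairs = 500, ties = "half"), 0.5)
  # noise far larger than the band: a coin flip
  noisy <- true + rnorm(length(true), sd = 50)
  acc <- detection_accuracy(true, noisy, 2, n_pairs = 4000)
  expect_equal(acc, 0.5, tolerance = 0.06)
  expect_error(detection_accuracy(rep(3, 10), 1:10, 2, n_pairs = 10),
               "no qualifying pairs")
})

test_that("pair drawing respects the difference band", {
  true <- rep(1:50, each = 3)
  set.seed(41)
  pairs <- draw_detection_pairs(true, 10, 800)
  d <- true[pairs[, 1]] - true[pairs[, 2]]
  expect_identical(nrow(pairs), 800L)
  expect_true(all(d != 0 & abs(d) <= 10))
})

test_that("standardized scores are z-scores with guarded degenerate columns", {
  report <- tibble::tibble(
    method = c("a", "b", "c"),
    slope = c(1, 0.8, 0.6), slope_sd = c(0.1, 0.1, 0.1),
    r2_star = c(0.9, 0.5, 0.1), det2 = c(0.6, 0.5, 0.4),
    det10 = c(0.8, 0.7, 0.6), det20 = c(0.9, 0.8, 0.7))
  sc <- standardized_scores(report)
  # slope_sd has zero spread across estimators: guarded to 0
  expect_equal(sc$score_slope_sd, c(0, 0, 0))
  # remaining columns are plain z-scores of the performance transform
  expect_equal(sc$score_r2_star,
               (report$r2_star - mean(report$r2_star)) / sd(report$r2_star))
  expect_equal(sc$score_slope,
               as.numeric(scale(1 - abs(report$slope - 1))))
  # identical estimators share identical overall scores
  rep2 <- report[c(1, 1, 2), ]
  sc2 <- standardized_scores(rep2)
  expect_equal(sc2$overall[1], sc2$overall[2])
})

test_that("rolling bounds summarize estimates around each true richness", {
  true <- rep(1:20, each = 5)
  est <- rep(3, 100)
  rb <- rolling_bounds(true, est, window = 10)
  expect_true(all(rb$sd == 0))
  expect_true(all(rb$mean == 3))
  # a window spanning the whole range reproduces global moments
  rb2 <- rolling_bounds(true, true + 0.5, window = 1000)
  expect_equal(unique(rb2$mean), mean(true) + 0.5)
  # edges truncate: the first centre only sees truths within 5 above
  rb3 <- rolling_bounds(true, true, window = 10)
  expect_equal(rb3$n[1], sum(true <= 1 + 5))
})

test_that("a performance report covers every estimator with shared pairs", {
  ens <- tibble::tibble(true_richness = rep(5:64, each = 2))
  set.seed(51)
  ens$good <- ens$true_richness + rnorm(nrow(ens), sd = 2)
  ens$bad <- 0.3 * ens$true_richness + rnorm(nrow(ens), sd = 15)
  rep <- performance_report(ens, estimators = c("good", "bad"),
                            n_pairs = 400, seed = 3)
  expect_identical(rep$method, c("good", "bad"))
  expect_gt(rep$r2_star[1], rep$r2_star[2])
  expect_gt(rep$det2[1], rep$det2[2])
  expect_true(all(rep$det2 >= 0 & rep$det2 <= 1))
  sc <- standardized_scores(rep)
  expect_gt(sc$overall[1], sc$overall[2])
})
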