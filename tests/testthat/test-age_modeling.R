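test_that("noiseless quadratic cohorts are recovered exactly", {
  coh <- gen_cohort(n = 120, noise_sd = 0, seed = 1)
  fit <- suppressWarnings(fit_fi_age(coh))
  expect_identical(fit$best_family, "quadratic")
  expect_lt(max(abs(coef(fit) - c(a = -2e-4, b = 0.016, c = 0.1))), 1e-6)
  expect_gt(fit$r2, 0.999999)
  expect_equal(nrow(fit$aic_table), 5L)
  # model-object methods behave like a classic fit
  expect_length(predict(fit, data.frame(age = c(10, 40))), 2L)
  expect_equal(fitted(fit), coh$FI, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-7)
  expect_equal(dim(simulate(fit, nsim = 2, seed = 1)), c(120L, 2L))
  expect_error(fit_fi_age(gen_cohort(n = 5, seed = 2)), "at least 10")
})

test_that("quadratic family wins AIC on noisy quadratic cohorts", {
  wins <- 0L
  for (r in 1:20) {
    coh <- gen_cohort(n = 178, noise_sd = 0.02, seed = 500 + r)
    f <- suppressWarnings(fit_fi_age(coh))
    if (f$best_family == "quadratic") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("permutation test is calibrated on pure noise", {
  set.seed(9)
  coh <- data.frame(age = runif(80, 8, 60), FI = runif(80, 0.2, 0.4))
  f <- suppressWarnings(fit_fi_age(coh, n_perm = 199, seed = 10))
  expect_gt(f$perm_p, 0.05)
  # and detects a real quadratic signal
  coh2 <- gen_cohort(n = 100, noise_sd = 0.02, seed = 11)
  f2 <- suppressWarnings(fit_fi_age(coh2, n_perm = 199, seed = 12))
  expect_lt(f2$perm_p, 0.01)
})

test_that("rank-sum comparison matches exact enumeration and has power", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1)   # 2 / choose(6, 3)
  expect_warning(res2 <- compare_groups(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(res2$p.value, 1)
  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "at least 3")
  # power at the planted clinical offset
  hits <- 0L
  for (r in 1:40) {
    hp <- gen_cohort(n = 25, noise_sd = 0.02, seed = 700 + r)
    rd <- gen_cohort(n = 25, noise_sd = 0.02, group = "RD",
                     group_offset = -0.1, seed = 800 + r)
    if (compare_groups(hp$FI, rd$FI)$p.value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 38L)
})

test_that("multi-class SVM separates shifted groups and stays at chance without shift", {
  g <- gen_group_features(30, shift = 2, seed = 9)
  r <- classify_age_groups(g$x, g$group, k = 5, reps = 10, seed = 10)
  expect_gte(r$mean, 80)
  g0 <- gen_group_features(30, shift = 0, seed = 7)
  r0 <- classify_age_groups(g0$x, g0$group, k = 5, reps = 10, seed = 8)
  # within +/- 6 points of the 16.7% chance level
  expect_lt(abs(r0$mean - r0$chance), 6)
  expect_error(classify_age_groups(g$x, g$group, k = 1), "k >= 2")
  few <- gen_group_features(3, shift = 1, seed = 11)
  expect_error(classify_age_groups(few$x, few$group, k = 5), "loo")
  # scaling invariance: multiplying a feature by a constant changes nothing
  x_scaled <- g$x; x_scaled[, 1] <- x_scaled[, 1] * 100
  r_s <- classify_age_groups(x_scaled, g$group, k = 5, reps = 5, seed = 10)
  r_u <- classify_age_groups(g$x, g$group, k = 5, reps = 5, seed = 10)
  expect_equal(r_s$mean, r_u$mean)
})

test_that("SVR explains age from informative features and not from permuted ones", {
  set.seed(7)
  ages <- runif(90, 8, 60)
  x <- sapply(1:22, function(j) 0.1 * j * ages + rnorm(90, 0, 5))
  r <- regress_age(x, ages, reps = 5, seed = 3)
  expect_gte(r$mean, 0.8)
  rp <- regress_age(x, sample(ages), reps = 5, seed = 4)
  expect_lte(rp$mean, 0.05)
  rc <- regress_age(matrix(1, 90, 4), ages, reps = 3, seed = 5)
  expect_equal(rc$mean, 0)
  expect_true(rc$flag_nonpositive)
})
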