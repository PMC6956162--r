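test_that("surrogate p-value is the exceedance proportion", {
  expect_equal(surrogate_pvalue(5, 1:4), 0)
  expect_equal(surrogate_pvalue(0, 1:4), 1)
  expect_equal(surrogate_pvalue(50.5, 1:100), 0.5)
  expect_error(surrogate_pvalue(1, numeric(0)), "empty")
})

test_that("BH retention matches the step-up oracle", {
  # oracle: largest i with p_(i) <= q i / m, retain all smaller
  bh_oracle <- function(p, q) {
    o <- order(p)
    ok <- p[o] <= q * seq_along(p) / length(p)
    keep <- logical(length(p))
    if (any(ok)) keep[o[seq_len(max(which(ok)))]] <- TRUE
    keep
  }
  expect_identical(fdr_filter(c(0.002, 0.004, 0.02), q = 0.01),
                   c(TRUE, TRUE, FALSE))
  expect_identical(fdr_filter(c(0.002, 0.004, 0.02), q = 0.01),
                   bh_oracle(c(0.002, 0.004, 0.02), 0.01))
  expect_identical(fdr_filter(rep(1, 5), 0.01), rep(FALSE, 5))
  expect_identical(fdr_filter(numeric(0)), logical(0))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(30)^2
    expect_identical(fdr_filter(p, 0.05), bh_oracle(p, 0.05))
  }
  # zeros are retained (attainable with the exceedance estimator)
  expect_identical(fdr_filter(c(0, 0.9), 0.01), c(TRUE, FALSE))
})

test_that("dominant-mode selection follows the single/multi estimator rules", {
  cand <- function(...) {
    d <- data.frame(...)
    names(d) <- c("est_id", "code", "strength", "p")
    d
  }
  one <- cand(est_id = 2, code = 3, strength = 0.7, p = 0.001)
  expect_equal(nrow(select_dicm(one)), 1L)
  # single estimator, several codes: keep its max-strength candidate
  same <- cand(est_id = c(2, 2), code = c(3, 4), strength = c(0.5, 0.8),
               p = c(0.001, 0.002))
  expect_equal(select_dicm(same)$code, 4)
  # three estimators below the multi threshold: two smallest p retained
  three <- cand(est_id = c(1, 2, 5), code = c(1, 3, 5),
                strength = c(0.4, 0.6, 0.9), p = c(0.0001, 0.0020, 0.0005))
  sel <- select_dicm(three)
  expect_equal(nrow(sel), 2L)
  expect_setequal(sel$est_id, c(1, 5))
  expect_true(all(diff(sel$p) >= 0))
  # several estimators but none below 0.0025: single max-strength fallback
  weak <- cand(est_id = c(1, 2), code = c(1, 3), strength = c(0.4, 0.6),
               p = c(0.006, 0.008))
  expect_equal(select_dicm(weak)$est_id, 2)
  # p = 0 ties break toward larger strength
  ties <- cand(est_id = c(1, 2, 3), code = c(1, 3, 21),
               strength = c(0.2, 0.9, 0.8), p = c(0, 0, 0))
  expect_setequal(select_dicm(ties)$est_id, c(2, 3))
  expect_equal(nrow(select_dicm(one[0, ])), 0L)
})

test_that("circular-shift surrogates separate planted from null coupling", {
  rec <- gen_recording(2, 150, 10,
                       plan = plan_entry(c(1, 2), "iplv", "beta3",
                                         strength = 0.95),
                       seed = 21)
  bn <- filterbank(rec)
  ph <- bn$phase$beta3
  idx <- 301:600
  stat <- function(x, y) iplv(x[idx], y[idx])
  surr <- make_surrogates(ph[, 1], ph[, 2], stat, n_surr = 200, fs = 150,
                          seed = 5)
  obs <- stat(ph[, 1], ph[, 2])
  expect_equal(surrogate_pvalue(obs, surr), 0)
  # independent pair: observed sits inside the surrogate distribution
  rec0 <- gen_recording(2, 150, 10, seed = 22)
  ph0 <- filterbank(rec0)$phase$alpha1
  surr0 <- make_surrogates(ph0[, 1], ph0[, 2], stat, n_surr = 200, fs = 150,
                           seed = 6)
  expect_gt(surrogate_pvalue(stat(ph0[, 1], ph0[, 2]), surr0), 0.01)
  expect_error(make_surrogates(ph[, 1], ph[, 2], stat, 0, 150), "n_surr")
  expect_error(make_surrogates(ph[1:200, 1], ph[1:200, 2], stat, 10, 150),
               "shift")
})

test_that("null surrogate p-values are approximately uniform", {
  set.seed(31)
  pv <- numeric(0)
  for (s in 1:4) {
    rec <- gen_recording(2, 150, 28, seed = 33 + s)
    ph <- filterbank(rec)$phase$alpha1
    n <- nrow(ph)
    starts <- seq(1, n - 300, by = 300)  # non-overlapping windows
    pv <- c(pv, vapply(seq_along(starts), function(i) {
      idx <- starts[i]:(starts[i] + 299)
      obs <- iplv(ph[idx, 1], ph[idx, 2])
      offs <- sample(150:(n - 150), 199)
      surr <- vapply(offs, function(o)
        iplv(ph[idx, 1], ph[((idx - 1 + o) %% n) + 1, 2]), 0)
      surrogate_pvalue(obs, surr)
    }, 0))
  }
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the pipeline recovers a planted same-frequency coupling", {
  rec <- gen_recording(2, 150, 10,
                       plan = plan_entry(c(1, 2), "iplv", "beta3",
                                         strength = 0.8),
                       seed = 41)
  dt <- run_dicm(rec, estimators = c("aec", "iplv", "dpli"), n_surr = 200,
                 seed = 42)
  expect_s3_class(dt, "dicm_tensor")
  hit <- vapply(seq_len(dt$n_windows), function(t)
    any(dt$code[, t, 1] == within_code("beta3") & dt$est[, t, 1] == 2),
    TRUE)
  expect_gte(mean(hit), 0.9)
  # records sorted by ascending p; strengths in [0, 1]
  p1 <- dt$p[1, , 1]; p2 <- dt$p[2, , 1]
  both <- !is.na(p1) & !is.na(p2)
  expect_true(all(p1[both] <= p2[both]))
  st <- dt$strength[!is.na(dt$strength)]
  expect_true(all(st >= 0 & st <= 1))
  # bit-exact reproducibility under a fixed seed
  dt2 <- run_dicm(rec, estimators = c("aec", "iplv", "dpli"), n_surr = 200,
                  seed = 42)
  expect_identical(dt$code, dt2$code)
  expect_identical(dt$strength, dt2$strength)
})
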