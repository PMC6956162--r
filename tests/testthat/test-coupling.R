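test_that("iPLV analytic limits", {
  ph <- phase_ramp(400)
  expect_equal(iplv(ph, ph - pi / 2), 1, tolerance = 1e-12)
  expect_equal(iplv(ph, ph), 0, tolerance = 1e-12)
  expect_equal(iplv(ph, ph - pi / 6), 0.5, tolerance = 1e-12)
  # invariant to a common constant phase offset
  expect_equal(iplv(ph + 1.3, ph - pi / 6 + 1.3), 0.5, tolerance = 1e-12)
  expect_error(iplv(ph[1:4], ph[1:4]), "length")
})

test_that("dPLI analytic limits and strength", {
  ph <- phase_ramp(400)
  expect_equal(dpli(ph + 0.4, ph), 1)
  expect_equal(dpli(ph, ph), 0.5)
  expect_equal(dpli(ph - 0.4, ph), 0)
  expect_equal(dpli_strength(dpli(ph, ph)), 0)
  expect_equal(dpli(ph + 1.3, ph + 1.3), 0.5)  # common-offset invariance
})

test_that("AEC limits, affine invariance, and null behaviour", {
  e <- abs(sin(seq(0, 7, length.out = 340))) + 0.5
  expect_equal(aec(e, e), 1)
  expect_equal(aec(e, 10 - e), -1)
  expect_equal(aec(e, 3 + 2 * e), 1)  # positive affine rescaling
  expect_true(is.na(aec(e, rep(1, 340))))
  set.seed(1)
  null_r <- replicate(1000, abs(aec(abs(rnorm(340)), abs(rnorm(340)))))
  expect_gte(mean(null_r < 0.2), 0.95)
})

test_that("PAC strength increases with modulation depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  m <- matrix(0, length(depths), 4)
  for (r in 1:4) for (i in seq_along(depths)) {
    if (depths[i] == 0) {
      rec <- gen_recording(2, 150, 6, seed = 300 * r + i)
    } else {
      rec <- gen_recording(2, 150, 6,
                           plan = plan_entry(c(1, 2), "pac", "theta", "gamma",
                                             strength = depths[i]),
                           seed = 300 * r + i)
    }
    bn <- filterbank(rec)
    m[i, r] <- pac(bn$phase$theta[, 1], bn$env$gamma[, 2], "theta", 150)
  }
  means <- rowMeans(m)
  expect_true(all(diff(means) > 0))
  expect_gt(means[length(depths)], 0.8)
})

test_that("28 cross-band pairs are enumerated", {
  fc <- freq_codes()
  expect_equal(sum(fc$type == "cross"), 28L)
  expect_equal(nrow(fc), 36L)
  expect_equal(cross_code("theta", "gamma"), 21L)
})

test_that("neural gas recovers separated clusters; k = 1 gives the mean", {
  set.seed(5)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 5), ncol = 2),
             matrix(rnorm(200, -5), ncol = 2))
  cb <- neural_gas_codebook(x, 3, seed = 2)
  cb <- cb[order(cb[, 1]), ]
  # prototypes within 0.1 sd of the cluster sample means
  sample_means <- rbind(colMeans(x[201:300, ]), colMeans(x[1:100, ]),
                        colMeans(x[101:200, ]))
  expect_lt(max(abs(cb - sample_means)), 0.1)
  expect_equal(neural_gas_codebook(x, 1), matrix(colMeans(x), 1))
  expect_identical(neural_gas_codebook(x, 3, seed = 7),
                   neural_gas_codebook(x, 3, seed = 7))
  expect_error(neural_gas_codebook(matrix(1, 5, 2), 3), "distinct")
})

test_that("dSTE recovers direction and delay of a noisy shifted copy", {
  set.seed(6)
  a <- sample(1:8, 600, replace = TRUE)
  b <- c(rep(1L, 3), a[1:597])
  noise <- sample(1:8, 600, replace = TRUE)
  pick <- runif(600) < 0.1
  b[pick] <- noise[pick]
  d <- dste(a, b, 8, 1:5)
  expect_equal(d$direction, 1L)
  expect_equal(d$delay, 3L)
  expect_gt(d$strength, 0.5)
  # identical series: symmetric, near-zero net flow
  di <- dste(a, a, 8, 1:5)
  expect_lt(abs(di$te_ab - di$te_ba), 1e-12)
  # independent series: small net strength on average
  set.seed(7)
  nulls <- replicate(20, {
    dste(sample(1:8, 400, replace = TRUE),
         sample(1:8, 400, replace = TRUE), 8, 1:5)$strength
  })
  expect_lt(mean(nulls), 0.3)
  dg <- dste(rep(1L, 100), sample(1:8, 100, replace = TRUE), 8, 1:3)
  expect_true(dg$degenerate)
  expect_equal(dg$strength, 0)
})

test_that("compiled net-dSTE batch matches the R implementation", {
  set.seed(3)
  for (i in 1:5) {
    a <- sample(1:8, 280, replace = TRUE)
    b <- sample(1:8, 280, replace = TRUE)
    expect_equal(dicmflex:::dste_net_batch(a, matrix(b, ncol = 1), 8L, 1:10)[1],
                 dste(a, b, 8, 1:10)$strength, tolerance = 1e-12)
  }
})

test_that("estimate_all enumerates admissible candidates and finds planted modes", {
  et <- estimator_table()
  cand <- dicmflex:::candidate_table(et$name)
  expect_equal(nrow(cand), 36 + 8 + 28 + 36 + 36)
  expect_true(all(cand$code[cand$est == "iplv"] <= 8))
  expect_true(all(cand$code[cand$est == "pac"] > 8))
  rec <- gen_recording(2, 150, 6,
                       plan = plan_entry(c(1, 2), "iplv", "alpha1",
                                         strength = 0.9, lag = pi / 2),
                       seed = 8)
  ea <- estimate_all(filterbank(rec), estimators = "iplv")
  avg <- rowMeans(ea$strengths[, , 1])
  expect_equal(ea$candidates$code[which.max(avg)], within_code("alpha1"))
  # an all-zero recording degenerates cleanly
  rec0 <- new_recording(matrix(0, 2, 900) + 0, fs = 150)
  ea0 <- estimate_all(filterbank(rec0), estimators = "aec")
  expect_true(all(is.na(ea0$strengths)))
})
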