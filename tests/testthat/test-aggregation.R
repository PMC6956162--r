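# Toy tensors on the 4-channel frontal/temporal layout. Pair order for
# ch1..ch4 is (1,2) (1,3) (1,4) (2,3) (2,4) (3,4); pair 1 is the
# frontal L-R pair, pair 6 the temporal L-R pair.

test_that("dominance applies strict >75% sensor and >=50% segment rules", {
  lay <- toy_layout()
  T <- 10
  # mode (aec, delta) on all 4 cross-lobe pairs (1,3)(1,4)(2,3)(2,4)
  # in 6 of 10 windows
  code <- matrix(0L, T, 6); est <- matrix(0L, T, 6)
  cross_pairs <- c(2, 3, 4, 5)
  code[1:6, cross_pairs] <- 1L; est[1:6, cross_pairs] <- 1L
  dt <- toy_tensor(est, code)
  d <- dominance(dt, lay)
  row <- d[d$group1 == "frontal.L" & d$group2 == "temporal.R" &
             d$est_id == 1 & d$code == 1, ]
  expect_true(nrow(row) == 1)
  # full frontal-temporal subnetwork: 4/4 pairs in 6/10 windows -> dominant
  idx <- dicmflex:::subnet_pairs(dt, lay, "frontal", "temporal", "both")
  expect_setequal(idx, cross_pairs)
  expect_equal(as.numeric(dicmflex:::fo_on_pairs(dt, idx, 1, 1)), 0.6)
  # 3 of 4 pairs (exactly 75%) is NOT dominant (strict inequality)
  code2 <- matrix(0L, T, 6); est2 <- matrix(0L, T, 6)
  code2[1:6, c(2, 3, 4)] <- 1L; est2[1:6, c(2, 3, 4)] <- 1L
  dt2 <- toy_tensor(est2, code2)
  expect_equal(as.numeric(dicmflex:::fo_on_pairs(dt2, idx, 1, 1)), 0)
  # 4/4 pairs but only 4/10 windows: FO 0.4 < 0.5 -> not dominant
  code3 <- matrix(0L, T, 6); est3 <- matrix(0L, T, 6)
  code3[1:4, cross_pairs] <- 1L; est3[1:4, cross_pairs] <- 1L
  dt3 <- toy_tensor(est3, code3)
  d3 <- dominance(dt3, lay)
  expect_true(all(!d3$dominant[d3$code == 1]))
})

test_that("MSS averages matching-pair strengths over dominant segments", {
  lay <- toy_layout()
  T <- 5
  code <- matrix(0L, T, 6); est <- matrix(0L, T, 6)
  s <- matrix(0, T, 6)
  cross_pairs <- c(2, 3, 4, 5)
  code[1:3, cross_pairs] <- 1L; est[1:3, cross_pairs] <- 1L
  s[1:3, cross_pairs] <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 3), 3)
  dt <- toy_tensor(est, code, s)
  val <- mss(dt, lay, "frontal", "temporal", "both", est_id = 1, code = 1)
  expect_equal(as.numeric(val), 0.5)   # hand computation: mean of 2.0/4
  # constant 0.5 strengths -> MSS 0.5; zero strengths -> 0
  s2 <- s; s2[1:3, cross_pairs] <- 0.5
  expect_equal(as.numeric(mss(toy_tensor(est, code, s2), lay, "frontal",
                              "temporal", "both", est_id = 1, code = 1)), 0.5)
  s3 <- s; s3[1:3, cross_pairs] <- 0
  expect_equal(as.numeric(mss(toy_tensor(est, code, s3), lay, "frontal",
                              "temporal", "both", est_id = 1, code = 1)), 0)
  # no dominant segment -> 0 with flag
  none <- mss(toy_tensor(matrix(0L, T, 6), matrix(0L, T, 6)), lay,
              "frontal", "temporal", "both", est_id = 1, code = 1)
  expect_equal(as.numeric(none), 0)
  expect_true(attr(none, "flag"))
})

test_that("FO is the dominant-segment fraction", {
  lay <- toy_layout()
  T <- 90
  code <- matrix(0L, T, 6); est <- matrix(0L, T, 6)
  code[1:45, 1] <- 3L; est[1:45, 1] <- 2L
  dt <- toy_tensor(est, code)
  expect_equal(as.numeric(fo(dt, lay, "frontal", scope = "cross",
                             est_id = 2, code = 3)), 0.5)
  code[, 1] <- 3L; est[, 1] <- 2L
  expect_equal(as.numeric(fo(toy_tensor(est, code), lay, "frontal",
                             scope = "cross", est_id = 2, code = 3)), 1)
  expect_equal(as.numeric(fo(dt, lay, "temporal", scope = "cross",
                             est_id = 2, code = 3)), 0)
})

test_that("flexibility index matches hand-worked values and invariances", {
  cmb <- utils::combn(2, 2)
  # constant labels -> 0; alternating -> 1
  lab_const <- matrix(1L, 10, 1)
  dtc <- toy_tensor(lab_const, lab_const, channel_names = c("a", "b"),
                    pairs = data.frame(a = 1, b = 2))
  expect_equal(flexibility(dtc)$fi_global, 0)
  est_alt <- matrix(rep(c(1L, 2L), 5), 10, 1)
  dta <- toy_tensor(est_alt, matrix(1L, 10, 1), channel_names = c("a", "b"),
                    pairs = data.frame(a = 1, b = 2))
  expect_equal(flexibility(dta)$fi_global, 1)
  # T = 3, 2 pairs, one change in one pair -> (1 + 0) / (2 * 2) = 0.25
  est3 <- cbind(c(1L, 1L, 2L), c(1L, 1L, 1L))
  dt3 <- toy_tensor(est3, matrix(1L, 3, 2), channel_names = c("a", "b", "c"),
                    pairs = data.frame(a = c(1, 1), b = c(2, 3)))
  expect_equal(flexibility(dt3)$fi_global, 0.25)
  # invariant to relabelling (depends only on change/no-change)
  est3b <- cbind(c(5L, 5L, 3L), c(2L, 2L, 2L))
  dt3b <- toy_tensor(est3b, matrix(2L, 3, 2), channel_names = c("a", "b", "c"),
                     pairs = data.frame(a = c(1, 1), b = c(2, 3)))
  expect_equal(flexibility(dt3b)$fi_global, 0.25)
  # transitions into/out of no-coupling count as changes
  est0 <- matrix(c(1L, 0L, 1L), 3, 1)
  dt0 <- toy_tensor(est0, est0, channel_names = c("a", "b"),
                    pairs = data.frame(a = 1, b = 2))
  expect_equal(flexibility(dt0)$fi_global, 1)
  expect_error(flexibility(toy_tensor(matrix(1L, 1, 1), matrix(1L, 1, 1),
                                      channel_names = c("a", "b"),
                                      pairs = data.frame(a = 1, b = 2))),
               "2 windows")
})

test_that("feature vectors have 12 MSS + 10 FO entries; empty tensor is flagged", {
  lay <- toy_layout()
  dt <- toy_tensor(matrix(0L, 5, 6), matrix(0L, 5, 6))
  fv <- feature_vector(dt, lay)
  expect_length(fv, 22L)
  expect_equal(sum(startsWith(names(fv), "MSS")), 12L)
  expect_equal(sum(startsWith(names(fv), "FO")), 10L)
  expect_true(all(fv == 0))
  expect_true(all(attr(fv, "flags")))
})

test_that("a planted frontal cross-hemispheric delta AEC mode lands in row 1", {
  lay <- toy_layout()
  rec <- gen_recording(4, 150, 8,
                       plan = plan_entry(c(1, 2), "aec", "delta",
                                         strength = 0.95),
                       seed = 5)
  dt <- run_dicm(rec, estimators = "aec", n_surr = 200, seed = 6)
  fv <- feature_vector(dt, lay)
  expect_gt(fv[["MSS1"]], 0.3)
  expect_gte(fv[["FO1"]], 0.5)
  expect_true(all(fv[setdiff(names(fv), c("MSS1", "FO1"))] == 0))
})
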