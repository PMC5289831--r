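# Synthetic-data generation and the simulation studies.

test_that("control pool generation respects rates, size and determinism", {
  p0 <- gen_control(c(0, 1, 0.5), weeks = 10, per_sex_per_week = 7, seed = 3)
  expect_equal(dim(p0$male), c(70, 3))
  expect_true(all(p0$male[, 1] == 0) && all(p0$female[, 1] == 0))
  expect_true(all(p0$male[, 2] == 1) && all(p0$female[, 2] == 1))
  # identical seed, identical pool
  p1 <- gen_control(c(0, 1, 0.5), weeks = 10, per_sex_per_week = 7, seed = 3)
  expect_identical(p0$male, p1$male)
  # 0.05 over 728 animals: count within the binomial 99.9% interval
  p2 <- gen_control(0.05, weeks = 104, seed = 9)
  bounds <- qbinom(c(0.0005, 0.9995), 728, 0.05)
  expect_gte(sum(p2$male), bounds[1]); expect_lte(sum(p2$male), bounds[2])
  expect_error(gen_control(1.2, seed = 1), "\\[0, 1\\]")
  expect_error(gen_control(0.1, seed = NULL), "seed")
})

test_that("null resampling is deterministic and never rejects impossible traits", {
  pool <- gen_control(c(0, 0.002, 0.02), weeks = 30, seed = 17)
  r1 <- resample_null_t1e(pool, iterations = 50,
                          methods = c("MH_mid", "FE", "LR_KO"), seed = 21)
  r2 <- resample_null_t1e(pool, iterations = 50,
                          methods = c("MH_mid", "FE", "LR_KO"), seed = 21)
  expect_identical(r1, r2)
  # a trait with rate zero can never produce a rejection
  zero_rows <- r1[r1$trait == "1", ]
  expect_true(all(zero_rows$fraction == 0))
  expect_true(all(r1$fraction >= 0 & r1$fraction <= 1))
  expect_true(all(abs(r1$se - sqrt(r1$fraction * (1 - r1$fraction) / r1$iterations)) < 1e-12))
  expect_error(resample_null_t1e(pool, n_ko_per_sex = 300, iterations = 5, seed = 1),
               "pool")
})

test_that("stage-2 error-rate table is well formed and filtering matters little for huge effects", {
  r <- stage2_t1e_sim(effects = c(0, 0.9), thresholds = 0.05,
                      stage1_filters = c(NA, 0.05), iterations = 300,
                      weeks = 30, seed = 31)
  expect_true(all(r$fraction >= 0 & r$fraction <= 1))
  big <- r[r$effect == 0.9, ]
  # with a huge genotype effect nearly every iteration passes stage 1,
  # so filtering barely changes the stage-2 rejection fraction
  expect_lt(abs(big$fraction[big$stage1_filter == "none"] -
                big$fraction[big$stage1_filter != "none"]), 0.02)
  # the stage-2 null holds throughout (same effect in both sexes)
  expect_true(all(r$fraction[r$stage1_filter == "none"] <= 0.05 + 3 * pmax(r$se, 0.01)))
  r2 <- stage2_t1e_sim(effects = c(0, 0.9), thresholds = 0.05,
                       stage1_filters = c(NA, 0.05), iterations = 300,
                       weeks = 30, seed = 31)
  expect_identical(r, r2)
})

test_that("power grids reproduce the paired method orderings", {
  r <- power_sim(baselines = 0.025, mains = c(0.1, 0.3), interactions = 0,
                 iterations = 250, stage1_methods = c("FE", "FE_mid", "MH_mid"),
                 stage2_methods = "LR_KO", weeks = 30, seed = 41)
  for (mn in c(0.1, 0.3)) {
    cell <- r[r$main_effect == mn & r$stage == 1, ]
    fe <- cell$power[cell$method == "FE"]
    femid <- cell$power[cell$method == "FE_mid"]
    # mid-P dominance holds pathwise on shared draws
    expect_gte(femid, fe)
  }
  # power increases with the main effect (2 MC SEs of slack)
  for (m in c("FE", "FE_mid", "MH_mid")) {
    p1 <- r[r$method == m & r$main_effect == 0.1, ]
    p3 <- r[r$method == m & r$main_effect == 0.3, ]
    expect_gte(p3$power, p1$power - 2 * sqrt(p1$se^2 + p3$se^2))
  }
  # stage-2 power with the stage-1 filter can only lose iterations
  s2 <- r[r$stage == 2, ]
  for (mn in c(0.1, 0.3)) {
    cc <- s2[s2$main_effect == mn, ]
    expect_lte(cc$power[cc$filtered], cc$power[!cc$filtered])
  }
  # with zero baseline all stage-1 methods coincide within Monte-Carlo error
  # (full-size control pool: every method then rejects iff any abnormal occurs)
  r0 <- power_sim(baselines = 0, mains = 0.3, interactions = 0,
                  iterations = 250, stage1_methods = c("FE", "FE_mid", "MH_mid", "LR_G"),
                  stage2_methods = character(0), weeks = 104, seed = 43)
  pw <- r0$power
  expect_lt(max(pw) - min(pw), 4 * max(r0$se) + 1e-9)
})
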