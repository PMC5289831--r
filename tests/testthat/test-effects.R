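# Wilson and Newcombe effect-size intervals.

test_that("Wilson interval matches the closed forms and mirror symmetry", {
  z2 <- qnorm(0.975)^2
  w <- wilson_ci(0, 7)
  expect_equal(unname(w["lower"]), 0)
  expect_equal(unname(w["upper"]), z2 / (7 + z2), tolerance = 1e-10)
  w7 <- wilson_ci(7, 7)
  expect_equal(unname(w7["upper"]), 1)
  # mirror: interval for (k, n) reflects interval for (n-k, n) about 1/2
  for (k in 0:10) {
    a <- wilson_ci(k, 10); b <- wilson_ci(10 - k, 10)
    expect_equal(unname(a["lower"]), 1 - unname(b["upper"]), tolerance = 1e-12)
  }
  expect_error(wilson_ci(2, 0), "at least 1")
  expect_error(wilson_ci(5, 3), "\\[0, n\\]")
})

test_that("Newcombe method-10 interval composes the Wilson bounds", {
  # identical groups: zero estimate, symmetric interval
  e <- newcombe_diff_ci(2, 9, 2, 9)
  expect_equal(e$estimate, 0)
  expect_equal(e$lower, -e$upper, tolerance = 1e-12)
  # 7/7 vs 0/7: compose the boundary closed forms
  w1 <- wilson_ci(7, 7); w2 <- wilson_ci(0, 7)
  e2 <- newcombe_diff_ci(7, 7, 0, 7)
  expect_equal(e2$estimate, 1)
  expect_equal(e2$lower, 1 - sqrt((1 - w1["lower"])^2 + w2["upper"]^2),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(e2$upper, 1)
  # bounds stay inside [-1, 1] across count edge cases
  for (k1 in c(0, 3, 7)) for (k2 in c(0, 5)) {
    ee <- newcombe_diff_ci(k1, 7, k2, 5)
    expect_true(ee$lower >= -1 && ee$upper <= 1)
    expect_true(ee$lower <= ee$estimate && ee$estimate <= ee$upper)
    expect_true(is.finite(ee$lower) && is.finite(ee$upper))
  }
  expect_error(newcombe_diff_ci(0, 0, 1, 5), "non-empty")
})

test_that("Newcombe interval covers the true difference at near-nominal rate", {
  set.seed(77)
  n <- 50; reps <- 2000
  for (pp in list(c(0.05, 0.05), c(0.3, 0.05), c(0.3, 0.3))) {
    k1 <- rbinom(reps, n, pp[1]); k2 <- rbinom(reps, n, pp[2])
    cover <- vapply(seq_len(reps), function(i) {
      e <- newcombe_diff_ci(k1[i], n, k2[i], n)
      e$lower <= pp[1] - pp[2] && pp[1] - pp[2] <= e$upper
    }, logical(1))
    expect_gte(mean(cover), 0.93)
  }
})

test_that("sex-averaged and knockout sex-difference effects follow their constructions", {
  d <- make_dataset(c(4, 10), c(0, 10), c(2, 10), c(0, 10))
  em <- newcombe_diff_ci(4, 10, 0, 10); ef <- newcombe_diff_ci(2, 10, 0, 10)
  avg <- sex_averaged_effect(d)
  expect_equal(avg$estimate, (em$estimate + ef$estimate) / 2)  # (0.4 + 0.2)/2
  expect_equal(avg$estimate, 0.3)
  expect_equal(avg$lower, min(em$lower, ef$lower))
  expect_equal(avg$upper, max(em$upper, ef$upper))
  # identical tables collapse to the common per-sex estimate
  di <- make_dataset(c(3, 7), c(1, 20), c(3, 7), c(1, 20))
  ei <- sex_averaged_effect(di); e1 <- newcombe_diff_ci(3, 7, 1, 20)
  expect_equal(ei$estimate, e1$estimate)
  expect_equal(ei$lower, e1$lower)
  # knockout sex difference: antisymmetric under sex swap
  kd <- ko_sex_difference(d)
  expect_equal(kd$estimate, 0.2)
  dsw <- sex_counts(male = d$female, female = d$male)
  expect_equal(ko_sex_difference(dsw)$estimate, -kd$estimate)
  # fallback when one sex is absent
  d1 <- make_dataset(c(4, 10), c(0, 10), c(0, 0), c(0, 0))
  expect_warning(ef1 <- sex_averaged_effect(d1), "one sex")
  expect_equal(ef1$estimate, em$estimate)
})
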