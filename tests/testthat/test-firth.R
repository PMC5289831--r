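# Firth bias-reduced logistic regression and the penalized LRT engine.

test_that("Firth fit matches the add-half closed form on saturated designs", {
  # one binary covariate: slope equals the 2x2 log-odds ratio after adding
  # 1/2 to every cell, including under complete separation
  cases <- list(c(3, 7, 1, 7), c(7, 7, 0, 7), c(0, 5, 0, 9), c(4, 12, 2, 6))
  for (cs in cases) {
    k1 <- cs[1]; n1 <- cs[2]; k0 <- cs[3]; n0 <- cs[4]
    f <- firth_fit(cbind(1, c(1, 0)), events = c(k1, k0), trials = c(n1, n0))
    closed <- log((k1 + 0.5) * (n0 - k0 + 0.5) / ((n1 - k1 + 0.5) * (k0 + 0.5)))
    expect_true(f$converged)
    expect_equal(unname(f$coefficients[2]), closed, tolerance = 1e-6)
    expect_true(all(is.finite(f$coefficients)))
  }
  # intercept-only: fitted probability is (k + 1/2) / (n + 1)
  for (k in c(0, 3, 7)) {
    f <- firth_fit(matrix(1, 7, 1), events = rep(0, 7) + c(rep(1, k), rep(0, 7 - k)))
    expect_equal(f$fitted[1], (k + 0.5) / 8, tolerance = 1e-8)
  }
})

test_that("penalized optimum agrees with a generic optimizer", {
  # small table: per sex WT 1/20, KO 4/7 (and an asymmetric variant)
  X <- cbind(1, c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0))
  for (kk in list(c(4, 4, 1, 1), c(4, 1, 1, 0), c(7, 0, 0, 2))) {
    k <- kk; n <- c(7, 7, 20, 20)
    full <- firth_fit(X, k, n)
    expect_equal(full$penalized_loglik, oracle_pll_max(X, k, n),
                 tolerance = 1e-6)
    null_g <- firth_fit(X, k, n, fixed_zero = c(3L, 4L))
    expect_equal(null_g$penalized_loglik, oracle_pll_max(X, k, n, c(3L, 4L)),
                 tolerance = 1e-6)
    d <- make_dataset(c(k[1], 7), c(k[3], 20), c(k[2], 7), c(k[4], 20))
    p_oracle <- pchisq(2 * (oracle_pll_max(X, k, n) -
                            oracle_pll_max(X, k, n, c(3L, 4L))),
                       2, lower.tail = FALSE)
    expect_equal(lr_g(d)$p.value, p_oracle, tolerance = 1e-5)
    p_oracle_i <- pchisq(max(0, 2 * (oracle_pll_max(X, k, n) -
                                     oracle_pll_max(X, k, n, 4L))),
                         1, lower.tail = FALSE)
    expect_equal(lr_i(d)$p.value, p_oracle_i, tolerance = 1e-5)
  }
})

test_that("singular designs error and separation stays finite", {
  X <- cbind(1, c(1, 0, 1, 0), c(1, 0, 1, 0))  # duplicated column
  expect_error(firth_fit(X, c(1, 0, 1, 0)), "singular|rank")
  # complete separation: all KO abnormal, no WT abnormal
  d <- make_dataset(c(7, 7), c(0, 721), c(7, 7), c(0, 721))
  r <- lr_g(d)
  expect_true(is.finite(r$statistic))
  expect_gt(r$p.value, 0)
  expect_lt(r$p.value, 1)
  expect_true(all(is.finite(coef(r$fit_full))))
})

test_that("LRT is invariant to sex relabeling and degenerate data give p = 1", {
  for (k in 1:7) {
    pm <- lr_ko(make_dataset(c(k, 7), c(0, 10), c(0, 7), c(0, 10)))$p.value
    pf <- lr_ko(make_dataset(c(0, 7), c(0, 10), c(k, 7), c(0, 10)))$p.value
    expect_equal(pm, pf, tolerance = 1e-9)
  }
  # strictly decreasing in the abnormal count
  p <- vapply(1:7, function(k)
    lr_ko(make_dataset(c(k, 7), c(0, 10), c(0, 7), c(0, 10)))$p.value, numeric(1))
  expect_true(all(diff(p) < 0))
  # no information about genotype: all cells zero events (balanced groups,
  # where the penalty shrinks every cell identically)
  d0 <- make_dataset(c(0, 7), c(0, 7), c(0, 7), c(0, 7))
  expect_equal(lr_g(d0)$p.value, 1, tolerance = 1e-6)
  # identical per-sex tables: no heterogeneity signal
  di <- make_dataset(c(3, 7), c(1, 20), c(3, 7), c(1, 20))
  expect_equal(lr_i(di)$p.value, 1, tolerance = 1e-3)
  expect_equal(lr_ko(di)$p.value, 1, tolerance = 1e-3)
  # missing knockout sex is untestable at stage 2
  expect_error(lr_ko(make_dataset(c(0, 0), c(0, 10), c(1, 7), c(0, 10))),
               "both sexes")
})

test_that("single-sex input degrades to a genotype-only test with warning", {
  d <- make_dataset(c(4, 7), c(1, 20), c(0, 0), c(0, 0))
  expect_warning(r <- lr_g(d), "one sex")
  expect_equal(unname(r$parameter), 1)
  # equals the direct two-row genotype LRT
  direct <- penalized_lrt(cbind(1, c(1, 0)), c(4, 1), c(7, 20), tested = 2L)
  expect_equal(r$p.value, direct$p.value, tolerance = 1e-9)
})

test_that("firth_glm model object behaves like a classed fit", {
  set.seed(42)
  df <- data.frame(y = rbinom(40, 1, 0.3), x = rnorm(40))
  f <- firth_glm(y ~ x, data = df)
  expect_s3_class(f, "firth_glm")
  expect_named(coef(f), c("(Intercept)", "x"))
  expect_equal(dim(vcov(f)), c(2, 2))
  expect_equal(length(predict(f, type = "response")), 40)
  expect_true(all(predict(f, type = "response") > 0 &
                  predict(f, type = "response") < 1))
  expect_equal(predict(f, newdata = df[1:3, ]),
               predict(f)[1:3], ignore_attr = TRUE)
  s <- summary(f)
  expect_s3_class(s, "summary.firth_glm")
  expect_equal(nrow(s$coefficients), 2)
  expect_equal(length(residuals(f)), 40)
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(40, 2))
  expect_output(print(f), "Firth")
})

test_that("batch screen detects strong batch effects and flags degenerate traits", {
  set.seed(7)
  mk <- function(trait, batch, n, rate)
    data.frame(trait_id = trait, sex = rep(c("M", "F"), n / 2),
               batch = batch, outcome = rbinom(n, 1, rate))
  rec <- rbind(mk("batchy", "b1", 100, 0.01), mk("batchy", "b2", 100, 0.5),
               mk("nullish", "b1", 100, 0.1), mk("nullish", "b2", 100, 0.1),
               mk("empty", "b1", 100, 0), mk("empty", "b2", 100, 0))
  r <- batch_screen(rec)
  expect_true(r$batch_effect[r$trait_id == "batchy"])
  expect_true(r$q[r$trait_id == "batchy"] <= 0.05)
  expect_false(r$batch_effect[r$trait_id == "nullish"])
  expect_equal(r$p[r$trait_id == "empty"], 1)
  expect_true(r$uninformative[r$trait_id == "empty"])
  expect_error(batch_screen(rec[rec$batch == "b1", ]), "two batches")
})
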