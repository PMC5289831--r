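# Exact conditional tests and their mid-P variants, pinned by enumeration
# oracles and checked against the stated degenerate-table conventions.

test_that("one-sided Fisher matches hand enumeration and handles degeneracy", {
  # 2/7 vs 0/7: p = C(12,5)/C(14,7)
  t <- two_by_two(2, 7, 0, 7)
  expect_equal(fisher_one_sided(t)$p.value, choose(12, 5) / choose(14, 7),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(t, mid = TRUE)$p.value,
               choose(12, 5) / choose(14, 7) / 2, tolerance = 1e-12)
  # degenerate conditional law
  expect_equal(fisher_one_sided(two_by_two(0, 7, 0, 7))$p.value, 1)
  expect_equal(fisher_one_sided(two_by_two(0, 7, 0, 7), mid = TRUE)$p.value, 0.5)
  expect_equal(fisher_one_sided(two_by_two(5, 5, 7, 7))$p.value, 1)
  # random tables: agreement with the oracle; mid strictly below standard
  set.seed(11)
  for (i in 1:60) {
    n <- sample.int(12, 2, replace = TRUE)
    k <- c(sample.int(n[1] + 1, 1) - 1, sample.int(n[2] + 1, 1) - 1)
    ps <- fisher_one_sided(two_by_two(k[1], n[1], k[2], n[2]))$p.value
    pm <- fisher_one_sided(two_by_two(k[1], n[1], k[2], n[2]), mid = TRUE)$p.value
    expect_equal(ps, oracle_fisher_p(k[1], n[1], k[2], n[2]), tolerance = 1e-10)
    expect_equal(pm, oracle_fisher_p(k[1], n[1], k[2], n[2], mid = TRUE),
                 tolerance = 1e-10)
    expect_lt(pm, ps)       # point probability is always positive on the support
    expect_gt(pm, 0); expect_lte(ps, 1)
    # cross-check against the reference implementation
    m <- matrix(c(k[1], n[1] - k[1], k[2], n[2] - k[2]), 2, byrow = TRUE)
    expect_equal(ps, fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_error(two_by_two(3, 2, 0, 7), "exceed")
})

test_that("stage-1 doubled-minimum Fisher follows the spec'd composition", {
  d <- make_dataset(c(2, 7), c(0, 7), c(0, 7), c(0, 7))
  expect_equal(fe_stage1(d, mid = TRUE)$p.value, 2 * choose(12, 5) / choose(14, 7) / 2,
               tolerance = 1e-12)
  # both strata degenerate: cap at 1
  d0 <- make_dataset(c(0, 7), c(0, 7), c(0, 7), c(0, 7))
  expect_equal(fe_stage1(d0)$p.value, 1)
  # identical strata: twice the common p, capped
  ds <- make_dataset(c(3, 7), c(1, 10), c(3, 7), c(1, 10))
  common <- fisher_one_sided(two_by_two(3, 7, 1, 10))$p.value
  expect_equal(fe_stage1(ds)$p.value, min(1, 2 * common), tolerance = 1e-12)
  # absent sex: present sex's p unmultiplied, with warning
  d1 <- make_dataset(c(2, 7), c(0, 7), c(0, 0), c(0, 0))
  expect_warning(p1 <- fe_stage1(d1, mid = TRUE)$p.value, "one sex")
  expect_equal(p1, choose(12, 5) / choose(14, 7) / 2, tolerance = 1e-12)
})

test_that("exact stratified MH agrees with enumeration and collapses to Fisher", {
  set.seed(22)
  for (i in 1:40) {
    d <- random_dataset(10)
    for (mid in c(TRUE, FALSE)) {
      p <- mh_exact_mid(d, mid = mid)$p.value
      po <- oracle_mh_p(d$male$events_a, d$male$total_a,
                        d$male$events_b, d$male$total_b,
                        d$female$events_a, d$female$total_a,
                        d$female$events_b, d$female$total_b, mid = mid)
      expect_equal(p, po, tolerance = 1e-10)
    }
    # symmetric under exchanging the strata
    dsw <- sex_counts(male = d$female, female = d$male)
    expect_equal(mh_exact_mid(d)$p.value, mh_exact_mid(dsw)$p.value,
                 tolerance = 1e-12)
    # cross-check the standard-P variant against the reference implementation
    arr <- array(c(d$male$events_a, d$male$events_b,
                   d$male$total_a - d$male$events_a,
                   d$male$total_b - d$male$events_b,
                   d$female$events_a, d$female$events_b,
                   d$female$total_a - d$female$events_a,
                   d$female$total_b - d$female$events_b), dim = c(2, 2, 2))
    ref <- tryCatch(mantelhaen.test(arr, exact = TRUE,
                                    alternative = "greater")$p.value,
                    error = function(e) NA_real_)   # degenerate strata
    if (!is.na(ref))
      expect_equal(mh_exact_mid(d, mid = FALSE)$p.value, ref, tolerance = 1e-9)
  }
  # one informative stratum: equals that stratum's Fisher test
  d1 <- make_dataset(c(3, 7), c(1, 9), c(0, 5), c(0, 5))
  expect_equal(mh_exact_mid(d1, mid = TRUE)$p.value,
               fisher_one_sided(two_by_two(3, 7, 1, 9), mid = TRUE)$p.value,
               tolerance = 1e-12)
  # both strata degenerate
  d0 <- make_dataset(c(0, 7), c(0, 7), c(0, 7), c(0, 7))
  expect_equal(mh_exact_mid(d0, mid = TRUE)$p.value, 0.5)
  expect_equal(mh_exact_mid(d0, mid = FALSE)$p.value, 1)
})

test_that("Zelen homogeneity test matches the doubly conditional enumeration", {
  # no events to apportion
  expect_equal(zelen_mid(make_dataset(c(0, 7), c(0, 7), c(0, 7), c(0, 7)))$p.value, 1)
  # identical strata with the observed count modal: standard p is 1
  di <- make_dataset(c(2, 7), c(1, 10), c(2, 7), c(1, 10))
  expect_equal(zelen_mid(di, mid = FALSE)$p.value, 1, tolerance = 1e-12)
  set.seed(33)
  for (i in 1:40) {
    d <- random_dataset(10)
    for (mid in c(TRUE, FALSE)) {
      expect_equal(zelen_mid(d, mid = mid)$p.value,
                   oracle_zelen_p(d$male$events_a, d$male$total_a,
                                  d$male$events_b, d$male$total_b,
                                  d$female$events_a, d$female$total_a,
                                  d$female$events_b, d$female$total_b, mid = mid),
                   tolerance = 1e-10)
    }
  }
})

test_that("knockout-only Fisher matches enumeration and conventions", {
  # equal cohorts, equal abnormal counts: the observed outcome is modal
  de <- make_dataset(c(3, 7), c(0, 10), c(3, 7), c(0, 10))
  expect_equal(fe_ko(de, mid = FALSE)$p.value, 1, tolerance = 1e-12)
  expect_lt(fe_ko(de, mid = TRUE)$p.value, 1)
  # complete penetrance in one sex
  d7 <- make_dataset(c(7, 7), c(0, 10), c(0, 7), c(0, 10))
  expect_equal(fe_ko(d7)$p.value, oracle_fe_ko_p(7, 7, 0, 7), tolerance = 1e-12)
  # no abnormalities at all
  expect_equal(fe_ko(make_dataset(c(0, 7), c(0, 10), c(0, 7), c(0, 10)))$p.value, 1)
  set.seed(44)
  for (i in 1:40) {
    n <- sample.int(12, 2, replace = TRUE)
    k <- c(sample.int(n[1] + 1, 1) - 1, sample.int(n[2] + 1, 1) - 1)
    d <- make_dataset(c(k[1], n[1]), c(0, 5), c(k[2], n[2]), c(0, 5))
    for (mid in c(TRUE, FALSE))
      expect_equal(fe_ko(d, mid = mid)$p.value,
                   oracle_fe_ko_p(k[1], n[1], k[2], n[2], mid = mid),
                   tolerance = 1e-10)
  }
  expect_error(fe_ko(make_dataset(c(0, 0), c(0, 5), c(1, 7), c(0, 5))),
               "both sexes")
})

test_that("conditional laws are proper and the standard tests super-uniform", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample.int(12, 4, replace = TRUE)
    k <- vapply(n, function(nn) sample.int(nn + 1L, 1L) - 1L, integer(1))
    law_m <- phenodim:::.hyper_law(k[1] + k[2], n[1], n[2])
    law <- phenodim:::.conv_law(law_m, phenodim:::.hyper_law(k[3] + k[4], n[3], n[4]))
    expect_lt(abs(sum(law_m$pmf) - 1), 1e-12)
    expect_lt(abs(sum(law$pmf) - 1), 1e-12)
    # exact super-uniformity at alpha = 0.05: P(p <= alpha) <= alpha
    for (l in list(law_m, law)) {
      pvals <- rev(cumsum(rev(l$pmf)))          # upper-tail p at each support point
      expect_lte(sum(l$pmf[pvals <= 0.05]), 0.05 + 1e-12)
    }
  }
})
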