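# Exact conditional tests for rare-event 2x2 and sex-stratified tables,
# with optional mid-P correction. All tests condition on the table margins,
# so the null laws are (products/convolutions of) central hypergeometric
# distributions; probabilities come from stats::dhyper and tails are
# accumulated from the smaller terms for numerical stability.

# law of the group-a event count conditional on margins:
# n_events abnormal among n_a + n_b animals, n_a of them in group a
.hyper_law <- function(n_events, n_a, n_b) {
  supp <- max(0L, n_events - n_b):min(n_events, n_a)
  list(supp = supp,
       pmf = stats::dhyper(supp, n_events, n_a + n_b - n_events, n_a))
}

# convolution of two stratum laws: law of the total group-a event count
.conv_law <- function(l1, l2) {
  t <- outer(l1$supp, l2$supp, `+`)
  p <- outer(l1$pmf, l2$pmf)
  supp <- sort(unique(as.vector(t)))
  pmf <- vapply(supp, function(v) sum(p[t == v]), numeric(1))
  list(supp = supp, pmf = pmf)
}

# upper-tail (one-sided toward large T) p-value on a discrete law;
# degenerate support -> standard 1, mid 0.5
.upper_tail_p <- function(law, t_obs, mid) {
  if (length(law$supp) == 1L) return(if (mid) 0.5 else 1)
  i <- match(t_obs, law$supp)
  if (is.na(i)) stop("observed value outside conditional support", call. = FALSE)
  tail <- law$pmf[law$supp >= t_obs]
  p <- sum(sort(tail))                      # accumulate small terms first
  if (mid) p <- p - 0.5 * law$pmf[i]
  min(max(p, .Machine$double.xmin), 1)
}

.htest <- function(p, method, dname, stat = NULL, df = NULL) {
  out <- list(p.value = p, method = method, data.name = dname)
  if (!is.null(stat)) out$statistic <- c(statistic = stat)
  if (!is.null(df)) out$parameter <- c(df = df)
  structure(out, class = "htest")
}

#' One-sided Fisher exact test with optional mid-P correction
#'
#' Conditional on the margins of a [two_by_two()] table, the group-a
#' (knockout) event count is hypergeometric; the one-sided p-value is the
#' probability of at least the observed count (alternative: knockout rate
#' greater than wild-type). The mid-P variant replaces the point probability
#' of the observed outcome by half of it, reducing the conservatism exact
#' tests suffer on discrete supports. Degenerate tables (no events, or no
#' room to vary) give p = 1 (standard) or 0.5 (mid).
#'
#' @param t a [two_by_two()] table (group a = knockout).
#' @param mid logical: apply the mid-P correction?
#' @return An `"htest"` result.
#' @examples
#' fisher_one_sided(two_by_two(2, 7, 0, 7))        # 0.2308
#' fisher_one_sided(two_by_two(2, 7, 0, 7), mid = TRUE)  # 0.1154
#' @export
fisher_one_sided <- function(t, mid = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  law <- .hyper_law(t$events_a + t$events_b, t$total_a, t$total_b)
  p <- .upper_tail_p(law, t$events_a, mid)
  .htest(p, sprintf("One-sided Fisher exact test (%s)",
                    if (mid) "mid-P" else "standard P"),
         sprintf("%d/%d vs %d/%d", t$events_a, t$total_a, t$events_b, t$total_b),
         stat = t$events_a)
}

.fisher_p <- function(ea, na, eb, nb, mid) {
  .upper_tail_p(.hyper_law(ea + eb, na, nb), ea, mid)
}

#' Stage-1 per-sex Fisher test (FE / FE_mid)
#'
#' Runs [fisher_one_sided()] separately in each sex and returns twice the
#' smaller of the two p-values (Bonferroni over the two sexes), capped at 1.
#' `mid = FALSE` is the FE method; `mid = TRUE` the FE_mid method. If one
#' sex stratum is absent, the present sex's p-value is returned unmultiplied
#' with a warning.
#'
#' @param d a [sex_counts()] data set.
#' @param mid logical: use per-sex mid-P values?
#' @return An `"htest"` result.
#' @export
fe_stage1 <- function(d, mid = FALSE) {
  stopifnot(inherits(d, "sex_counts"))
  lab <- sprintf("Sex-wise one-sided Fisher exact test, doubled minimum (%s)",
                 if (mid) "FE_mid" else "FE")
  m_ok <- .stratum_present(d$male); f_ok <- .stratum_present(d$female)
  if (!m_ok || !f_ok) {
    warning("one sex absent; returning the present sex's p-value unmultiplied",
            call. = FALSE)
    t <- if (m_ok) d$male else d$female
    return(.htest(.fisher_p(t$events_a, t$total_a, t$events_b, t$total_b, mid),
                  lab, .dataset_id(d)))
  }
  pm <- .fisher_p(d$male$events_a, d$male$total_a, d$male$events_b, d$male$total_b, mid)
  pf <- .fisher_p(d$female$events_a, d$female$total_a, d$female$events_b, d$female$total_b, mid)
  .htest(min(1, 2 * min(pm, pf)), lab, .dataset_id(d))
}

.fe_stage1_p <- function(km_ko, nm_ko, km_wt, nm_wt, kf_ko, nf_ko, kf_wt, nf_wt, mid) {
  min(1, 2 * min(.fisher_p(km_ko, nm_ko, km_wt, nm_wt, mid),
                 .fisher_p(kf_ko, nf_ko, kf_wt, nf_wt, mid)))
}

#' Exact one-sided stratified Cochran-Mantel-Haenszel test (MH / MH_mid)
#'
#' Tests for a higher abnormality rate in knockouts than wild-types,
#' aggregating over the two sex strata. Conditional on all margins, the
#' total knockout event count is the convolution of the two per-stratum
#' hypergeometric laws; the p-value is the upper tail at the observed total
#' (`mid = TRUE` gives the MH_mid variant). A stratum with a degenerate
#' conditional law contributes a point mass, so the test then reduces to
#' the other stratum's Fisher test.
#'
#' @inheritParams fe_stage1
#' @param mid logical: mid-P correction (the MH_mid method, default).
#' @return An `"htest"` result.
#' @export
mh_exact_mid <- function(d, mid = TRUE) {
  stopifnot(inherits(d, "sex_counts"))
  law <- .mh_law(d)
  t_obs <- d$male$events_a + d$female$events_a
  p <- .upper_tail_p(law, t_obs, mid)
  .htest(p, sprintf("Exact one-sided Cochran-Mantel-Haenszel test, sex-stratified (%s)",
                    if (mid) "MH_mid" else "MH"),
         .dataset_id(d), stat = t_obs)
}

.mh_law <- function(d) {
  .conv_law(.hyper_law(d$male$events_a + d$male$events_b,
                       d$male$total_a, d$male$total_b),
            .hyper_law(d$female$events_a + d$female$events_b,
                       d$female$total_a, d$female$total_b))
}

.mh_p <- function(km_ko, nm_ko, km_wt, nm_wt, kf_ko, nf_ko, kf_wt, nf_wt, mid) {
  law <- .conv_law(.hyper_law(km_ko + km_wt, nm_ko, nm_wt),
                   .hyper_law(kf_ko + kf_wt, nf_ko, nf_wt))
  .upper_tail_p(law, km_ko + kf_ko, mid)
}

#' Zelen exact test of odds-ratio homogeneity across sexes (mid-P)
#'
#' Conditional on all margins and on the total knockout event count, the
#' male knockout event count has a law proportional to the product of the
#' two per-stratum hypergeometric weights. The two-sided p-value sums the
#' probabilities of all outcomes no more probable than the observed one
#' (ties included within relative tolerance 1e-10); the mid variant
#' subtracts half the observed outcome's probability. A conditional support
#' of size one (in particular zero total events) gives p = 1.
#'
#' @inheritParams fe_stage1
#' @param mid logical: mid-P correction (default TRUE).
#' @return An `"htest"` result.
#' @export
zelen_mid <- function(d, mid = TRUE) {
  stopifnot(inherits(d, "sex_counts"))
  p <- .zelen_p(d$male$events_a, d$male$total_a, d$male$events_b, d$male$total_b,
                d$female$events_a, d$female$total_a, d$female$events_b,
                d$female$total_b, mid)
  .htest(p, sprintf("Zelen exact test of odds-ratio homogeneity (%s)",
                    if (mid) "mid-P" else "standard P"), .dataset_id(d))
}

.zelen_p <- function(km_ko, nm_ko, km_wt, nm_wt, kf_ko, nf_ko, kf_wt, nf_wt,
                     mid = TRUE) {
  lm <- .hyper_law(km_ko + km_wt, nm_ko, nm_wt)
  lf <- .hyper_law(kf_ko + kf_wt, nf_ko, nf_wt)
  T <- km_ko + kf_ko
  a1 <- lm$supp[lm$supp >= T - max(lf$supp) & lm$supp <= T - min(lf$supp)]
  if (length(a1) <= 1L) return(1)
  f <- lm$pmf[match(a1, lm$supp)] * lf$pmf[match(T - a1, lf$supp)]
  f_obs <- f[match(km_ko, a1)]
  p <- sum(sort(f[f <= f_obs * (1 + 1e-10)])) / sum(sort(f))
  if (mid) p <- p - 0.5 * f_obs / sum(sort(f))
  min(max(p, .Machine$double.xmin), 1)
}

#' Knockout-only two-sided Fisher exact test across sexes (FE_KO)
#'
#' Conditional on the knockout margins (animals per sex, total abnormal),
#' the male abnormal count is hypergeometric. The two-sided p-value uses
#' the point-probability method: the sum of probabilities of all outcomes
#' no more probable than the observed one; the mid variant (default)
#' subtracts half the observed outcome's probability. A support of size one
#' (in particular zero abnormalities) gives p = 1.
#'
#' @inheritParams fe_stage1
#' @param mid logical: mid-P correction (default TRUE).
#' @return An `"htest"` result.
#' @export
fe_ko <- function(d, mid = TRUE) {
  stopifnot(inherits(d, "sex_counts"))
  if (d$male$total_a == 0L || d$female$total_a == 0L)
    stop("knockout animals required in both sexes for FE_KO", call. = FALSE)
  p <- .fe_ko_p(d$male$events_a, d$male$total_a,
                d$female$events_a, d$female$total_a, mid)
  .htest(p, sprintf("Knockout-only two-sided Fisher exact test across sexes (%s)",
                    if (mid) "FE_KO mid-P" else "FE_KO standard P"),
         .dataset_id(d))
}

.fe_ko_p <- function(km, nm, kf, nf, mid = TRUE) {
  law <- .hyper_law(km + kf, nm, nf)
  if (length(law$supp) <= 1L) return(1)
  f_obs <- law$pmf[match(km, law$supp)]
  p <- sum(sort(law$pmf[law$pmf <= f_obs * (1 + 1e-10)]))
  if (mid) p <- p - 0.5 * f_obs
  min(max(p, .Machine$double.xmin), 1)
}
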