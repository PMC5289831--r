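# Minimum attainable p-values ("alpha star") given fixed margins, and the
# attainability filters built on them. Because the tests are discrete and
# conditional, the smallest p-value a data set can produce is a function of
# its margins only; hypotheses whose alpha star exceeds the working
# significance level can never be rejected and are removed BEFORE testing,
# which shrinks the multiplicity burden without touching observed outcomes.

#' Minimum attainable p-value of the stratified MH test
#'
#' The smallest (mid-)p-value [mh_exact_mid()] can attain on any table with
#' the observed margins: the upper-tail p at the largest attainable total
#' knockout event count (all events allocated to knockouts up to per-stratum
#' capacity). Degenerate margins give 0.5 (mid) / 1 (standard).
#'
#' @param d a [sex_counts()] data set.
#' @param mid logical: same variant as the test that will be run.
#' @return A single probability.
#' @export
mh_alpha_star <- function(d, mid = TRUE) {
  stopifnot(inherits(d, "sex_counts"))
  law <- .mh_law(d)
  .upper_tail_p(law, max(law$supp), mid)
}

.mh_alpha_star_counts <- function(km_ko, nm_ko, km_wt, nm_wt,
                                  kf_ko, nf_ko, kf_wt, nf_wt, mid = TRUE) {
  law <- .conv_law(.hyper_law(km_ko + km_wt, nm_ko, nm_wt),
                   .hyper_law(kf_ko + kf_wt, nf_ko, nf_wt))
  .upper_tail_p(law, max(law$supp), mid)
}

#' Minimum attainable p-value of the knockout-only sex test (LR_KO)
#'
#' Enumerates every allocation of `total_abnormal_ko` abnormal animals
#' between the sexes (respecting per-sex capacities) and returns the
#' smallest [lr_ko()] p-value. With equal cohorts the minimum sits at the
#' all-in-one-sex allocation, but the enumeration guards against unequal
#' cohort sizes.
#'
#' @param n_male,n_female knockout animals per sex (both positive).
#' @param total_abnormal_ko total abnormal knockout animals.
#' @param control a [firth_control()] list.
#' @return A single probability.
#' @examples
#' lrko_alpha_star(7, 7, 4)  # 0.02299: 4 abnormalities can reach 5%
#' @export
lrko_alpha_star <- function(n_male, n_female, total_abnormal_ko,
                            control = firth_control()) {
  n_male <- as.integer(n_male); n_female <- as.integer(n_female)
  k <- as.integer(total_abnormal_ko)
  if (n_male < 1L || n_female < 1L)
    stop("knockout animals required in both sexes", call. = FALSE)
  if (k < 0L || k > n_male + n_female)
    stop("total abnormal count exceeds cohort size", call. = FALSE)
  a <- max(0L, k - n_female):min(k, n_male)
  min(vapply(a, function(am)
    .lr_ko_test(am, n_male, k - am, n_female, control)$p.value, numeric(1)))
}

#' Grid of stage-2 minimum attainable p-values
#'
#' Tabulates [lrko_alpha_star()] for every total abnormality count from 0 to
#' the full cohort, with the penetrance each count represents. With 7+7
#' knockouts this is the grid showing that at least 4 abnormalities are
#' needed before the sexual-dimorphism test can reach the 5% level.
#'
#' @inheritParams lrko_alpha_star
#' @return Data frame with columns `penetrance`, `n_male`, `n_female`,
#'   `n_abnormal`, `alpha_star`.
#' @export
alpha_star_grid <- function(n_male = 7, n_female = 7,
                            control = firth_control()) {
  kmax <- max(n_male, n_female)
  k <- seq_len(kmax)
  data.frame(
    penetrance = round(100 * k / kmax, 1),
    n_male = n_male, n_female = n_female, n_abnormal = k,
    alpha_star = vapply(k, function(kk)
      lrko_alpha_star(n_male, n_female, kk, control), numeric(1)))
}

#' Apply attainability filters to alpha-star records
#'
#' Flags which hypotheses can possibly reach significance at each stage.
#' Decisions depend on margins only (never on observed p-values), which is
#' what preserves the validity of downstream FDR control.
#'
#' @param records data frame with columns `alpha_star_stage1` and (optionally)
#'   `alpha_star_stage2`.
#' @param stage1_threshold,stage2_threshold significance thresholds in (0,1).
#' @return `records` with logical columns `pass_stage1_filter` and
#'   `pass_stage2_filter` appended.
#' @export
apply_filters <- function(records, stage1_threshold = 0.05,
                          stage2_threshold = 0.05) {
  stopifnot(stage1_threshold > 0, stage1_threshold <= 1,
            stage2_threshold > 0, stage2_threshold <= 1)
  records$pass_stage1_filter <- records$alpha_star_stage1 < stage1_threshold |
    stage1_threshold == 1
  if (!is.null(records$alpha_star_stage2)) {
    records$pass_stage2_filter <- records$pass_stage1_filter &
      (records$alpha_star_stage2 < stage2_threshold | stage2_threshold == 1)
  }
  records
}
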