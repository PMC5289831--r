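# Effect sizes for rare-event categorical traits: differences in
# abnormality proportions with Newcombe method-10 confidence intervals
# (built from per-group Wilson score intervals). Odds ratios are avoided
# deliberately: with rare events they explode to infinity with no precision.

#' Wilson score interval for a single proportion
#'
#' Without continuity correction. Handles the boundary cases k = 0 and
#' k = n with finite limits (0 and 1 respectively at the data boundary).
#'
#' @param k event count, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

.effect <- function(estimate, lower, upper, level) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 level = level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("Difference in abnormality proportions: %.4f [%g%% CI %.4f, %.4f]\n",
              x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Newcombe method-10 interval for a difference of proportions
#'
#' For d = k1/n1 - k2/n2, combines the per-group Wilson score limits
#' (l1, u1) and (l2, u2) as
#' lower = d - sqrt((p1 - l1)^2 + (u2 - p2)^2),
#' upper = d + sqrt((u1 - p1)^2 + (p2 - l2)^2).
#' Recommended for small and highly unbalanced designs; bounds always lie
#' in \[-1, 1\].
#'
#' @param k1,n1 events/trials in the first group.
#' @param k2,n2 events/trials in the second group.
#' @param level confidence level (default 0.95).
#' @return An `"effect_estimate"` (estimate, lower, upper, level).
#' @export
newcombe_diff_ci <- function(k1, n1, k2, n2, level = 0.95) {
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  w1 <- wilson_ci(k1, n1, level); w2 <- wilson_ci(k2, n2, level)
  d <- p1 - p2
  .effect(d,
          max(-1, d - sqrt((p1 - w1["lower"])^2 + (w2["upper"] - p2)^2)),
          min(1, d + sqrt((w1["upper"] - p1)^2 + (p2 - w2["lower"])^2)),
          level)
}

#' Sex-averaged genotype effect with conservative interval
#'
#' The knockout-minus-wild-type difference in abnormality proportions is
#' estimated per sex with [newcombe_diff_ci()]; the reported estimate is the
#' mean of the two differences and the conservative interval takes the
#' minimum of the two lower bounds and the maximum of the two upper bounds.
#' In the presence of sexual dimorphism this interval is wide by design.
#'
#' @param d a [sex_counts()] data set.
#' @param level confidence level (default 0.95).
#' @return An `"effect_estimate"`.
#' @export
sex_averaged_effect <- function(d, level = 0.95) {
  stopifnot(inherits(d, "sex_counts"))
  m_ok <- .stratum_present(d$male) && d$male$total_a > 0L && d$male$total_b > 0L
  f_ok <- .stratum_present(d$female) && d$female$total_a > 0L && d$female$total_b > 0L
  one <- function(t) newcombe_diff_ci(t$events_a, t$total_a,
                                      t$events_b, t$total_b, level)
  if (!m_ok || !f_ok) {
    if (!m_ok && !f_ok)
      stop("no sex with both wild-type and knockout animals", call. = FALSE)
    warning("one sex absent; returning the present sex's effect estimate",
            call. = FALSE)
    return(one(if (m_ok) d$male else d$female))
  }
  em <- one(d$male); ef <- one(d$female)
  .effect((em$estimate + ef$estimate) / 2,
          min(em$lower, ef$lower), max(em$upper, ef$upper), level)
}

#' Knockout sex-difference effect for stage 2
#'
#' Difference in abnormality proportion between male and female knockout
#' animals (male minus female), with the Newcombe method-10 interval. This
#' is the effect-size companion to the stage-2 sexual-dimorphism tests.
#'
#' @inheritParams sex_averaged_effect
#' @return An `"effect_estimate"`.
#' @export
ko_sex_difference <- function(d, level = 0.95) {
  stopifnot(inherits(d, "sex_counts"))
  if (d$male$total_a == 0L || d$female$total_a == 0L)
    stop("knockout animals required in both sexes", call. = FALSE)
  newcombe_diff_ci(d$male$events_a, d$male$total_a,
                   d$female$events_a, d$female$total_a, level)
}
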