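# Simulation machinery: synthetic control pools, global-null type-I error
# by relabeling resampling, stage-2 type-I error in the presence of a
# genotype main effect, and power grids. All entry points are deterministic
# given their seed.
#
# Performance note: every conditional test here is a function of the
# knockout event counts (am, af) given the margins, and under relabeling
# the margins are fixed per trait, so p-values are computed once per
# distinct (am, af) and looked up afterwards.

.seed_guard <- function(seed) {
  if (is.null(seed) || is.na(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(as.integer(seed))
}

#' Draw per-trait abnormality rates for a synthetic screen
#'
#' Log-uniform rates spanning the range observed for rare-event categorical
#' traits in high-throughput phenotyping control data (most traits well
#' below 1%, a few up to 5%).
#'
#' @param n_traits number of traits.
#' @param range length-2 numeric range of rates.
#' @param seed RNG seed (required).
#' @return Numeric vector of rates.
#' @export
trait_rates <- function(n_traits = 100, range = c(1e-5, 0.05), seed = 1) {
  .seed_guard(seed)
  exp(stats::runif(n_traits, log(range[1]), log(range[2])))
}

#' Generate a synthetic control pool
#'
#' Emulates a phenotyping pipeline collecting weekly control cohorts of
#' `per_sex_per_week` animals per sex over `weeks` weeks (default: two
#' years of seven per sex, 728 animals per sex), with independent
#' binomial outcomes per animal and trait at the given per-trait rates.
#'
#' @param rates per-trait abnormality probabilities in \[0, 1\].
#' @param weeks number of weekly cohorts.
#' @param per_sex_per_week animals per sex per week.
#' @param seed RNG seed (required).
#' @return An object of class `"control_pool"`: list with binary matrices
#'   `male` and `female` (animals x traits), `rates`, and the design
#'   parameters.
#' @export
gen_control <- function(rates, weeks = 104, per_sex_per_week = 7, seed = 1) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  .seed_guard(seed)
  n <- weeks * per_sex_per_week
  draw <- function() {
    m <- vapply(rates, function(r) stats::rbinom(n, 1L, r), integer(n))
    dim(m) <- c(n, length(rates))
    m
  }
  structure(list(male = draw(), female = draw(), rates = rates,
                 weeks = weeks, per_sex_per_week = per_sex_per_week,
                 n_per_sex = n, seed = seed),
            class = "control_pool")
}

#' @export
print.control_pool <- function(x, ...) {
  cat(sprintf("Synthetic control pool: %d traits, %d animals/sex (%d weeks x %d), seed %s\n",
              length(x$rates), x$n_per_sex, x$weeks, x$per_sex_per_week,
              format(x$seed)))
  invisible(x)
}

.sim_methods_s1 <- c("FE", "FE_mid", "MH", "MH_mid", "LR_G")
.sim_methods_s2 <- c("LR_KO", "FE_KO", "Zelen", "LR_I")

# p-value for a method at given cell counts (KO events/totals, WT events/totals)
.method_p <- function(method, am, nm_ko, af, nf_ko, em_wt, nm_wt, ef_wt, nf_wt,
                      lrko_memo = NULL) {
  switch(method,
    FE     = .fe_stage1_p(am, nm_ko, em_wt, nm_wt, af, nf_ko, ef_wt, nf_wt, mid = FALSE),
    FE_mid = .fe_stage1_p(am, nm_ko, em_wt, nm_wt, af, nf_ko, ef_wt, nf_wt, mid = TRUE),
    MH     = .mh_p(am, nm_ko, em_wt, nm_wt, af, nf_ko, ef_wt, nf_wt, mid = FALSE),
    MH_mid = .mh_p(am, nm_ko, em_wt, nm_wt, af, nf_ko, ef_wt, nf_wt, mid = TRUE),
    LR_G   = .lr_g_p(am, nm_ko, af, nf_ko, em_wt, nm_wt, ef_wt, nf_wt),
    LR_I   = .lr_i_p(am, nm_ko, af, nf_ko, em_wt, nm_wt, ef_wt, nf_wt),
    LR_KO  = .lrko_memo_p(am, nm_ko, af, nf_ko, lrko_memo),
    FE_KO  = .fe_ko_p(am, nm_ko, af, nf_ko, mid = TRUE),
    Zelen  = .zelen_p(am, nm_ko, em_wt, nm_wt, af, nf_ko, ef_wt, nf_wt, mid = TRUE),
    stop("unknown method: ", method, call. = FALSE))
}

# LR_KO depends only on the knockout cells: memoize on (am, af)
.lrko_memo_p <- function(am, nm, af, nf, memo = NULL) {
  if (is.null(memo)) return(.lr_ko_p(am, nm, af, nf))
  key <- am * (nf + 1L) + af + 1L
  p <- memo$m[key]
  if (is.na(p)) {
    p <- .lr_ko_p(am, nm, af, nf)
    memo$m[key] <- p
  }
  p
}

.new_lrko_memo <- function(nm, nf) {
  e <- new.env(parent = emptyenv())
  e$m <- rep(NA_real_, (nm + 1L) * (nf + 1L))
  e
}

.rate_row <- function(method, threshold, trait, hits, iters) {
  f <- hits / iters
  data.frame(method = method, threshold = threshold, trait = trait,
             fraction = f, se = sqrt(f * (1 - f) / iters),
             iterations = iters, stringsAsFactors = FALSE)
}

#' Global-null type-I error by relabeling resampling
#'
#' In each iteration, `n_ko_per_sex` animals per sex are drawn from the
#' control pool without replacement and relabeled as knockouts; the rest
#' stay wild-type. Each requested method is run on every trait and the
#' fraction of p-values at or below each threshold is tallied per trait and
#' overall. Since there is no genotype effect, these fractions estimate the
#' type-I error rate, expected at or below the nominal threshold for valid
#' (conservative) tests.
#'
#' @param pool a [gen_control()] pool.
#' @param n_ko_per_sex knockout animals per sex to relabel.
#' @param iterations number of resampling iterations.
#' @param methods any subset of `"FE"`, `"FE_mid"`, `"MH"`, `"MH_mid"`,
#'   `"LR_G"` (stage 1) and `"LR_KO"`, `"FE_KO"`, `"Zelen"`, `"LR_I"`
#'   (stage 2).
#' @param thresholds significance thresholds.
#' @param seed RNG seed (required).
#' @param shared_draw if `TRUE` (default) the same relabeled animals are
#'   used for all traits within an iteration, as in a real pipeline where
#'   one cohort is phenotyped for every trait; if `FALSE` each trait draws
#'   its own knockouts.
#' @return Data frame of class `"error_rate_table"` with columns `method`,
#'   `threshold`, `trait` (trait index or `"overall"`), `fraction`, `se`,
#'   `iterations`.
#' @export
resample_null_t1e <- function(pool, n_ko_per_sex = 7, iterations = 1000,
                              methods = "MH_mid", thresholds = 0.05,
                              seed = 1, shared_draw = TRUE) {
  stopifnot(inherits(pool, "control_pool"))
  methods <- match.arg(methods, c(.sim_methods_s1, .sim_methods_s2),
                       several.ok = TRUE)
  N <- pool$n_per_sex
  nko <- as.integer(n_ko_per_sex)
  if (nko >= N) stop("n_ko_per_sex exceeds the pool size", call. = FALSE)
  .seed_guard(seed)
  ntr <- length(pool$rates)
  Em <- colSums(pool$male); Ef <- colSums(pool$female)

  # draw all relabelings first
  AM <- matrix(0L, iterations, ntr)
  AF <- matrix(0L, iterations, ntr)
  for (it in seq_len(iterations)) {
    if (shared_draw) {
      im <- sample.int(N, nko); jf <- sample.int(N, nko)
      AM[it, ] <- colSums(pool$male[im, , drop = FALSE])
      AF[it, ] <- colSums(pool$female[jf, , drop = FALSE])
    } else {
      for (tr in seq_len(ntr)) {
        AM[it, tr] <- sum(pool$male[sample.int(N, nko), tr])
        AF[it, tr] <- sum(pool$female[sample.int(N, nko), tr])
      }
    }
  }

  nwt <- N - nko
  out <- list()
  for (method in methods) {
    lrko_memo <- .new_lrko_memo(nko, nko)
    # p-values per trait via lookup over distinct (am, af)
    P <- matrix(NA_real_, iterations, ntr)
    for (tr in seq_len(ntr)) {
      key <- AM[, tr] * (nko + 1L) + AF[, tr] + 1L
      uk <- unique(key)
      pv <- vapply(uk, function(kk) {
        am <- (kk - 1L) %/% (nko + 1L); af <- (kk - 1L) %% (nko + 1L)
        .method_p(method, am, nko, af, nko,
                  Em[tr] - am, nwt, Ef[tr] - af, nwt, lrko_memo)
      }, numeric(1))
      P[, tr] <- pv[match(key, uk)]
    }
    for (th in thresholds) {
      hit <- P <= th
      out[[length(out) + 1L]] <-
        .rate_row(method, th, "overall", sum(hit), iterations * ntr)
      per_tr <- colSums(hit)
      out[[length(out) + 1L]] <-
        data.frame(method = method, threshold = th,
                   trait = as.character(seq_len(ntr)),
                   fraction = per_tr / iterations,
                   se = sqrt(per_tr / iterations * (1 - per_tr / iterations) / iterations),
                   iterations = iterations, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("error_rate_table", class(res))
  attr(res, "seed") <- seed
  res
}

#' Stage-2 type-I error in the presence of a genotype main effect
#'
#' Simulates a knockout with the same added abnormality probability in both
#' sexes (so the stage-2 null of no interaction holds), and measures the
#' rejection fraction of the stage-2 LR_KO test at each threshold, both
#' unconditionally and conditional on passing a stage-1 MH_mid significance
#' filter. Wild-type cohorts represent two years of weekly collection.
#'
#' @param baseline wild-type abnormality rate (default 0.05).
#' @param effects genotype effect sizes added to the baseline on the
#'   probability scale (knockout rate = min(1, baseline + effect) in both
#'   sexes).
#' @param thresholds stage-2 significance thresholds.
#' @param stage1_filters stage-1 significance filters; `NA` entries mean no
#'   filtering and are reported as `"none"`.
#' @param iterations iterations per effect size.
#' @param weeks,per_sex_per_week,n_ko_per_sex design sizes.
#' @param seed RNG seed (required).
#' @return Data frame of class `"error_rate_table"` with columns `effect`,
#'   `threshold`, `stage1_filter`, `fraction`, `se`, `iterations`.
#' @export
stage2_t1e_sim <- function(baseline = 0.05, effects = seq(0, 0.9, by = 0.1),
                           thresholds = c(0.05, 0.025, 0.01, 0.001),
                           stage1_filters = c(NA, 0.001, 0.01, 0.025, 0.05),
                           iterations = 1000, weeks = 104, per_sex_per_week = 7,
                           n_ko_per_sex = 7, seed = 1) {
  if (baseline < 0 || baseline > 1 || any(effects < 0 | effects > 1))
    stop("baseline and effects must lie in [0, 1]", call. = FALSE)
  .seed_guard(seed)
  nwt <- weeks * per_sex_per_week - n_ko_per_sex
  nko <- n_ko_per_sex
  lrko_memo <- .new_lrko_memo(nko, nko)
  out <- list()
  for (eff in effects) {
    pko <- min(1, baseline + eff)
    s1 <- s2 <- numeric(iterations)
    for (it in seq_len(iterations)) {
      em <- stats::rbinom(1L, nwt, baseline); ef <- stats::rbinom(1L, nwt, baseline)
      am <- stats::rbinom(1L, nko, pko); af <- stats::rbinom(1L, nko, pko)
      s1[it] <- .mh_p(am, nko, em, nwt, af, nko, ef, nwt, mid = TRUE)
      s2[it] <- .lrko_memo_p(am, nko, af, nko, lrko_memo)
    }
    for (th in thresholds) for (fl in stage1_filters) {
      keep <- if (is.na(fl)) rep(TRUE, iterations) else s1 <= fl
      hits <- sum(s2 <= th & keep)
      f <- hits / iterations
      out[[length(out) + 1L]] <-
        data.frame(effect = eff, threshold = th,
                   stage1_filter = if (is.na(fl)) "none" else format(fl),
                   fraction = f, se = sqrt(f * (1 - f) / iterations),
                   iterations = iterations, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("error_rate_table", class(res))
  attr(res, "seed") <- seed
  res
}

#' Power of the stage-1 and stage-2 tests over an effect grid
#'
#' For each grid cell, knockout abnormality probability is
#' min(1, baseline + main) in one sex and min(1, baseline + main +
#' interaction) in the other (the interaction is assigned to a fixed,
#' configurable sex); wild-type cohorts stay at the baseline rate. The
#' detection fraction at `alpha` is reported per method; stage-2 methods
#' are reported both unconditionally and conditional on stage-1 MH_mid
#' significance at `stage1_filter`.
#'
#' @param baselines,mains,interactions numeric grids of baseline rates,
#'   main effects, and one-sex interaction effects (probability scale).
#' @param iterations iterations per grid cell.
#' @param stage1_methods,stage2_methods methods to evaluate (either may be
#'   empty).
#' @param alpha significance threshold for the power tally.
#' @param stage1_filter stage-1 filter level for the filtered stage-2 power.
#' @param interaction_sex `"male"` or `"female"`: the sex receiving the
#'   interaction effect.
#' @param weeks,per_sex_per_week,n_ko_per_sex design sizes.
#' @param seed RNG seed (required).
#' @return Data frame of class `"error_rate_table"` with columns `baseline`,
#'   `main_effect`, `interaction_effect`, `stage`, `method`, `filtered`,
#'   `power`, `se`, `iterations`.
#' @export
power_sim <- function(baselines = c(0, 0.01, 0.025, 0.05, 0.075),
                      mains = c(0, 0.1, 0.2, 0.3),
                      interactions = c(0, 0.2, 0.35),
                      iterations = 1000,
                      stage1_methods = c("FE", "FE_mid", "MH_mid", "LR_G"),
                      stage2_methods = c("Zelen", "LR_I", "LR_KO", "FE_KO"),
                      alpha = 0.05, stage1_filter = 0.05,
                      interaction_sex = c("male", "female"),
                      weeks = 104, per_sex_per_week = 7, n_ko_per_sex = 7,
                      seed = 1) {
  interaction_sex <- match.arg(interaction_sex)
  if (any(baselines < 0 | baselines > 1) || any(mains < 0 | mains > 1) ||
      any(interactions < 0 | interactions > 1))
    stop("rates and effects must lie in [0, 1]", call. = FALSE)
  stage1_methods <- if (length(stage1_methods))
    match.arg(stage1_methods, .sim_methods_s1, several.ok = TRUE) else character(0)
  stage2_methods <- if (length(stage2_methods))
    match.arg(stage2_methods, .sim_methods_s2, several.ok = TRUE) else character(0)
  .seed_guard(seed)
  nwt <- weeks * per_sex_per_week - n_ko_per_sex
  nko <- n_ko_per_sex
  lrko_memo <- .new_lrko_memo(nko, nko)
  memo <- new.env(parent = emptyenv())   # cache for Firth/Zelen p on full counts
  memo_p <- function(method, am, af, em, ef) {
    key <- paste(method, am, af, em, ef)
    p <- memo[[key]]
    if (is.null(p)) {
      p <- .method_p(method, am, nko, af, nko, em, nwt, ef, nwt, lrko_memo)
      memo[[key]] <- p
    }
    p
  }
  need_filter <- length(stage2_methods) > 0
  out <- list()
  for (b in baselines) for (mn in mains) for (ia in interactions) {
    p_m <- min(1, b + mn + if (interaction_sex == "male") ia else 0)
    p_f <- min(1, b + mn + if (interaction_sex == "female") ia else 0)
    hits1 <- stats::setNames(numeric(length(stage1_methods)), stage1_methods)
    hits2 <- stats::setNames(numeric(length(stage2_methods)), stage2_methods)
    hits2f <- hits2
    for (it in seq_len(iterations)) {
      em <- stats::rbinom(1L, nwt, b); ef <- stats::rbinom(1L, nwt, b)
      am <- stats::rbinom(1L, nko, p_m); af <- stats::rbinom(1L, nko, p_f)
      for (method in stage1_methods)
        hits1[method] <- hits1[method] + (memo_p(method, am, af, em, ef) <= alpha)
      if (length(stage2_methods)) {
        pass1 <- if (need_filter) memo_p("MH_mid", am, af, em, ef) <= stage1_filter else TRUE
        for (method in stage2_methods) {
          p2 <- memo_p(method, am, af, em, ef)
          hits2[method] <- hits2[method] + (p2 <= alpha)
          hits2f[method] <- hits2f[method] + (p2 <= alpha && pass1)
        }
      }
    }
    cell <- function(stage, method, filtered, hits)
      data.frame(baseline = b, main_effect = mn, interaction_effect = ia,
                 stage = stage, method = method, filtered = filtered,
                 power = hits / iterations,
                 se = sqrt(hits / iterations * (1 - hits / iterations) / iterations),
                 iterations = iterations, stringsAsFactors = FALSE)
    for (method in stage1_methods)
      out[[length(out) + 1L]] <- cell(1L, method, FALSE, hits1[method])
    for (method in stage2_methods) {
      out[[length(out) + 1L]] <- cell(2L, method, FALSE, hits2[method])
      out[[length(out) + 1L]] <- cell(2L, method, TRUE, hits2f[method])
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("error_rate_table", class(res))
  attr(res, "seed") <- seed
  res
}
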