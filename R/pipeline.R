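# Orchestration of the two-stage workflow: stage-1 genotype testing with
# attainability filtering and FDR control, then stage-2 sexual-dimorphism
# testing restricted to stage-1 discoveries, with effect sizes attached.

#' Configuration for the two-stage pipeline
#'
#' The default configuration is the recommended workflow: MH_mid at stage 1
#' behind an MH alpha-star filter at 5%, BH FDR at 5% for stage-1 calls,
#' stage 2 restricted to stage-1 discoveries, an LR_KO alpha-star filter,
#' the LR_KO test, and BH FDR at 20% for stage-2 calls.
#'
#' @param stage1_method one of `"MH_mid"`, `"FE"`, `"FE_mid"`, `"LR_G"`.
#' @param stage2_method one of `"LR_KO"`, `"Zelen"`, `"LR_I"`, `"FE_KO"`.
#' @param use_mh_alpha_star_filter apply the stage-1 attainability filter?
#' @param use_lrko_alpha_star_filter apply the stage-2 attainability filter?
#' @param restrict_stage2_to_stage1_significant test stage 2 only in stage-1
#'   discoveries?
#' @param fdr_scope `"global-BH"` or `"within-family-BB"` (family = line x
#'   zygosity).
#' @param stage1_fdr_level,stage2_fdr_level FDR levels in (0, 1).
#' @param alpha_star_stage1_threshold,alpha_star_stage2_threshold
#'   attainability thresholds in (0, 1].
#' @param legacy_fixed_threshold if non-NULL (e.g. `1e-4`), disables filters
#'   and FDR and calls significance by `p < threshold` at both stages.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stage1_method = c("MH_mid", "FE", "FE_mid", "LR_G"),
                            stage2_method = c("LR_KO", "Zelen", "LR_I", "FE_KO"),
                            use_mh_alpha_star_filter = TRUE,
                            use_lrko_alpha_star_filter = TRUE,
                            restrict_stage2_to_stage1_significant = TRUE,
                            fdr_scope = c("global-BH", "within-family-BB"),
                            stage1_fdr_level = 0.05,
                            stage2_fdr_level = 0.20,
                            alpha_star_stage1_threshold = 0.05,
                            alpha_star_stage2_threshold = 0.05,
                            legacy_fixed_threshold = NULL) {
  cfg <- list(stage1_method = match.arg(stage1_method),
              stage2_method = match.arg(stage2_method),
              use_mh_alpha_star_filter = isTRUE(use_mh_alpha_star_filter),
              use_lrko_alpha_star_filter = isTRUE(use_lrko_alpha_star_filter),
              restrict_stage2_to_stage1_significant =
                isTRUE(restrict_stage2_to_stage1_significant),
              fdr_scope = match.arg(fdr_scope),
              stage1_fdr_level = stage1_fdr_level,
              stage2_fdr_level = stage2_fdr_level,
              alpha_star_stage1_threshold = alpha_star_stage1_threshold,
              alpha_star_stage2_threshold = alpha_star_stage2_threshold,
              legacy_fixed_threshold = legacy_fixed_threshold)
  stopifnot(cfg$stage1_fdr_level > 0, cfg$stage1_fdr_level < 1,
            cfg$stage2_fdr_level > 0, cfg$stage2_fdr_level < 1,
            cfg$alpha_star_stage1_threshold > 0,
            cfg$alpha_star_stage1_threshold <= 1,
            cfg$alpha_star_stage2_threshold > 0,
            cfg$alpha_star_stage2_threshold <= 1)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Two-stage pipeline configuration\n")
  if (!is.null(x$legacy_fixed_threshold)) {
    cat(sprintf("  LEGACY fixed-threshold mode: p < %g, no filters, no FDR\n",
                x$legacy_fixed_threshold))
  }
  cat(sprintf("  stage 1: %s%s, FDR (%s) at %g\n", x$stage1_method,
              if (x$use_mh_alpha_star_filter)
                sprintf(" [MH alpha-star filter < %g]", x$alpha_star_stage1_threshold)
              else "",
              x$fdr_scope, x$stage1_fdr_level))
  cat(sprintf("  stage 2: %s%s%s, FDR (%s) at %g\n", x$stage2_method,
              if (x$restrict_stage2_to_stage1_significant)
                " [restricted to stage-1 calls]" else "",
              if (x$use_lrko_alpha_star_filter)
                sprintf(" [LR_KO alpha-star filter < %g]", x$alpha_star_stage2_threshold)
              else "",
              x$fdr_scope, x$stage2_fdr_level))
  invisible(x)
}

#' Pipeline configuration matching a numbered multiplicity approach
#'
#' Maps the ten pre-registered combinations of filters, FDR scope and
#' stage-2 level that were compared when selecting the workflow; approach 6
#' (stage-1 alpha-star filter, restriction, global BH, stage-2 FDR 20%) is
#' the recommended one.
#'
#' @param n approach number, 1 to 10.
#' @param ... overrides passed on to [pipeline_config()].
#' @return A [pipeline_config()] object.
#' @export
approach_config <- function(n, ...) {
  stopifnot(n %in% 1:10)
  mh_filter <- n %in% c(2, 5, 6, 9, 10)
  within_family <- n %in% c(7, 8, 9, 10)
  restrict <- n %in% 3:10
  lrko_filter <- n %in% c(2, 9, 10)
  s2_level <- if (n %in% c(4, 6, 8, 10)) 0.20 else 0.05
  pipeline_config(stage1_method = "MH_mid", stage2_method = "LR_KO",
                  use_mh_alpha_star_filter = mh_filter,
                  use_lrko_alpha_star_filter = lrko_filter,
                  restrict_stage2_to_stage1_significant = restrict,
                  fdr_scope = if (within_family) "within-family-BB" else "global-BH",
                  stage2_fdr_level = s2_level, ...)
}

.stage1_p <- function(d, method) {
  switch(method,
         MH_mid = mh_exact_mid(d, mid = TRUE)$p.value,
         FE = fe_stage1(d, mid = FALSE)$p.value,
         FE_mid = fe_stage1(d, mid = TRUE)$p.value,
         LR_G = lr_g(d)$p.value)
}

.stage2_p <- function(d, method) {
  switch(method,
         LR_KO = lr_ko(d)$p.value,
         Zelen = zelen_mid(d, mid = TRUE)$p.value,
         LR_I = lr_i(d)$p.value,
         FE_KO = fe_ko(d, mid = TRUE)$p.value)
}

.adjust_calls <- function(p, family, cfg, level) {
  if (cfg$fdr_scope == "global-BH") {
    r <- bh(p, level)
    list(padj = r$adjusted, call = r$reject)
  } else {
    r <- bb(p, family, level)
    list(padj = r$adjusted, call = r$reject)
  }
}

#' Run stage 1 of the pipeline (genotype effect)
#'
#' Computes the stage-1 attainability filter (margins only), the stage-1
#' p-values for surviving data sets, FDR-adjusted calls, and sex-averaged
#' effect sizes. Rows removed by the filter carry no p-value.
#'
#' @param datasets list of [sex_counts()] data sets.
#' @param cfg a [pipeline_config()].
#' @return Data frame with one row per data set.
#' @export
run_stage1 <- function(datasets, cfg = pipeline_config()) {
  if (length(datasets) == 0L) stop("no data sets supplied", call. = FALSE)
  stopifnot(inherits(cfg, "pipeline_config"))
  legacy <- !is.null(cfg$legacy_fixed_threshold)
  mid <- cfg$stage1_method %in% c("MH_mid", "FE_mid", "LR_G")
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    data.frame(dataset = .dataset_id(d), line_id = d$line_id,
               zygosity = d$zygosity, trait_id = d$trait_id,
               s1_alpha_star = mh_alpha_star(d, mid = mid),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$s1_filtered <- if (cfg$use_mh_alpha_star_filter && !legacy)
    res$s1_alpha_star >= cfg$alpha_star_stage1_threshold else FALSE
  res$s1_p <- NA_real_
  res$note <- ""
  for (i in which(!res$s1_filtered)) {
    p <- tryCatch(withCallingHandlers(
      .stage1_p(datasets[[i]], cfg$stage1_method),
      warning = function(w) {
        res$note[i] <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }), error = function(e) {
        res$note[i] <<- conditionMessage(e); NA_real_
      })
    res$s1_p[i] <- p
  }
  res$s1_padj <- NA_real_
  res$s1_call <- FALSE
  tested <- !res$s1_filtered & !is.na(res$s1_p)
  if (any(tested)) {
    if (legacy) {
      res$s1_call[tested] <- res$s1_p[tested] < cfg$legacy_fixed_threshold
    } else {
      fam <- paste(res$line_id, res$zygosity, sep = ":")
      a <- .adjust_calls(res$s1_p[tested], fam[tested], cfg, cfg$stage1_fdr_level)
      res$s1_padj[tested] <- a$padj
      res$s1_call[tested] <- a$call
    }
  }
  # sex-averaged genotype effect sizes (reported for every testable row)
  res$effect_est <- res$effect_lo <- res$effect_hi <- NA_real_
  for (i in seq_along(datasets)) {
    e <- tryCatch(suppressWarnings(sex_averaged_effect(datasets[[i]])),
                  error = function(e) NULL)
    if (!is.null(e)) {
      res$effect_est[i] <- e$estimate
      res$effect_lo[i] <- e$lower
      res$effect_hi[i] <- e$upper
    }
  }
  res
}

#' Run stage 2 of the pipeline (sexual dimorphism)
#'
#' Builds the stage-2 candidate set (stage-1 discoveries when restriction is
#' enabled), applies the LR_KO attainability filter, computes stage-2
#' p-values and FDR-adjusted calls over the candidate set, and attaches the
#' knockout sex-difference effect sizes.
#'
#' @param stage1 result of [run_stage1()].
#' @param datasets the same list of [sex_counts()] data sets.
#' @param cfg a [pipeline_config()].
#' @return `stage1` with stage-2 columns appended.
#' @export
run_stage2 <- function(stage1, datasets, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  legacy <- !is.null(cfg$legacy_fixed_threshold)
  res <- stage1
  n <- nrow(res)
  res$s2_eligible <- if (cfg$restrict_stage2_to_stage1_significant)
    res$s1_call else (!res$s1_filtered & !is.na(res$s1_p))
  res$s2_alpha_star <- NA_real_
  res$s2_filtered <- FALSE
  res$s2_p <- res$s2_padj <- NA_real_
  res$s2_call <- FALSE
  res$ko_diff_est <- res$ko_diff_lo <- res$ko_diff_hi <- NA_real_
  for (i in which(res$s2_eligible)) {
    d <- datasets[[i]]
    a2 <- tryCatch(lrko_alpha_star(d$male$total_a, d$female$total_a,
                                   d$male$events_a + d$female$events_a),
                   error = function(e) NA_real_)
    res$s2_alpha_star[i] <- a2
    if (cfg$use_lrko_alpha_star_filter && !legacy) {
      res$s2_filtered[i] <- is.na(a2) || a2 >= cfg$alpha_star_stage2_threshold
    } else if (is.na(a2)) {
      res$s2_filtered[i] <- TRUE     # untestable (a sex without knockouts)
    }
    if (!res$s2_filtered[i]) {
      res$s2_p[i] <- tryCatch(suppressWarnings(.stage2_p(d, cfg$stage2_method)),
                              error = function(e) {
                                res$note[i] <<- paste(res$note[i], conditionMessage(e))
                                NA_real_
                              })
      e <- tryCatch(ko_sex_difference(d), error = function(e) NULL)
      if (!is.null(e)) {
        res$ko_diff_est[i] <- e$estimate
        res$ko_diff_lo[i] <- e$lower
        res$ko_diff_hi[i] <- e$upper
      }
    }
  }
  tested <- res$s2_eligible & !res$s2_filtered & !is.na(res$s2_p)
  if (any(tested)) {
    if (legacy) {
      res$s2_call[tested] <- res$s2_p[tested] < cfg$legacy_fixed_threshold
    } else {
      fam <- paste(res$line_id, res$zygosity, sep = ":")
      a <- .adjust_calls(res$s2_p[tested], fam[tested], cfg, cfg$stage2_fdr_level)
      res$s2_padj[tested] <- a$padj
      res$s2_call[tested] <- a$call
    }
  }
  res
}

#' Run the full two-stage pipeline
#'
#' Composes [run_stage1()] and [run_stage2()] and attaches a
#' filter-accounting summary (how many data sets each step removed) plus
#' the configuration used, so every report is self-describing. Each input
#' data set appears in the report exactly once with an explicit disposition.
#'
#' @inheritParams run_stage1
#' @return An object of class `"pheno_pipeline"`: list with `report`
#'   (data frame), `summary` (named counts), `config`.
#' @export
run_pipeline <- function(datasets, cfg = pipeline_config()) {
  s1 <- run_stage1(datasets, cfg)
  rep <- run_stage2(s1, datasets, cfg)
  rep$disposition <- ifelse(rep$s1_filtered, "filtered_stage1",
                     ifelse(is.na(rep$s1_p), "failed_stage1",
                     ifelse(!rep$s1_call, "tested_stage1",
                     ifelse(!rep$s2_eligible | rep$s2_filtered, "stage1_call_filtered_stage2",
                     ifelse(rep$s2_call, "stage2_call", "tested_stage2")))))
  summary <- c(n_datasets = nrow(rep),
               removed_stage1_filter = sum(rep$s1_filtered),
               tested_stage1 = sum(!rep$s1_filtered & !is.na(rep$s1_p)),
               stage1_calls = sum(rep$s1_call),
               stage2_candidates = sum(rep$s2_eligible),
               removed_stage2_filter = sum(rep$s2_eligible & rep$s2_filtered),
               tested_stage2 = sum(!is.na(rep$s2_p)),
               stage2_calls = sum(rep$s2_call))
  structure(list(report = rep, summary = summary, config = cfg),
            class = "pheno_pipeline")
}

#' @export
print.pheno_pipeline <- function(x, ...) {
  print(x$config)
  cat("\nFilter accounting:\n")
  for (nm in names(x$summary)) cat(sprintf("  %-24s %d\n", nm, x$summary[[nm]]))
  invisible(x)
}
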