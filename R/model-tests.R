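# Firth penalized-LRT phenotype tests: genotype (LR_G), interaction (LR_I),
# knockout-only sex effect (LR_KO), and the batch-variation screen.
#
# Coding convention: sex is one indicator column (reference = female),
# genotype indicator 1 = knockout, interaction = product. Aggregated rows
# (one per sex-by-group cell) are used throughout: the binomial likelihood,
# information and hence the penalized LRT are identical to per-animal rows.

# rows M-KO, F-KO, M-WT, F-WT with columns (intercept, sexM, geno, sexM:geno)
.design_full <- function(d) {
  X <- cbind(`(Intercept)` = 1, sexM = c(1, 0, 1, 0),
             geno = c(1, 1, 0, 0), `sexM:geno` = c(1, 0, 0, 0))
  k <- c(d$male$events_a, d$female$events_a, d$male$events_b, d$female$events_b)
  n <- c(d$male$total_a, d$female$total_a, d$male$total_b, d$female$total_b)
  list(X = X, k = k, n = n)
}

.lrt_htest <- function(lrt, method, dname) {
  lrt$method <- method
  lrt$data.name <- dname
  lrt
}

# degraded single-sex genotype test: Y ~ genotype vs constant
.lr_single_sex <- function(t, dname, method, control) {
  X <- cbind(`(Intercept)` = 1, geno = c(1, 0))
  lrt <- penalized_lrt(X, events = c(t$events_a, t$events_b),
                       trials = c(t$total_a, t$total_b), tested = 2L,
                       control = control)
  .lrt_htest(lrt, paste0(method, " [single-sex degraded: Y ~ genotype]"), dname)
}

#' Stage-1 genotype test by Firth penalized likelihood ratio (LR_G)
#'
#' Compares the null model `Y ~ sex` with the test model
#' `Y ~ genotype + sex + genotype:sex` by a penalized likelihood-ratio test
#' with 2 degrees of freedom, so a genotype effect in either or both sexes
#' contributes to the statistic.
#'
#' @param d a [sex_counts()] data set.
#' @param control a [firth_control()] list.
#' @return An `"htest"` result.
#' @export
lr_g <- function(d, control = firth_control()) {
  stopifnot(inherits(d, "sex_counts"))
  dname <- .dataset_id(d)
  if (!.stratum_present(d$male) || !.stratum_present(d$female)) {
    warning("only one sex present; testing Y ~ genotype vs constant (df = 1)",
            call. = FALSE)
    t <- if (.stratum_present(d$male)) d$male else d$female
    return(.lr_single_sex(t, dname, "LR_G", control))
  }
  dd <- .design_full(d)
  lrt <- penalized_lrt(dd$X, dd$k, dd$n, tested = c(3L, 4L), control = control)
  .lrt_htest(lrt, "LR_G: Firth penalized LRT for genotype (Y ~ geno + sex + geno:sex vs Y ~ sex)",
             dname)
}

#' Stage-2 interaction test by Firth penalized likelihood ratio (LR_I)
#'
#' Compares the null model `Y ~ sex + genotype` with the test model
#' `Y ~ genotype + sex + genotype:sex` (1 df): a direct test of the
#' genotype-by-sex interaction using all animals. Has no power when the
#' wild-type abnormality rate is zero (the conditional information about the
#' interaction vanishes); see [lr_ko()] for the knockout-only alternative.
#'
#' @inheritParams lr_g
#' @return An `"htest"` result.
#' @export
lr_i <- function(d, control = firth_control()) {
  stopifnot(inherits(d, "sex_counts"))
  dname <- .dataset_id(d)
  if (!.stratum_present(d$male) || !.stratum_present(d$female)) {
    warning("only one sex present; interaction untestable, testing Y ~ genotype vs constant (df = 1)",
            call. = FALSE)
    t <- if (.stratum_present(d$male)) d$male else d$female
    return(.lr_single_sex(t, dname, "LR_I", control))
  }
  dd <- .design_full(d)
  lrt <- penalized_lrt(dd$X, dd$k, dd$n, tested = 4L, control = control)
  .lrt_htest(lrt, "LR_I: Firth penalized LRT for genotype-by-sex interaction", dname)
}

#' Stage-2 knockout-only sex-effect test (LR_KO)
#'
#' Within the knockout animals only, compares `Y ~ sex` with a constant
#' model by Firth penalized likelihood ratio (1 df). Under the assumption of
#' equal (near-zero) background rates across sexes this assesses sexual
#' dimorphism of the knockout phenotype, and retains power when the
#' wild-type abnormality rate is zero.
#'
#' @inheritParams lr_g
#' @return An `"htest"` result.
#' @export
lr_ko <- function(d, control = firth_control()) {
  stopifnot(inherits(d, "sex_counts"))
  if (d$male$total_a == 0L || d$female$total_a == 0L)
    stop("knockout animals required in both sexes for LR_KO", call. = FALSE)
  lrt <- .lr_ko_test(d$male$events_a, d$male$total_a,
                     d$female$events_a, d$female$total_a, control)
  .lrt_htest(lrt, "LR_KO: Firth penalized LRT for sex within knockouts (Y ~ sex vs constant)",
             .dataset_id(d))
}

.lr_ko_test <- function(km, nm, kf, nf, control = firth_control()) {
  X <- cbind(`(Intercept)` = 1, sexM = c(1, 0))
  penalized_lrt(X, events = c(km, kf), trials = c(nm, nf), tested = 2L,
                control = control)
}

# bare p-value fast paths for the simulation engine -------------------------

.lr_ko_p <- function(km, nm, kf, nf) .lr_ko_test(km, nm, kf, nf)$p.value

.lr_g_p <- function(km_ko, nm_ko, kf_ko, nf_ko, km_wt, nm_wt, kf_wt, nf_wt) {
  X <- cbind(1, c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0))
  penalized_lrt(X, events = c(km_ko, kf_ko, km_wt, kf_wt),
                trials = c(nm_ko, nf_ko, nm_wt, nf_wt), tested = c(3L, 4L))$p.value
}

.lr_i_p <- function(km_ko, nm_ko, kf_ko, nf_ko, km_wt, nm_wt, kf_wt, nf_wt) {
  X <- cbind(1, c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0))
  penalized_lrt(X, events = c(km_ko, kf_ko, km_wt, kf_wt),
                trials = c(nm_ko, nf_ko, nm_wt, nf_wt), tested = 4L)$p.value
}

#' Screen control data for batch-to-batch variation
#'
#' For each trait, tests `Y ~ sex + batch` against `Y ~ sex` by Firth
#' penalized likelihood ratio with (number of batches - 1) degrees of
#' freedom, then appends Benjamini-Hochberg adjusted q-values. Traits with
#' zero events are recorded with p = 1 and flagged uninformative. A
#' non-significant screen justifies pooling control animals across batches.
#'
#' @param records data frame of per-animal control records with columns
#'   `trait_id`, `sex` (`"M"`/`"F"`), `batch`, `outcome` (0/1).
#' @param fdr_level level for the BH adjustment flag (default 0.05).
#' @param control a [firth_control()] list.
#' @return Data frame with one row per trait: `trait_id`, `statistic`, `df`,
#'   `p`, `q`, `batch_effect` (q at or below `fdr_level`), `uninformative`.
#' @export
batch_screen <- function(records, fdr_level = 0.05, control = firth_control()) {
  req <- c("trait_id", "sex", "batch", "outcome")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (length(unique(records$batch)) < 2L)
    stop("batch screen requires at least two batches", call. = FALSE)
  sexM <- .normalize_sex(records$sex) == "M"
  batch <- factor(records$batch)
  traits <- unique(as.character(records$trait_id))
  out <- lapply(traits, function(tr) {
    idx <- records$trait_id == tr
    y <- as.numeric(records$outcome[idx])
    b <- droplevels(batch[idx])
    df <- nlevels(b) - 1L
    if (sum(y) == 0 || df == 0L)
      return(data.frame(trait_id = tr, statistic = 0, df = df, p = 1,
                        uninformative = TRUE))
    # aggregate to sex-by-batch cells
    cell <- interaction(sexM[idx], b, drop = TRUE)
    k <- tapply(y, cell, sum)
    n <- tapply(y, cell, length)
    s <- tapply(sexM[idx], cell, `[`, 1)
    bl <- tapply(as.integer(b), cell, `[`, 1)
    Xb <- stats::model.matrix(~ factor(bl, levels = sort(unique(as.integer(b)))))[, -1, drop = FALSE]
    X <- cbind(`(Intercept)` = 1, sexM = as.numeric(s), Xb)
    lrt <- tryCatch(
      penalized_lrt(X, events = as.numeric(k), trials = as.numeric(n),
                    tested = seq.int(3L, ncol(X)), control = control),
      error = function(e) NULL)
    if (is.null(lrt))
      return(data.frame(trait_id = tr, statistic = NA_real_, df = df, p = 1,
                        uninformative = TRUE))
    data.frame(trait_id = tr, statistic = unname(lrt$statistic),
               df = unname(lrt$parameter), p = lrt$p.value,
               uninformative = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$batch_effect <- res$q <= fdr_level & !res$uninformative
  res[c("trait_id", "statistic", "df", "p", "q", "batch_effect", "uninformative")]
}
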