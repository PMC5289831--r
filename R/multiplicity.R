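# Multiplicity control: flat Benjamini-Hochberg FDR and the
# Benjamini-Bogomolov two-step procedure controlling the average FDR over
# families (here: gene x zygosity).

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Rejects the k-hat smallest p-values where
#' k-hat = max\{k : p_(k) <= k q / m\}; adjusted p-values are the standard
#' monotone (cummin) transform as in [stats::p.adjust()], which is used for
#' the computation.
#'
#' @param pvals p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical flags).
#' @export
bh <- function(pvals, q = 0.05) {
  .check_p(pvals)
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

.check_p <- function(p) {
  if (length(p) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Benjamini-Bogomolov within-family FDR procedure
#'
#' Two-step control of the average FDR over families. Step 1 runs a
#' within-family BH at level `q` and counts the number R of families with at
#' least one rejection. Step 2 declares significant only hypotheses that are
#' rejected by a within-family BH at the adjusted level R q / m (m = number
#' of families), applied only inside the R selected families.
#'
#' @param pvals p-values in (0, 1].
#' @param family family identifier per hypothesis (gene x zygosity).
#' @param q FDR level in (0, 1).
#' @return List with `reject` (final flags), `selected` (per-hypothesis flag
#'   that its family was selected in step 1), `R`, `n_families`,
#'   `step2_level`, and `adjusted` (within-family BH-adjusted p-values).
#' @export
bb <- function(pvals, family, q = 0.05) {
  .check_p(pvals)
  stopifnot(q > 0, q < 1, length(family) == length(pvals))
  family <- as.character(family)
  fams <- unique(family)
  m <- length(fams)
  adj <- numeric(length(pvals))
  for (f in fams) {
    i <- family == f
    adj[i] <- stats::p.adjust(pvals[i], method = "BH")
  }
  sel_fams <- fams[vapply(fams, function(f) any(adj[family == f] <= q), logical(1))]
  R <- length(sel_fams)
  level2 <- R * q / m
  selected <- family %in% sel_fams
  reject <- selected & adj <= level2
  list(reject = reject, selected = selected, R = R, n_families = m,
       step2_level = level2, adjusted = adj)
}
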