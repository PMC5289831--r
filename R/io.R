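# Reading per-animal or aggregated phenotype tables, writing pipeline
# reports. Delimited text only (comma or tab, sniffed); counts are the
# internal currency, so per-animal input is aggregated at the door and
# control animals are pooled across batches.

.normalize_sex <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[s %in% c("M", "MALE")] <- "M"
  s[s %in% c("F", "FEMALE")] <- "F"
  bad <- !(s %in% c("M", "F"))
  if (any(bad))
    stop("unknown sex token(s) in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  s
}

.normalize_group <- function(x) {
  g <- tolower(trimws(as.character(x)))
  bad <- !(g %in% c("control", "knockout"))
  if (any(bad))
    stop("unknown group token(s) in row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  g
}

.sniff_read <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read phenotype records into sex-stratified count data sets
#'
#' Accepts either per-animal records (columns `animal_id`, `line_id`,
#' `zygosity`, `sex`, `group`, `trait_id`, `outcome`, optional
#' `batch_date`) or pre-aggregated counts (columns `line_id`, `zygosity`,
#' `trait_id`, `sex`, `group`, `total`, `abnormal`). Sex tokens are
#' case-insensitive (`M`/`F`/`Male`/`Female`); groups are `control` or
#' `knockout`. Control animals are pooled across batches. Each line x
#' zygosity x trait combination becomes one [sex_counts()] data set, with
#' the control pool shared across lines when `line_id` is `"control"`-free;
#' controls are matched to every line within the same trait.
#'
#' @param path file path (comma- or tab-separated, sniffed from the header).
#' @param format `"auto"` (default), `"per_animal"`, or `"aggregated"`.
#' @return Named list of [sex_counts()] data sets.
#' @export
read_phenotype_records <- function(path,
                                   format = c("auto", "per_animal", "aggregated")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- .sniff_read(path)
  per_animal_cols <- c("animal_id", "line_id", "zygosity", "sex", "group",
                       "trait_id", "outcome")
  agg_cols <- c("line_id", "zygosity", "trait_id", "sex", "group", "total",
                "abnormal")
  if (format == "auto")
    format <- if (all(per_animal_cols %in% names(df))) "per_animal"
              else if (all(agg_cols %in% names(df))) "aggregated"
              else stop("header matches neither the per-animal nor the aggregated schema",
                        call. = FALSE)
  if (format == "per_animal") {
    miss <- setdiff(per_animal_cols, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    if (!all(df$outcome %in% c(0, 1)))
      stop("outcome must be 0 or 1; offending row(s): ",
           paste(utils::head(which(!(df$outcome %in% c(0, 1))), 5), collapse = ", "),
           call. = FALSE)
    dup <- duplicated(df[c("animal_id", "trait_id")])
    if (any(dup))
      stop("duplicate animal x trait record(s) in row(s): ",
           paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
    df$sex <- .normalize_sex(df$sex)
    df$group <- .normalize_group(df$group)
    agg <- stats::aggregate(cbind(abnormal = df$outcome,
                                  total = rep(1L, nrow(df))),
                            by = df[c("line_id", "zygosity", "trait_id",
                                      "sex", "group")],
                            FUN = sum)
  } else {
    miss <- setdiff(agg_cols, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    df$sex <- .normalize_sex(df$sex)
    df$group <- .normalize_group(df$group)
    if (any(df$abnormal > df$total | df$abnormal < 0 | df$total < 0))
      stop("abnormal counts must lie in [0, total]; offending row(s): ",
           paste(utils::head(which(df$abnormal > df$total | df$abnormal < 0 |
                                     df$total < 0), 5), collapse = ", "),
           call. = FALSE)
    agg <- stats::aggregate(df[c("abnormal", "total")],
                            by = df[c("line_id", "zygosity", "trait_id",
                                      "sex", "group")],
                            FUN = sum)
  }
  # controls recorded under the knockout line's ids are matched to that line;
  # otherwise the control pool for the trait is shared across lines
  is_ctrl <- agg$group == "control"
  cell <- function(rows) {
    if (nrow(rows) == 0L) c(0L, 0L) else c(sum(rows$abnormal), sum(rows$total))
  }
  ko <- agg[!is_ctrl, , drop = FALSE]
  keys <- unique(ko[c("line_id", "zygosity", "trait_id")])
  datasets <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    kk <- ko[ko$line_id == k$line_id & ko$zygosity == k$zygosity &
               ko$trait_id == k$trait_id, ]
    ctrl <- agg[is_ctrl & agg$trait_id == k$trait_id &
                  agg$line_id == k$line_id & agg$zygosity == k$zygosity, ]
    if (nrow(ctrl) == 0L)
      ctrl <- agg[is_ctrl & agg$trait_id == k$trait_id, ]
    make_dataset(ko_male = cell(kk[kk$sex == "M", ]),
                 wt_male = cell(ctrl[ctrl$sex == "M", ]),
                 ko_female = cell(kk[kk$sex == "F", ]),
                 wt_female = cell(ctrl[ctrl$sex == "F", ]),
                 line_id = k$line_id, zygosity = k$zygosity,
                 trait_id = k$trait_id)
  })
  names(datasets) <- vapply(datasets, .dataset_id, character(1))
  datasets
}

#' Write aggregated count data sets to a delimited file
#'
#' The inverse of [read_phenotype_records()] for the aggregated schema;
#' a write-then-read round trip recovers identical data sets.
#'
#' @param datasets list of [sex_counts()] data sets.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_datasets <- function(datasets, path, sep = "\t") {
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(line_id = d$line_id,
               zygosity = d$zygosity,
               trait_id = d$trait_id,
               sex = c("M", "F", "M", "F"),
               group = rep(c("knockout", "control"), each = 2),
               total = c(d$male$total_a, d$female$total_a,
                         d$male$total_b, d$female$total_b),
               abnormal = c(d$male$events_a, d$female$events_a,
                            d$male$events_b, d$female$events_b),
               stringsAsFactors = FALSE)
  }))
  # the shared control pool appears once per trait, not once per line
  rows <- rows[!duplicated(rows[c("line_id", "zygosity", "trait_id", "sex", "group")]), ]
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report to a tab-separated file
#'
#' Fixed column order, full-precision numerics, and a `#`-prefixed header
#' line carrying the configuration fingerprint, so a written report is a
#' complete record of what was run. Re-parsing recovers all p-values
#' exactly.
#'
#' @param x a `"pheno_pipeline"` result from [run_pipeline()] (or its
#'   report data frame).
#' @param path output path.
#' @export
write_report <- function(x, path) {
  rep <- if (inherits(x, "pheno_pipeline")) x$report else x
  if (!is.data.frame(rep) || nrow(rep) == 0L)
    stop("report has no rows", call. = FALSE)
  cfg_line <- if (inherits(x, "pheno_pipeline"))
    paste0("# config: ", paste(names(unclass(x$config)), vapply(
      unclass(x$config), function(v) if (is.null(v)) "NULL" else format(v),
      character(1)), sep = "=", collapse = "; "))
  else "# config: (not recorded)"
  num <- vapply(rep, is.numeric, logical(1))
  out <- rep
  out[num] <- lapply(rep[num], function(v) sprintf("%.17g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cfg_line, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a written pipeline report
#'
#' @param path a file written by [write_report()].
#' @return The report data frame (numeric columns restored).
#' @export
read_report <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Generate a small example data file
#'
#' Writes a per-animal file with a handful of knockout lines (7 animals per
#' sex) against a pooled control cohort, with one line carrying a strong
#' sexually dimorphic effect. Useful as CLI/demo input.
#'
#' @param path output path.
#' @param n_lines number of knockout lines.
#' @param n_controls control animals per sex.
#' @param seed RNG seed (required).
#' @return `path`, invisibly.
#' @export
write_example_data <- function(path, n_lines = 4, n_controls = 140, seed = 1) {
  .seed_guard(seed)
  rows <- list()
  add <- function(line, zyg, sex, grp, outc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      animal_id = paste0(line, "_", sex, "_", grp, "_", seq_along(outc)),
      line_id = line, zygosity = zyg, sex = sex, group = grp,
      trait_id = "abnormal_morphology", outcome = outc,
      stringsAsFactors = FALSE)
  }
  add("control", "wt", "M", "control", stats::rbinom(n_controls, 1, 0.005))
  add("control", "wt", "F", "control", stats::rbinom(n_controls, 1, 0.005))
  for (i in seq_len(n_lines)) {
    line <- sprintf("line%02d", i)
    pm <- if (i == 1) 0.9 else 0.02   # line 1: dimorphic, males affected
    pf <- 0.02
    add(line, "hom", "M", "knockout", stats::rbinom(7, 1, pm))
    add(line, "hom", "F", "knockout", stats::rbinom(7, 1, pf))
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
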