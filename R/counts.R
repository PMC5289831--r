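#' Construct a 2x2 count table for one trait
#'
#' Holds event/trial counts for two groups on a single binary trait. In the
#' phenotyping context group `a` is the knockout cohort and group `b` the
#' wild-type (control) cohort, and an "event" is an abnormal phenotype call.
#'
#' @param events_a,total_a events and trials in group a (knockout).
#' @param events_b,total_b events and trials in group b (wild-type).
#' @return An object of class `"two_by_two"`.
#' @examples
#' two_by_two(2, 7, 0, 721)
#' @export
two_by_two <- function(events_a, total_a, events_b, total_b) {
  x <- list(events_a = as.integer(events_a), total_a = as.integer(total_a),
            events_b = as.integer(events_b), total_b = as.integer(total_b))
  for (v in x) {
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop("counts must be single non-negative integers", call. = FALSE)
  }
  if (x$events_a > x$total_a || x$events_b > x$total_b)
    stop("events cannot exceed totals", call. = FALSE)
  structure(x, class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$events_a, x$total_a - x$events_a,
                x$events_b, x$total_b - x$events_b),
              2, 2, byrow = TRUE,
              dimnames = list(c("knockout", "wild-type"),
                              c("abnormal", "normal")))
  print(m)
  invisible(x)
}

#' Sex-stratified counts for one wild-type vs knockout data set
#'
#' The 2x2x2 table (sex x group x outcome) for one knockout line, zygosity and
#' trait: a [two_by_two()] per sex with knockout as group a and wild-type as
#' group b. This is the unit of analysis throughout the pipeline; per-animal
#' records are aggregated to this form at the door (see
#' [read_phenotype_records()]).
#'
#' @param male,female [two_by_two()] tables (knockout = group a); either may
#'   encode an absent stratum with all totals zero.
#' @param line_id,zygosity,trait_id identifiers carried into reports.
#' @return An object of class `"sex_counts"`.
#' @examples
#' sex_counts(male = two_by_two(4, 7, 0, 721),
#'            female = two_by_two(0, 7, 1, 721),
#'            line_id = "L1", zygosity = "hom", trait_id = "eye")
#' @export
sex_counts <- function(male, female, line_id = NA_character_,
                       zygosity = NA_character_, trait_id = NA_character_) {
  stopifnot(inherits(male, "two_by_two"), inherits(female, "two_by_two"))
  if (male$total_a + male$total_b + female$total_a + female$total_b == 0L)
    stop("at least one stratum must have positive totals", call. = FALSE)
  structure(list(male = male, female = female,
                 line_id = as.character(line_id),
                 zygosity = as.character(zygosity),
                 trait_id = as.character(trait_id)),
            class = "sex_counts")
}

#' @export
print.sex_counts <- function(x, ...) {
  cat(sprintf("Sex-stratified counts: line %s (%s), trait %s\n",
              x$line_id, x$zygosity, x$trait_id))
  cat("Males:\n"); print(x$male)
  cat("Females:\n"); print(x$female)
  invisible(x)
}

# convenience constructor from eight raw counts
#' Build sex-stratified counts from raw cell counts
#'
#' @param ko_male,wt_male,ko_female,wt_female length-2 vectors
#'   `c(events, total)` for each sex-by-group cell.
#' @inheritParams sex_counts
#' @return A [sex_counts()] object.
#' @export
make_dataset <- function(ko_male, wt_male, ko_female, wt_female,
                         line_id = NA_character_, zygosity = NA_character_,
                         trait_id = NA_character_) {
  sex_counts(male = two_by_two(ko_male[1], ko_male[2], wt_male[1], wt_male[2]),
             female = two_by_two(ko_female[1], ko_female[2],
                                 wt_female[1], wt_female[2]),
             line_id = line_id, zygosity = zygosity, trait_id = trait_id)
}

# stratum is "present" when it contains any animal
.stratum_present <- function(t) (t$total_a + t$total_b) > 0L

.dataset_id <- function(d) paste(d$line_id, d$zygosity, d$trait_id, sep = ":")

# knockout-only 2x2 (sex x outcome): group a = male KO, group b = female KO
.ko_table <- function(d) {
  two_by_two(d$male$events_a, d$male$total_a,
             d$female$events_a, d$female$total_a)
}
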