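#' Evidence records and the scoring rubric
#'
#' Each literature finding is one *evidence record*: a pathogen, a climate
#' driver, and a signed strength score on the rubric grid. Positive scores
#' support sensitivity of the pathogen to the driver; negative scores encode
#' contradicting evidence of the same strength. The default grid is
#' `c(5, 20, 40, 60, 80)` together with its negative mirror.
#'
#' @name evidence
NULL

#' Default rubric grid of evidence-strength scores
#' @return numeric vector of the positive grid values.
#' @export
rubric_grid <- function() c(5, 20, 40, 60, 80)

#' Validate a table of evidence records
#'
#' Checks the schema (columns `pathogen_id`, `driver`, `score`, and optionally
#' `source_id`), canonicalises driver labels against the vocabulary, and
#' checks every score lies on the rubric grid or its negation.
#'
#' @param records data frame of evidence records.
#' @param grid positive rubric grid; scores must be in `c(grid, -grid)`.
#' @param vocab driver vocabulary, see [driver_vocabulary()].
#' @return the validated records, with `driver` canonicalised.
#' @export
validate_evidence <- function(records, grid = rubric_grid(),
                              vocab = default_vocabulary()) {
  need <- c("pathogen_id", "driver", "score")
  if (!all(need %in% names(records)))
    validation_error(paste("evidence table must have columns",
                           paste(need, collapse = ", ")))
  if (nrow(records)) {
    records$driver <- normalise_driver(records$driver, vocab)
    bad <- !(records$score %in% c(grid, -grid))
    if (any(bad))
      validation_error(sprintf(
        "score(s) off the rubric grid: %s",
        paste(unique(records$score[bad]), collapse = ", ")))
  }
  records
}

#' Read an evidence-record CSV
#'
#' Expected columns: `pathogen_id, driver, score, source_id` (header
#' mandatory, UTF-8, "." decimal separator).
#'
#' @param path CSV file path.
#' @inheritParams validate_evidence
#' @return validated evidence data frame.
#' @export
read_evidence <- function(path, grid = rubric_grid(),
                          vocab = default_vocabulary()) {
  validate_evidence(utils::read.csv(path, stringsAsFactors = FALSE),
                    grid = grid, vocab = vocab)
}

#' Median of a multiset of signed evidence scores
#'
#' The standard sample median: the middle order statistic for odd counts, the
#' arithmetic mean of the two middle order statistics for even counts.
#' Sensitivity is defined downstream as a *strictly positive* median, so a
#' median of exactly zero (e.g. from `c(-60, 60)`) is not positive evidence.
#'
#' @param scores non-empty numeric vector.
#' @return numeric scalar.
#' @examples
#' median_score(c(5, 40))   # 22.5
#' median_score(c(-20, 40, 80))
#' @export
median_score <- function(scores) {
  if (length(scores) == 0) value_error("median_score: empty score set")
  if (anyNA(scores)) value_error("median_score: NA score")
  stats::median(scores)
}

#' Aggregate evidence records to per-(pathogen, driver) median scores
#'
#' One median per (pathogen, driver) pair that has at least one record; pairs
#' with no records are absent from the output, which is distinct from a
#' non-positive median (both count as "not sensitive" downstream).
#'
#' @param records evidence data frame (validated with [validate_evidence()]).
#' @param grid,vocab passed to [validate_evidence()].
#' @return data frame with columns `pathogen_id`, `driver`, `median_score`,
#'   `n_records`, `positive` (0/1, strict positivity).
#' @export
aggregate_evidence <- function(records, grid = rubric_grid(),
                               vocab = default_vocabulary()) {
  records <- validate_evidence(records, grid = grid, vocab = vocab)
  if (!nrow(records)) {
    return(data.frame(pathogen_id = character(0), driver = character(0),
                      median_score = numeric(0), n_records = integer(0),
                      positive = integer(0)))
  }
  key <- interaction(records$pathogen_id, records$driver, drop = TRUE,
                     sep = "\r")
  med <- tapply(records$score, key, median_score)
  n <- tapply(records$score, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    pathogen_id = vapply(parts, `[`, character(1), 1L),
    driver = vapply(parts, `[`, character(1), 2L),
    median_score = as.numeric(med),
    n_records = as.integer(n),
    stringsAsFactors = FALSE
  )
  out$positive <- as.integer(out$median_score > 0)
  out <- out[order(out$pathogen_id, out$driver), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-pathogen sensitivity profiles
#'
#' A pathogen's *sensitivity profile* is the set of climate drivers with
#' strictly positive median evidence, plus derived counts and
#' primary/secondary flags. The roster must cover every pathogen under
#' assessment, including those with no literature records at all: these get
#' `n_drivers = 0`.
#'
#' @param medians output of [aggregate_evidence()].
#' @param roster character vector of all pathogen ids under assessment.
#' @param vocab driver vocabulary.
#' @return a `climsens_profiles` data frame with columns `pathogen_id`,
#'   `n_drivers`, `has_primary`, `has_secondary`, `drivers` (semicolon-joined
#'   short codes), and a list column `positive_drivers` of canonical driver
#'   names. The full median table is kept in `attr(, "medians")`.
#' @examples
#' rec <- data.frame(pathogen_id = "P1", driver = c("rainfall", "rainfall"),
#'                   score = c(20, 80))
#' build_profiles(aggregate_evidence(rec), roster = c("P1", "P2"))
#' @export
build_profiles <- function(medians, roster, vocab = default_vocabulary()) {
  roster <- as.character(roster)
  if (anyDuplicated(roster))
    validation_error("roster contains duplicate pathogen ids")
  extra <- setdiff(unique(medians$pathogen_id), roster)
  if (length(extra))
    consistency_error(sprintf(
      "medians reference pathogen(s) absent from roster: %s",
      paste(extra, collapse = ", ")))

  pos <- medians[medians$positive == 1, , drop = FALSE]
  by_path <- split(pos$driver, factor(pos$pathogen_id, levels = roster))
  primset <- primary_drivers()
  secset <- secondary_drivers()

  drivers_list <- lapply(by_path, function(d) sort(unique(d)))
  prof <- data.frame(
    pathogen_id = roster,
    n_drivers = vapply(drivers_list, length, integer(1), USE.NAMES = FALSE),
    has_primary = vapply(drivers_list, function(d) any(d %in% primset),
                         logical(1), USE.NAMES = FALSE),
    has_secondary = vapply(drivers_list, function(d) any(d %in% secset),
                           logical(1), USE.NAMES = FALSE),
    drivers = vapply(drivers_list, function(d)
      format_driver_codes(d, vocab, sep = ";"), character(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  prof$positive_drivers <- unname(drivers_list)
  rownames(prof) <- NULL
  attr(prof, "medians") <- medians
  class(prof) <- c("climsens_profiles", "data.frame")
  prof
}

#' One-call profile construction from raw records
#'
#' Convenience wrapper: validate, aggregate, and profile.
#'
#' @inheritParams aggregate_evidence
#' @inheritParams build_profiles
#' @return see [build_profiles()].
#' @export
sensitivity_profiles <- function(records, roster, grid = rubric_grid(),
                                 vocab = default_vocabulary()) {
  build_profiles(aggregate_evidence(records, grid, vocab), roster, vocab)
}

#' @export
print.climsens_profiles <- function(x, ...) {
  n <- nrow(x)
  ns <- sum(x$n_drivers >= 1)
  cat("Climate-sensitivity profiles\n")
  cat(sprintf("  %d pathogens; %d (%.1f%%) with positive evidence for >= 1 driver\n",
              n, ns, if (n) 100 * ns / n else 0))
  if (ns) {
    cat(sprintf("  %d with primary drivers, %d with secondary drivers\n",
                sum(x$has_primary), sum(x$has_secondary)))
  }
  invisible(x)
}

#' Write profile outputs as CSV
#'
#' Writes the per-pair median table (`pathogen_id, driver, median_score,
#' positive`) and the profile summary (`pathogen_id, n_drivers, has_primary,
#' has_secondary, drivers`).
#'
#' @param profiles a `climsens_profiles` object.
#' @param medians_path,summary_path output file paths (either may be `NULL`
#'   to skip).
#' @return invisibly, the profiles.
#' @export
write_profiles <- function(profiles, medians_path = NULL, summary_path = NULL) {
  if (!is.null(medians_path)) {
    med <- attr(profiles, "medians")
    utils::write.csv(med[, c("pathogen_id", "driver", "median_score",
                             "positive")],
                     medians_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    cols <- c("pathogen_id", "n_drivers", "has_primary", "has_secondary",
              "drivers")
    utils::write.csv(as.data.frame(profiles)[, cols], summary_path,
                     row.names = FALSE)
  }
  invisible(profiles)
}
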