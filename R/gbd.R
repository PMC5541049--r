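#' Disease-burden tables
#'
#' A burden table holds, per disease: all-ages DALYs (thousands), the climate
#' drivers with positive median evidence for its constituent pathogen(s), the
#' corresponding median scores, and the taxon code(s) of the main
#' pathogen(s). Where a disease has two constituent pathogens, a driver's
#' score cell joins their medians with `" + "` (e.g. `"40 + 12.5"`); the
#' disease is counted once and is sensitive to a driver if *any* constituent
#' pathogen's median for it is positive.
#'
#' The 2010 Global Burden of Disease working table for the 25 assessed
#' high-impact human infectious diseases ships with the package:
#' `system.file("extdata", "gbd_burden_2010.csv", package = "climsens")`.
#'
#' @name burden
NULL

parse_score_cell <- function(cell) {
  cell <- squish(cell %||% "")
  if (is.na(cell) || cell == "" || grepl("^[-–—]+$", cell))
    return(list())
  entries <- strsplit(cell, ",", fixed = TRUE)[[1]]
  lapply(entries, function(e) {
    vals <- suppressWarnings(as.numeric(squish(strsplit(e, "+",
                                                        fixed = TRUE)[[1]])))
    if (anyNA(vals))
      validation_error(sprintf("unparseable score entry '%s'", squish(e)))
    vals
  })
}

format_score_cell <- function(scores) {
  if (!length(scores)) return("")
  paste(vapply(scores, function(v) paste(v, collapse = " + "), character(1)),
        collapse = ", ")
}

#' Parse a disease-burden CSV into validated rows
#'
#' Expected columns: `disease`, `dalys_thousands`, `drivers` (comma-separated
#' driver codes, empty for no positive drivers), `scores` (comma-separated
#' median scores aligned with `drivers`, `" + "`-joined where a disease has
#' two constituent pathogens), `taxon` (codes among B, P, V). Driver and
#' score cells must have matching arity; every listed median must be
#' positive (the table lists positive-evidence drivers only).
#'
#' @param path CSV file path, or a data frame already in that shape.
#' @param vocab driver vocabulary.
#' @return a `burden_table` data frame with parsed list columns
#'   `driver_names` and `driver_medians`.
#' @examples
#' tab <- read_burden_table(system.file("extdata", "gbd_burden_2010.csv",
#'                                      package = "climsens"))
#' nrow(tab)  # 25 diseases
#' @export
read_burden_table <- function(path, vocab = default_vocabulary()) {
  raw <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = "character")
  need <- c("disease", "dalys_thousands", "drivers", "scores", "taxon")
  if (!all(need %in% names(raw)))
    validation_error(paste("burden table must have columns",
                           paste(need, collapse = ", ")))
  raw$dalys_thousands <- as.numeric(raw$dalys_thousands)
  if (anyNA(raw$dalys_thousands) || any(raw$dalys_thousands < 0))
    validation_error("dalys_thousands must be non-negative numbers")

  driver_names <- vector("list", nrow(raw))
  driver_medians <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    drivers <- parse_driver_codes(raw$drivers[i], vocab)
    scores <- parse_score_cell(raw$scores[i])
    if (length(drivers) != length(scores))
      validation_error(sprintf(
        "row '%s': %d driver code(s) but %d score entr(ies)",
        raw$disease[i], length(drivers), length(scores)))
    if (length(scores) && any(unlist(scores) <= 0))
      validation_error(sprintf(
        "row '%s': burden tables list positive medians only", raw$disease[i]))
    driver_names[[i]] <- drivers
    names(scores) <- drivers
    driver_medians[[i]] <- scores
  }
  out <- data.frame(disease = raw$disease,
                    dalys_thousands = raw$dalys_thousands,
                    taxon = squish(raw$taxon),
                    stringsAsFactors = FALSE)
  out$driver_names <- driver_names
  out$driver_medians <- driver_medians
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Format parsed burden rows back to CSV cells
#'
#' Inverse of [read_burden_table()]'s cell parsing; round-trips any valid
#' table.
#'
#' @param tab a `burden_table`.
#' @param vocab driver vocabulary.
#' @return data frame with character columns `disease`, `dalys_thousands`,
#'   `drivers`, `scores`, `taxon`.
#' @export
format_burden_table <- function(tab, vocab = default_vocabulary()) {
  data.frame(
    disease = tab$disease,
    dalys_thousands = as.character(tab$dalys_thousands),
    drivers = vapply(tab$driver_names, format_driver_codes, character(1),
                     vocab = vocab),
    scores = vapply(tab$driver_medians, format_score_cell, character(1)),
    taxon = tab$taxon,
    stringsAsFactors = FALSE
  )
}

#' Classify a disease's climate sensitivity
#'
#' `"primary"` if any positive driver is primary-class; `"secondary_only"` if
#' the disease has positive drivers but none primary; `"none"` otherwise.
#'
#' @param drivers character vector of positive driver names (one disease).
#' @param vocab driver vocabulary.
#' @return `"none"`, `"secondary_only"` or `"primary"`.
#' @examples
#' classify_disease("altitude")             # secondary_only
#' classify_disease(c("altitude", "wind"))  # primary
#' @export
classify_disease <- function(drivers, vocab = default_vocabulary()) {
  if (!length(drivers)) return("none")
  cls <- classify_driver(drivers, vocab)
  if (any(cls == "primary")) "primary" else "secondary_only"
}

#' Attribute DALY burden to climate-sensitive diseases
#'
#' Classifies each disease ([classify_disease()]), sums DALYs over the
#' climate-sensitive and primary-sensitive subsets, and expresses each
#' disease's burden relative to the all-cause DALY total. Fractions are
#' computed on unrounded sums; the printed relative-impact column is the
#' ratio x 100 rounded to 2 dp.
#'
#' @param tab a `burden_table` (see [read_burden_table()]).
#' @param all_cause_total all-cause DALYs in the same units (thousands);
#'   default the 2010 GBD all-cause total, 2,490,385.
#' @return a `burden_report` list: counts (`n_diseases`, `n_any_driver`,
#'   `n_primary`, `n_secondary_only`), DALY sums (`total_dalys`,
#'   `sensitive_dalys`, `primary_sensitive_dalys`), fractions
#'   (`fraction_sensitive`, `fraction_primary_sensitive` of the table total),
#'   `relative_impacts` (named ratios to `all_cause_total`) and a per-disease
#'   `table` with the classification.
#' @examples
#' tab <- read_burden_table(system.file("extdata", "gbd_burden_2010.csv",
#'                                      package = "climsens"))
#' attribute_burden(tab)
#' @export
attribute_burden <- function(tab, all_cause_total = 2490385) {
  if (!nrow(tab)) value_error("burden table has no rows")
  if (all_cause_total <= 0) value_error("all_cause_total must be positive")
  cls <- vapply(tab$driver_names, classify_disease, character(1))
  sensitive <- cls != "none"
  primary <- cls == "primary"

  per_disease <- data.frame(
    disease = tab$disease,
    dalys_thousands = tab$dalys_thousands,
    classification = cls,
    relative_impact_pct = round(100 * tab$dalys_thousands / all_cause_total, 2),
    n_drivers = lengths(tab$driver_names),
    stringsAsFactors = FALSE
  )

  structure(list(
    n_diseases = nrow(tab),
    n_any_driver = sum(sensitive),
    n_primary = sum(primary),
    n_secondary_only = sum(cls == "secondary_only"),
    total_dalys = sum(tab$dalys_thousands),
    sensitive_dalys = sum(tab$dalys_thousands[sensitive]),
    primary_sensitive_dalys = sum(tab$dalys_thousands[primary]),
    fraction_sensitive = sum(tab$dalys_thousands[sensitive]) /
      sum(tab$dalys_thousands),
    fraction_primary_sensitive = sum(tab$dalys_thousands[primary]) /
      sum(tab$dalys_thousands),
    relative_impacts = stats::setNames(tab$dalys_thousands / all_cause_total,
                                       tab$disease),
    all_cause_total = all_cause_total,
    table = per_disease
  ), class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat("Climate-sensitivity burden attribution\n")
  cat(sprintf("  diseases: %d; climate-sensitive: %d (%s%%); with primary drivers: %d (%s%%)\n",
              x$n_diseases, x$n_any_driver,
              pct(x$n_any_driver, x$n_diseases),
              x$n_primary, pct(x$n_primary, x$n_diseases)))
  cat(sprintf("  secondary-only: %d (%s)\n", x$n_secondary_only,
              paste(x$table$disease[x$table$classification == "secondary_only"],
                    collapse = ", ")))
  cat(sprintf("  DALY share of the %d-disease total: sensitive %.1f%%, primary-sensitive %.1f%%\n",
              x$n_diseases, 100 * x$fraction_sensitive,
              100 * x$fraction_primary_sensitive))
  cat(sprintf("  totals (thousand DALYs): all %s, sensitive %s, primary %s\n",
              format(x$total_dalys, big.mark = ","),
              format(x$sensitive_dalys, big.mark = ","),
              format(x$primary_sensitive_dalys, big.mark = ",")))
  invisible(x)
}
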