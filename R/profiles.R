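#' Read and validate a pathogen-attribute table
#'
#' Expected CSV columns: `pathogen_id`, `taxon`, `routes` (semicolon-joined
#' transmission routes), `host_class`, `emerging` (0/1), `h_index`,
#' `n_countries`. Every pathogen must have at least one transmission route;
#' `host_class = "unknown"` is allowed and is dropped listwise by the zoonotic
#' analyses.
#'
#' @param path CSV file path.
#' @param n_countries_max number of European countries in scope; `n_countries`
#'   may not exceed it.
#' @return validated attribute data frame with a list column `route_list`.
#' @export
read_attributes <- function(path, n_countries_max = 34) {
  validate_attributes(utils::read.csv(path, stringsAsFactors = FALSE),
                      n_countries_max = n_countries_max)
}

#' @rdname read_attributes
#' @param attributes attribute data frame (as from the CSV).
#' @export
validate_attributes <- function(attributes, n_countries_max = 34) {
  need <- c("pathogen_id", "taxon", "routes", "host_class", "emerging",
            "h_index", "n_countries")
  if (!all(need %in% names(attributes)))
    validation_error(paste("attribute table must have columns",
                           paste(need, collapse = ", ")))
  if (anyDuplicated(attributes$pathogen_id))
    validation_error("duplicate pathogen_id in attribute table")
  bad_taxon <- setdiff(unique(attributes$taxon), pathogen_taxa())
  if (length(bad_taxon))
    vocab_error(sprintf("unknown taxon: %s", paste(bad_taxon, collapse = ", ")))
  bad_host <- setdiff(unique(attributes$host_class), host_classes())
  if (length(bad_host))
    vocab_error(sprintf("unknown host class: %s",
                        paste(bad_host, collapse = ", ")))
  route_list <- lapply(strsplit(as.character(attributes$routes), ";",
                                fixed = TRUE),
                       function(r) squish(r[squish(r) != ""]))
  bad_route <- setdiff(unique(unlist(route_list)), transmission_routes())
  if (length(bad_route))
    vocab_error(sprintf("unknown transmission route: %s",
                        paste(bad_route, collapse = ", ")))
  if (any(lengths(route_list) == 0))
    validation_error("every pathogen must have at least one transmission route")
  if (any(attributes$h_index < 0) || any(attributes$n_countries < 0))
    validation_error("h_index and n_countries must be non-negative")
  if (any(attributes$n_countries > n_countries_max))
    validation_error(sprintf("n_countries exceeds the configured maximum (%d)",
                             n_countries_max))
  attributes$emerging <- as.integer(attributes$emerging)
  if (!all(attributes$emerging %in% c(0L, 1L)))
    validation_error("emerging must be 0/1")
  attributes$route_list <- route_list
  attributes
}

#' Descriptive summary of a pathogen cohort
#'
#' Counts over a set of sensitivity profiles: how many pathogens are
#' climate-sensitive (positive median evidence for at least one driver), the
#' histogram of per-pathogen driver counts, the primary/secondary split,
#' per-driver frequencies among sensitive pathogens, and co-occurrence counts
#' for every unordered driver pair. Percentages are derived on demand, never
#' stored.
#'
#' @param profiles a `climsens_profiles` object (see [build_profiles()]).
#' @param attributes optional attribute table keyed by the same roster; only
#'   needed when `filter` uses attributes or for [breakdown_by()].
#' @param filter optional predicate: either a logical vector along the roster
#'   or a function taking the merged profile+attribute data frame and
#'   returning one.
#' @return a `cohort_summary` list with fields `n_total`, `n_sensitive`,
#'   `driver_count_histogram`, `n_has_primary`, `n_has_secondary`,
#'   `n_secondary_only`, `driver_frequency`, `pair_counts`.
#' @export
cohort_summary <- function(profiles, attributes = NULL, filter = NULL) {
  df <- as.data.frame(profiles)
  if (!is.null(attributes)) {
    if (!setequal(attributes$pathogen_id, df$pathogen_id))
      consistency_error("profiles and attributes cover different rosters")
    attributes <- attributes[match(df$pathogen_id, attributes$pathogen_id), ,
                             drop = FALSE]
    df <- cbind(df, attributes[, setdiff(names(attributes), "pathogen_id"),
                               drop = FALSE])
  }
  keep <- rep(TRUE, nrow(df))
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(df) else filter
    if (!is.logical(keep) || length(keep) != nrow(df))
      value_error("filter must yield one logical per pathogen")
    keep[is.na(keep)] <- FALSE
  }
  df <- df[keep, , drop = FALSE]

  n_total <- nrow(df)
  sens <- df$n_drivers >= 1
  n_sensitive <- sum(sens)
  kmax <- if (n_total) max(df$n_drivers) else 0
  hist <- tabulate(df$n_drivers + 1L, nbins = kmax + 1L)
  names(hist) <- 0:kmax

  n_has_primary <- sum(df$has_primary)
  n_has_secondary <- sum(df$has_secondary)
  n_both <- sum(df$has_primary & df$has_secondary)

  freq <- integer(length(climate_drivers()))
  names(freq) <- sort(climate_drivers())
  pos <- unlist(df$positive_drivers[sens])
  if (length(pos)) {
    tb <- table(pos)
    freq[names(tb)] <- as.integer(tb)
  }

  pairs <- list()
  for (d in df$positive_drivers[sens]) {
    if (length(d) >= 2) {
      cmb <- utils::combn(sort(d), 2)
      for (j in seq_len(ncol(cmb))) {
        key <- paste(cmb[, j], collapse = " & ")
        pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
      }
    }
  }
  pair_counts <- unlist(pairs) %||% integer(0)
  if (length(pair_counts))
    pair_counts <- pair_counts[order(names(pair_counts))]

  structure(list(
    n_total = n_total,
    n_sensitive = n_sensitive,
    driver_count_histogram = hist,
    n_has_primary = n_has_primary,
    n_has_secondary = n_has_secondary,
    n_secondary_only = n_has_secondary - n_both,
    driver_frequency = freq,
    pair_counts = pair_counts
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  pathogens: %d; climate-sensitive: %d (%s%%)\n",
              x$n_total, x$n_sensitive, pct(x$n_sensitive, x$n_total)))
  if (x$n_sensitive) {
    cat(sprintf("  of sensitive: %d (%s%%) with primary drivers, %d (%s%%) with secondary\n",
                x$n_has_primary, pct(x$n_has_primary, x$n_sensitive),
                x$n_has_secondary, pct(x$n_has_secondary, x$n_sensitive)))
    cat(sprintf("  secondary-only: %d\n", x$n_secondary_only))
    top <- utils::head(driver_frequencies(x), 4)
    cat("  most frequent drivers:",
        paste(sprintf("%s (%d)", top$driver, top$count), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Driver frequencies among sensitive pathogens, ranked
#'
#' @param summary a `cohort_summary`.
#' @return data frame `driver`, `count`, descending by count, ties broken
#'   alphabetically by driver name.
#' @export
driver_frequencies <- function(summary) {
  f <- summary$driver_frequency
  out <- data.frame(driver = names(f), count = as.integer(f),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$driver), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Driver co-occurrence counts among sensitive pathogens, ranked
#'
#' A pair's count is the number of sensitive pathogens whose positive driver
#' set contains both drivers; a pathogen with k drivers contributes to
#' choose(k, 2) pairs.
#'
#' @param summary a `cohort_summary`.
#' @return data frame `driver1`, `driver2`, `count`, descending by count, ties
#'   alphabetical.
#' @export
driver_pairs <- function(summary) {
  pc <- summary$pair_counts
  if (!length(pc))
    return(data.frame(driver1 = character(0), driver2 = character(0),
                      count = integer(0)))
  parts <- strsplit(names(pc), " & ", fixed = TRUE)
  out <- data.frame(
    driver1 = vapply(parts, `[`, character(1), 1L),
    driver2 = vapply(parts, `[`, character(1), 2L),
    count = as.integer(pc),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$driver1, out$driver2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort summaries broken down by taxon or transmission route
#'
#' Taxa partition the cohort; transmission routes do not -- a pathogen with
#' several routes appears in each of its routes' summaries, so route totals
#' sum to the total number of (pathogen, route) memberships.
#'
#' @param profiles a `climsens_profiles` object.
#' @param attributes attribute table for the same roster.
#' @param facet `"taxon"` or `"route"`.
#' @return named list of `cohort_summary`, one per facet level (all levels of
#'   the controlled vocabulary, including empty ones).
#' @export
breakdown_by <- function(profiles, attributes, facet = c("taxon", "route")) {
  facet <- tryCatch(match.arg(facet),
                    error = function(e) value_error(
                      sprintf("unknown facet '%s'", facet[1])))
  if (facet == "taxon") {
    levels <- pathogen_taxa()
    sel <- function(df, lev) df$taxon == lev
  } else {
    levels <- transmission_routes()
    sel <- function(df, lev)
      vapply(df$route_list, function(r) lev %in% r, logical(1))
  }
  out <- lapply(levels, function(lev)
    cohort_summary(profiles, attributes, filter = function(df) sel(df, lev)))
  names(out) <- levels
  out
}

#' Plot a cohort's driver-count histogram and driver frequencies
#'
#' Base-graphics convenience mirroring the usual presentation of these
#' summaries (driver-count frequency histogram; per-driver frequency bars).
#'
#' @param x a `cohort_summary`.
#' @param which `"counts"` (histogram of number of drivers per pathogen) or
#'   `"drivers"` (frequency of each driver among sensitive pathogens).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.cohort_summary <- function(x, which = c("counts", "drivers"), ...) {
  which <- match.arg(which)
  if (which == "counts") {
    graphics::barplot(x$driver_count_histogram,
                      xlab = "number of climate drivers",
                      ylab = "pathogens", ...)
  } else {
    f <- driver_frequencies(x)
    graphics::barplot(stats::setNames(f$count, f$driver), las = 2,
                      ylab = "sensitive pathogens", ...)
  }
}
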