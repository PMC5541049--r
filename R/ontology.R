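#' Controlled vocabularies: climate drivers, taxa, transmission routes, hosts
#'
#' The assessment scores literature evidence against eleven climate-driver
#' sets. Seven are *primary* drivers -- climate variables themselves, expected
#' to change under climate change (climate change, oscillations, extreme
#' weather events, moisture, rainfall, temperature, wind) -- and four are
#' *secondary* drivers, i.e. combinations, consequences or proxies of primary
#' drivers (altitude, vegetation, particulate matter, salinity). Each driver
#' has a short code used in burden tables (CC, O, EWE, M, R, T, W, Alt, V, P,
#' S).
#'
#' `driver_vocabulary()` returns the vocabulary as a data frame with columns
#' `driver`, `code` and `class`. The default is shipped as a packaged CSV and
#' can be overridden with a YAML file (keys `driver`, `code`, `class`, one
#' entry per driver) for sensitivity analyses that regroup the driver sets.
#'
#' @param config optional path to a YAML file overriding the packaged
#'   vocabulary. The file must define a list of records with fields
#'   `driver`, `code` and `class` (`"primary"` or `"secondary"`).
#' @return data frame with columns `driver`, `code`, `class`.
#' @examples
#' driver_vocabulary()
#' @export
driver_vocabulary <- function(config = NULL) {
  if (is.null(config)) {
    path <- system.file("extdata", "climate_drivers.csv", package = "climsens",
                        mustWork = TRUE)
    vocab <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    raw <- yaml::read_yaml(config)
    vocab <- do.call(rbind, lapply(raw, function(r)
      data.frame(driver = r$driver, code = r$code, class = r$class,
                 stringsAsFactors = FALSE)))
  }
  validate_vocabulary(vocab)
  vocab
}

validate_vocabulary <- function(vocab) {
  need <- c("driver", "code", "class")
  if (!all(need %in% names(vocab)))
    validation_error("vocabulary must have columns driver, code, class")
  if (anyDuplicated(tolower(vocab$driver)) || anyDuplicated(tolower(vocab$code)))
    validation_error("vocabulary driver names and codes must be unique")
  if (!all(vocab$class %in% c("primary", "secondary")))
    validation_error("vocabulary class must be 'primary' or 'secondary'")
  invisible(vocab)
}

# Cache the packaged vocabulary: looked up on every parse call.
.vocab_cache <- new.env(parent = emptyenv())

default_vocabulary <- function() {
  if (is.null(.vocab_cache$vocab)) .vocab_cache$vocab <- driver_vocabulary()
  .vocab_cache$vocab
}

#' @rdname driver_vocabulary
#' @export
climate_drivers <- function() default_vocabulary()$driver

#' @rdname driver_vocabulary
#' @export
primary_drivers <- function() {
  v <- default_vocabulary()
  v$driver[v$class == "primary"]
}

#' @rdname driver_vocabulary
#' @export
secondary_drivers <- function() {
  v <- default_vocabulary()
  v$driver[v$class == "secondary"]
}

#' The eight transmission routes recognised by the assessment
#' @return character vector of route names.
#' @export
transmission_routes <- function() {
  c("airborne", "direct nonsexual contact", "fomite", "foodborne",
    "sexual direct contact", "soilborne", "vector-borne", "waterborne")
}

#' The five pathogen taxa recognised by the assessment
#' @return character vector of taxon names.
#' @export
pathogen_taxa <- function() {
  c("bacteria", "fungi", "helminths", "protozoa", "viruses")
}

#' Host classes (zoonotic status)
#'
#' `"unknown"` is permitted: analyses of zoonotic status drop pathogens with
#' unknown host class by listwise deletion.
#' @return character vector of host-class labels.
#' @export
host_classes <- function() {
  c("human-only", "animal-only", "zoonotic", "unknown")
}

# Resolve one label (driver name or code, case-insensitive, trimmed; a
# trailing plural "s" on a code such as "EWEs" is tolerated) to a vocabulary
# row index. Errors name the offending token.
match_driver <- function(label, vocab = default_vocabulary()) {
  tok <- squish(label)
  low <- tolower(tok)
  i <- match(low, tolower(vocab$driver))
  if (is.na(i)) i <- match(low, tolower(vocab$code))
  if (is.na(i) && grepl("s$", low))
    i <- match(sub("s$", "", low), tolower(vocab$code))
  if (is.na(i))
    vocab_error(sprintf("unknown climate driver label: '%s'", tok))
  i
}

#' Classify a climate driver as primary or secondary
#'
#' Accepts a driver name or its short code, case-insensitively.
#'
#' @param label driver name (e.g. `"rainfall"`) or code (e.g. `"Alt"`);
#'   vectorised.
#' @param vocab vocabulary data frame, see [driver_vocabulary()].
#' @return character vector, `"primary"` or `"secondary"`.
#' @examples
#' classify_driver("rainfall")
#' classify_driver(c("Alt", "RAINFALL"))
#' @export
classify_driver <- function(label, vocab = default_vocabulary()) {
  vapply(label, function(l) vocab$class[match_driver(l, vocab)], character(1),
         USE.NAMES = FALSE)
}

#' Canonicalise driver labels to vocabulary driver names
#'
#' @inheritParams classify_driver
#' @return character vector of canonical driver names.
#' @export
normalise_driver <- function(label, vocab = default_vocabulary()) {
  vapply(label, function(l) vocab$driver[match_driver(l, vocab)], character(1),
         USE.NAMES = FALSE)
}

#' Parse a comma-separated cell of driver codes
#'
#' Burden tables list each disease's positive climate drivers as a cell of
#' comma-separated short codes, e.g. `"CC, EWE, M"`. Parsing preserves input
#' order, rejects unknown codes (vocabulary error) and duplicates (validation
#' error). An empty cell yields an empty driver list.
#'
#' @param cell character scalar, e.g. `"CC, EWE, M"`; `""`, `"-"`, `"--"` and
#'   em-dash placeholders denote no drivers.
#' @param vocab vocabulary data frame.
#' @return character vector of canonical driver names, in input order.
#' @examples
#' parse_driver_codes("CC, EWE, M, O, P, R, S, T, W")
#' parse_driver_codes("")
#' @export
parse_driver_codes <- function(cell, vocab = default_vocabulary()) {
  if (length(cell) != 1L) value_error("parse_driver_codes expects one cell")
  cell <- squish(cell %||% "")
  if (is.na(cell) || cell == "" || grepl("^[-–—]+$", cell))
    return(character(0))
  toks <- squish(strsplit(cell, ",", fixed = TRUE)[[1]])
  toks <- toks[toks != ""]
  drivers <- vapply(toks, function(t) vocab$driver[match_driver(t, vocab)],
                    character(1), USE.NAMES = FALSE)
  if (anyDuplicated(drivers))
    validation_error(sprintf("duplicate driver code(s) in cell '%s'", cell))
  drivers
}

#' Format a driver list back into a code cell
#'
#' Inverse of [parse_driver_codes()]: `parse_driver_codes(format_driver_codes(x))`
#' is the identity on any duplicate-free driver list.
#'
#' @param drivers character vector of driver names or codes.
#' @param vocab vocabulary data frame.
#' @param sep separator, default `", "`.
#' @return character scalar of short codes.
#' @export
format_driver_codes <- function(drivers, vocab = default_vocabulary(),
                                sep = ", ") {
  if (length(drivers) == 0) return("")
  codes <- vapply(drivers, function(d) vocab$code[match_driver(d, vocab)],
                  character(1), USE.NAMES = FALSE)
  paste(codes, collapse = sep)
}
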