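# Classed conditions so callers can distinguish bad vocabulary from bad data
# shapes; all inherit from "climsens_error".

climsens_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "climsens_error", "error")))
}

vocab_error       <- function(msg) climsens_stop(msg, "climsens_vocab_error")
validation_error  <- function(msg) climsens_stop(msg, "climsens_validation_error")
consistency_error <- function(msg) climsens_stop(msg, "climsens_consistency_error")
value_error       <- function(msg) climsens_stop(msg, "climsens_value_error")
degenerate_error  <- function(msg) climsens_stop(msg, "climsens_degenerate_table_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trim + collapse whitespace; used for all vocabulary matching.
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

stopifnot_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    value_error(sprintf("'%s' must be TRUE or FALSE", what))
  x
}

# Percentage for display only; counts are kept exact internally.
pct <- function(num, den, dp = 1) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, dp)
}
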