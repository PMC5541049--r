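# Independent oracles, deliberately naive: used to cross-check the package's
# computations, never sharing code with them.

# sort-and-pick median
brute_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Pearson chi-square by hand: sum (O - E)^2 / E
chi2_hand <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# expand a 2x2 table of counts into one row per observation
expand_2x2 <- function(a, b, c, d) {
  data.frame(
    exposure = rep(c(1, 1, 0, 0), times = c(a, b, c, d)),
    outcome = rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  )
}

# random 2x2 with all cells positive
random_2x2_cells <- function() sample(1:30, 4, replace = TRUE)

# evidence table from a named list pathogen -> driver -> scores
evidence_from_list <- function(spec) {
  rows <- list()
  for (p in names(spec)) {
    for (d in names(spec[[p]])) {
      for (s in spec[[p]][[d]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathogen_id = p, driver = d, score = s,
          source_id = "t", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# minimal valid attribute rows
make_attributes <- function(ids, taxon = "bacteria", routes = "foodborne",
                            host_class = "zoonotic", emerging = 0L,
                            h_index = seq_along(ids), n_countries = 5L) {
  validate_attributes(data.frame(
    pathogen_id = ids, taxon = taxon, routes = routes,
    host_class = host_class, emerging = emerging, h_index = h_index,
    n_countries = n_countries, stringsAsFactors = FALSE))
}

# generator configuration with every built-in effect switched off
null_synth_config <- function(seed) {
  synth_config(
    zoonotic_sensitivity_or = 1,
    emerging_rain_or = 1,
    emerging_h_top_or = 1,
    country_driver_slope = 0,
    route_driver_boost = stats::setNames(rep(1, 8), transmission_routes()),
    seed = seed)
}
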