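#' Configuration for the synthetic evidence-dataset generator
#'
#' Builds and validates the parameter set for [simulate_study()]. Defaults
#' describe a cohort of 157 high-impact pathogens reviewed against 11 climate
#' drivers, with taxon and transmission-route frequencies, route-dependent
#' driver propensities (vector-borne > soilborne > waterborne > foodborne >
#' contact), a zoonotic-to-sensitivity odds ratio, and a signed rubric-grid
#' score distribution for literature records.
#'
#' The generative model: each pathogen draws a taxon and an independent set
#' of transmission routes (a pathogen drawing none is assigned the most
#' common route, so every pathogen has at least one). A latent
#' (pathogen, driver) sensitivity indicator is Bernoulli with probability
#' `driver_base_rate * driver_weight[driver] * max(route_driver_boost[routes])`,
#' capped at 1. Truly sensitive pairs receive `>= 1` literature records
#' (Poisson, floored at 1) with mostly positive grid scores; insensitive
#' pairs occasionally receive noise records with mostly negative/low scores,
#' so observed median positivity is a noisy measurement of the latent truth.
#' The zoonotic flag is assigned so the latent any-driver log-odds difference
#' equals `log(zoonotic_sensitivity_or)`; the emerging flag depends on latent
#' rainfall sensitivity and top-quartile H-index with configurable odds
#' ratios; reporting-country counts are Poisson with mean increasing in the
#' latent driver count.
#'
#' @param n_pathogens cohort size.
#' @param taxon_mix named probability vector over the five taxa.
#' @param route_propensity named probability, per route, of a pathogen having
#'   that route.
#' @param driver_base_rate baseline probability a (pathogen, driver) pair is
#'   truly sensitive.
#' @param driver_weight named per-driver multiplier on the base rate
#'   (captures that moisture and rainfall evidence is far more common than
#'   oscillations or vegetation evidence).
#' @param route_driver_boost named per-route multiplier on the base rate; a
#'   pathogen's multiplier is the maximum over its routes.
#' @param zoonotic_sensitivity_or target odds ratio linking zoonotic status
#'   to latent any-driver sensitivity.
#' @param zoonotic_base_rate P(zoonotic) among latently insensitive pathogens.
#' @param human_vs_animal among non-zoonotic pathogens, probability of
#'   human-only (vs animal-only).
#' @param n_unknown_host number of pathogens with unknown host class.
#' @param emerging_base_rate baseline P(emerging).
#' @param emerging_rain_or,emerging_h_top_or odds ratios of emergence for
#'   latent rainfall sensitivity and top-quartile H-index.
#' @param records_per_positive_pair Poisson mean record count for sensitive
#'   pairs (floored at 1).
#' @param noise_record_rate probability an insensitive pair has any records.
#' @param score_probs_sensitive,score_probs_insensitive probabilities over
#'   the rubric grid for record magnitudes.
#' @param p_negative_sensitive,p_negative_insensitive probability a record's
#'   score is negative (contradicting evidence).
#' @param h_index_meanlog,h_index_sdlog lognormal parameters for H-indices
#'   (rounded to integers).
#' @param countries_base,country_driver_slope,n_countries_max Poisson mean is
#'   `countries_base + country_driver_slope * latent driver count`, truncated
#'   to `[0, n_countries_max]`.
#' @param grid positive rubric grid.
#' @param seed integer seed; all randomness in [simulate_study()] flows from
#'   it.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(
    n_pathogens = 157,
    taxon_mix = c(bacteria = 60, fungi = 21, helminths = 6, protozoa = 7,
                  viruses = 63) / 157,
    route_propensity = c("airborne" = 53, "direct nonsexual contact" = 81,
                         "fomite" = 34, "foodborne" = 68,
                         "sexual direct contact" = 27, "soilborne" = 5,
                         "vector-borne" = 19, "waterborne" = 28) / 157,
    driver_base_rate = 0.06,
    driver_weight = c("moisture" = 2.10, "rainfall" = 1.95,
                      "temperature" = 1.45, "particulate matter" = 1.30,
                      "extreme weather events" = 1.15, "altitude" = 0.85,
                      "salinity" = 0.65, "wind" = 0.65,
                      "climate change" = 0.50, "oscillations" = 0.20,
                      "vegetation" = 0.20),
    route_driver_boost = c("vector-borne" = 3.2, "soilborne" = 2.0,
                           "waterborne" = 1.8, "foodborne" = 1.5,
                           "airborne" = 1.0, "direct nonsexual contact" = 1.0,
                           "fomite" = 1.0, "sexual direct contact" = 1.0),
    zoonotic_sensitivity_or = 6.0,
    zoonotic_base_rate = 0.20,
    human_vs_animal = 0.5,
    n_unknown_host = 1,
    emerging_base_rate = 0.20,
    emerging_rain_or = 2.75,
    emerging_h_top_or = 3.7,
    records_per_positive_pair = 2,
    noise_record_rate = 0.04,
    score_probs_sensitive = c(0.10, 0.30, 0.25, 0.20, 0.15),
    score_probs_insensitive = c(0.55, 0.30, 0.08, 0.05, 0.02),
    p_negative_sensitive = 0.12,
    p_negative_insensitive = 0.85,
    h_index_meanlog = 3.5,
    h_index_sdlog = 0.8,
    countries_base = 8,
    country_driver_slope = 1.1,
    n_countries_max = 34,
    grid = rubric_grid(),
    seed = 20170802) {
  cfg <- mget(names(formals()))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_pathogens >= 1, "n_pathogens must be >= 1")
  chk(abs(sum(cfg$taxon_mix) - 1) < 1e-9, "taxon_mix must sum to 1")
  chk(setequal(names(cfg$taxon_mix), pathogen_taxa()),
      "taxon_mix must name the five taxa")
  chk(setequal(names(cfg$route_propensity), transmission_routes()),
      "route_propensity must name the eight routes")
  chk(all(cfg$route_propensity >= 0 & cfg$route_propensity <= 1),
      "route_propensity values must be in [0, 1]")
  chk(cfg$driver_base_rate >= 0 && cfg$driver_base_rate <= 1,
      "driver_base_rate must be in [0, 1]")
  chk(setequal(names(cfg$driver_weight), climate_drivers()),
      "driver_weight must name the eleven drivers")
  chk(all(cfg$driver_weight >= 0), "driver_weight values must be >= 0")
  chk(all(cfg$route_driver_boost >= 0), "route_driver_boost values must be >= 0")
  chk(setequal(names(cfg$route_driver_boost), transmission_routes()),
      "route_driver_boost must name the eight routes")
  chk(cfg$zoonotic_sensitivity_or > 0, "zoonotic_sensitivity_or must be > 0")
  for (f in c("zoonotic_base_rate", "human_vs_animal", "emerging_base_rate",
              "noise_record_rate", "p_negative_sensitive",
              "p_negative_insensitive"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, sprintf("%s must be in [0, 1]", f))
  chk(abs(sum(cfg$score_probs_sensitive) - 1) < 1e-9,
      "score_probs_sensitive must sum to 1")
  chk(abs(sum(cfg$score_probs_insensitive) - 1) < 1e-9,
      "score_probs_insensitive must sum to 1")
  chk(length(cfg$score_probs_sensitive) == length(cfg$grid) &&
        length(cfg$score_probs_insensitive) == length(cfg$grid),
      "score probability vectors must match the grid length")
  chk(cfg$records_per_positive_pair > 0,
      "records_per_positive_pair must be > 0")
  chk(cfg$n_unknown_host >= 0 && cfg$n_unknown_host <= cfg$n_pathogens,
      "n_unknown_host must be in [0, n_pathogens]")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single integer")
  if (length(problems))
    validation_error(paste("invalid generator config:",
                           paste(problems, collapse = "; ")))
  invisible(cfg)
}

# Run expr with a private RNG stream seeded from `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-pathogen route multiplier: max boost over the routes present.
route_multiplier <- function(route_mat, boost) {
  bm <- sweep(route_mat, 2, boost[colnames(route_mat)], `*`)
  do.call(pmax, as.data.frame(bm))
}

#' Closed-form expected fraction of latently climate-sensitive pathogens
#'
#' Exact expectation implied by a generator configuration, by enumeration
#' over all 2^8 transmission-route subsets (the generator's fallback for a
#' pathogen drawing no route -- assignment of the most common route -- is
#' accounted for).
#'
#' @param config a `synth_config`.
#' @return numeric scalar in `[0, 1]`.
#' @export
expected_sensitive_fraction <- function(config) {
  routes <- transmission_routes()
  p_route <- config$route_propensity[routes]
  boost <- config$route_driver_boost[routes]
  fallback <- routes[which.max(p_route)]
  p_driver_given_mult <- function(m) {
    p <- pmin(1, config$driver_base_rate * config$driver_weight * m)
    1 - prod(1 - p)
  }
  total <- 0
  for (mask in 0:(2^8 - 1)) {
    present <- as.logical(bitwAnd(mask, 2^(0:7)))
    prob <- prod(ifelse(present, p_route, 1 - p_route))
    mult <- if (any(present)) max(boost[present]) else boost[fallback]
    total <- total + prob * p_driver_given_mult(mult)
  }
  unname(total)
}

#' Generate a synthetic pathogen cohort with literature-evidence records
#'
#' Draws a full synthetic study -- a pathogen-attribute table and an
#' evidence-record table -- from the generative model described in
#' [synth_config()]. Deterministic given the config seed; the caller's RNG
#' state is untouched.
#'
#' @param config a `synth_config`.
#' @return list with elements `attributes` (data frame: `pathogen_id`,
#'   `taxon`, `routes`, `host_class`, `emerging`, `h_index`, `n_countries`,
#'   plus the simulation-truth columns `sensitive_truth` and
#'   `n_drivers_truth`) and `evidence` (data frame: `pathogen_id`, `driver`,
#'   `score`, `source_id`). The config is kept in `attr(, "config")`.
#' @examples
#' sim <- simulate_study(synth_config(n_pathogens = 40, seed = 1))
#' head(sim$evidence)
#' @export
simulate_study <- function(config = synth_config()) {
  validate_synth_config(config)
  with_seed(config$seed, {
    n <- config$n_pathogens
    drivers <- climate_drivers()
    routes <- transmission_routes()
    ids <- sprintf("SP%03d", seq_len(n))

    taxon <- sample(names(config$taxon_mix), n, replace = TRUE,
                    prob = config$taxon_mix)

    route_mat <- matrix(stats::rbinom(n * length(routes), 1,
                                      rep(config$route_propensity[routes],
                                          each = n)) == 1,
                        nrow = n, dimnames = list(NULL, routes))
    fallback <- routes[which.max(config$route_propensity[routes])]
    route_mat[rowSums(route_mat) == 0, fallback] <- TRUE

    mult <- route_multiplier(route_mat, config$route_driver_boost)
    p_pair <- pmin(1, outer(mult, config$driver_base_rate *
                              config$driver_weight[drivers]))
    latent <- matrix(stats::rbinom(length(p_pair), 1, p_pair) == 1,
                     nrow = n, dimnames = list(NULL, drivers))
    n_latent <- rowSums(latent)
    sensitive_truth <- n_latent > 0

    # evidence records: sensitive pairs always reviewed, insensitive pairs
    # only as occasional noise
    noise <- matrix(stats::rbinom(length(latent), 1,
                                  config$noise_record_rate) == 1,
                    nrow = n, dimnames = list(NULL, drivers)) & !latent
    pair_idx <- which(latent | noise, arr.ind = TRUE)
    if (nrow(pair_idx)) {
      is_sens <- latent[pair_idx]
      n_rec <- pmax(1L, stats::rpois(nrow(pair_idx),
                                     ifelse(is_sens,
                                            config$records_per_positive_pair,
                                            1)))
      rec_path <- rep(ids[pair_idx[, 1]], n_rec)
      rec_driver <- rep(drivers[pair_idx[, 2]], n_rec)
      rec_sens <- rep(is_sens, n_rec)
      m <- length(rec_sens)
      mag <- numeric(m)
      mag[rec_sens] <- sample(config$grid, sum(rec_sens), replace = TRUE,
                              prob = config$score_probs_sensitive)
      mag[!rec_sens] <- sample(config$grid, sum(!rec_sens), replace = TRUE,
                               prob = config$score_probs_insensitive)
      neg <- stats::rbinom(m, 1, ifelse(rec_sens,
                                        config$p_negative_sensitive,
                                        config$p_negative_insensitive)) == 1
      evidence <- data.frame(
        pathogen_id = rec_path,
        driver = rec_driver,
        score = ifelse(neg, -mag, mag),
        source_id = sprintf("src%06d", seq_len(m)),
        stringsAsFactors = FALSE
      )
      evidence <- evidence[order(evidence$pathogen_id, evidence$driver), ]
      rownames(evidence) <- NULL
    } else {
      evidence <- data.frame(pathogen_id = character(0), driver = character(0),
                             score = numeric(0), source_id = character(0))
    }

    # zoonotic flag: latent any-driver log-odds difference = log(target OR)
    p_z <- stats::plogis(stats::qlogis(config$zoonotic_base_rate) +
                           log(config$zoonotic_sensitivity_or) *
                             sensitive_truth)
    zoo <- stats::rbinom(n, 1, p_z) == 1
    host_class <- ifelse(zoo, "zoonotic",
                         ifelse(stats::rbinom(n, 1,
                                              config$human_vs_animal) == 1,
                                "human-only", "animal-only"))
    if (config$n_unknown_host > 0)
      host_class[sample.int(n, config$n_unknown_host)] <- "unknown"

    h_index <- as.integer(round(stats::rlnorm(n, config$h_index_meanlog,
                                              config$h_index_sdlog)))
    h_top <- h_index_quartiles(pmax(h_index, 0L)) == 4L

    p_e <- stats::plogis(stats::qlogis(config$emerging_base_rate) +
                           log(config$emerging_rain_or) *
                             latent[, "rainfall"] +
                           log(config$emerging_h_top_or) * h_top)
    emerging <- stats::rbinom(n, 1, p_e)

    n_countries <- pmin(config$n_countries_max,
                        stats::rpois(n, config$countries_base +
                                       config$country_driver_slope * n_latent))

    attributes <- data.frame(
      pathogen_id = ids,
      taxon = taxon,
      routes = apply(route_mat, 1, function(r)
        paste(routes[r], collapse = ";")),
      host_class = host_class,
      emerging = as.integer(emerging),
      h_index = pmax(h_index, 0L),
      n_countries = n_countries,
      sensitive_truth = as.integer(sensitive_truth),
      n_drivers_truth = as.integer(n_latent),
      stringsAsFactors = FALSE
    )
    out <- list(attributes = attributes, evidence = evidence)
    attr(out, "config") <- config
    out
  })
}

#' Generate a synthetic disease-burden table
#'
#' Produces rows in the burden-table schema (disease, DALYs, positive driver
#' codes, median scores with occasional `" + "`-joined two-pathogen cells,
#' taxon code), parseable by [read_burden_table()].
#'
#' @param config a `synth_config` (seed and grid are used).
#' @param n_diseases number of rows, >= 1.
#' @param p_sensitive probability a disease has any positive driver.
#' @param p_two_pathogens probability a driver cell carries medians for two
#'   constituent pathogens.
#' @return data frame with character columns `disease`, `dalys_thousands`,
#'   `drivers`, `scores`, `taxon`.
#' @export
simulate_burden_table <- function(config = synth_config(), n_diseases = 25,
                                  p_sensitive = 0.7, p_two_pathogens = 0.15) {
  if (n_diseases < 1) value_error("n_diseases must be >= 1")
  validate_synth_config(config)
  with_seed(config$seed + 1L, {
    vocab <- default_vocabulary()
    # positive medians reachable on the grid: values and adjacent midpoints
    med_pool <- sort(unique(c(config$grid,
                              (config$grid[-1] + config$grid[-length(config$grid)]) / 2)))
    rows <- lapply(seq_len(n_diseases), function(i) {
      sens <- stats::runif(1) < p_sensitive
      k <- if (sens) sample.int(length(vocab$code), 1) else 0L
      codes <- if (k) sort(sample(vocab$code, k)) else character(0)
      scores <- lapply(seq_len(k), function(j) {
        nsc <- 1L + (stats::runif(1) < p_two_pathogens)
        sample(med_pool, nsc, replace = TRUE)
      })
      data.frame(
        disease = sprintf("Synthetic disease %02d", i),
        dalys_thousands = as.character(round(stats::rlnorm(1, 8, 1.5))),
        drivers = paste(codes, collapse = ", "),
        scores = format_score_cell(scores),
        taxon = sample(c("B", "P", "V"), 1),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Write a simulated study to disk
#'
#' Writes `attributes.csv`, `evidence.csv`, and a `provenance.json` recording
#' the generator configuration, seed and schema version; optionally a
#' synthetic burden table as `burden.csv`.
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @param burden optional data frame from [simulate_burden_table()].
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, burden = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(attributes = file.path(dir, "attributes.csv"),
             evidence = file.path(dir, "evidence.csv"),
             provenance = file.path(dir, "provenance.json"))
  utils::write.csv(sim$attributes, paths[["attributes"]], row.names = FALSE)
  utils::write.csv(sim$evidence, paths[["evidence"]], row.names = FALSE)
  cfg <- attr(sim, "config")
  jsonlite::write_json(
    list(schema_version = "1.0",
         generator = "climsens::simulate_study",
         seed = cfg$seed,
         config = unclass(cfg)),
    paths[["provenance"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(burden)) {
    paths[["burden"]] <- file.path(dir, "burden.csv")
    utils::write.csv(burden, paths[["burden"]], row.names = FALSE)
  }
  invisible(paths)
}
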