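# Hand-built mini-cohort with known structure:
#   A: rainfall+moisture+temperature (primary x3)   B: altitude (secondary)
#   C: rainfall+altitude                            D: none
#   E: moisture+rainfall
mini_cohort <- function() {
  ev <- evidence_from_list(list(
    A = list(rainfall = 40, moisture = 60, temperature = 20),
    B = list(altitude = 80),
    C = list(rainfall = 20, altitude = 40),
    E = list(moisture = 20, rainfall = 20)))
  prof <- sensitivity_profiles(ev, roster = c("A", "B", "C", "D", "E"))
  att <- make_attributes(
    c("A", "B", "C", "D", "E"),
    taxon = c("bacteria", "viruses", "bacteria", "fungi", "helminths"),
    routes = c("foodborne;waterborne", "airborne", "foodborne",
               "airborne", "waterborne"),
    host_class = c("zoonotic", "human-only", "zoonotic", "animal-only",
                   "zoonotic"))
  list(prof = prof, att = att)
}

test_that("cohort summary counts sensitivity, splits and histogram correctly", {
  mc <- mini_cohort()
  s <- cohort_summary(mc$prof, mc$att)
  expect_equal(s$n_total, 5)
  expect_equal(s$n_sensitive, 4)
  expect_equal(s$driver_count_histogram, c("0" = 1, "1" = 1, "2" = 2, "3" = 1))
  expect_equal(s$n_has_primary, 3)
  expect_equal(s$n_has_secondary, 2)
  expect_equal(s$n_secondary_only, 1)
  # identity: primary + secondary-only = sensitive
  expect_equal(s$n_has_primary + s$n_secondary_only, s$n_sensitive)
  expect_equal(unname(s$driver_frequency["rainfall"]), 3L)
  expect_equal(unname(s$driver_frequency["vegetation"]), 0L)
})

test_that("an empty roster yields an all-zero summary", {
  prof <- sensitivity_profiles(
    data.frame(pathogen_id = character(0), driver = character(0),
               score = numeric(0)), roster = character(0))
  s <- cohort_summary(prof)
  expect_equal(s$n_total, 0)
  expect_equal(s$n_sensitive, 0)
  expect_equal(sum(s$driver_frequency), 0)
  expect_length(s$pair_counts, 0)
})

test_that("driver frequencies rank by count with alphabetical ties", {
  mc <- mini_cohort()
  f <- driver_frequencies(cohort_summary(mc$prof, mc$att))
  expect_equal(f$driver[1], "rainfall")     # 3
  expect_equal(f$count[1], 3)
  expect_equal(f$driver[2:3], c("altitude", "moisture"))  # tie at 2
  expect_equal(sum(f$count), sum(mc$prof$n_drivers))
})

test_that("driver pair counts enumerate co-occurrence among sensitive pathogens", {
  mc <- mini_cohort()
  p <- driver_pairs(cohort_summary(mc$prof, mc$att))
  top <- p[p$driver1 == "moisture" & p$driver2 == "rainfall", "count"]
  expect_equal(top, 2)  # A and E
  # A has three drivers -> contributes to exactly choose(3,2) = 3 pairs
  expect_equal(sum(p$count), 3 + 0 + 1 + 1)
})

test_that("pair counts never exceed either marginal frequency", {
  sim <- simulate_study(synth_config(n_pathogens = 100, seed = 21))
  prof <- sensitivity_profiles(sim$evidence, sim$attributes$pathogen_id)
  s <- cohort_summary(prof)
  pairs <- driver_pairs(s)
  for (i in seq_len(nrow(pairs))) {
    expect_lte(pairs$count[i],
               min(s$driver_frequency[pairs$driver1[i]],
                   s$driver_frequency[pairs$driver2[i]]))
  }
})

test_that("taxon breakdown partitions the cohort; route breakdown multi-counts", {
  mc <- mini_cohort()
  by_taxon <- breakdown_by(mc$prof, mc$att, "taxon")
  expect_equal(sum(vapply(by_taxon, `[[`, numeric(1), "n_total")), 5)
  by_route <- breakdown_by(mc$prof, mc$att, "route")
  expect_equal(sum(vapply(by_route, `[[`, numeric(1), "n_total")),
               sum(lengths(mc$att$route_list)))
  expect_equal(by_route[["waterborne"]]$n_total, 2)  # A and E
  expect_error(breakdown_by(mc$prof, mc$att, "colour"),
               class = "climsens_value_error")
})

test_that("a single-route cohort's route breakdown equals the global summary", {
  ids <- sprintf("Q%d", 1:4)
  ev <- evidence_from_list(list(Q1 = list(rainfall = 40)))
  prof <- sensitivity_profiles(ev, ids)
  att <- make_attributes(ids, routes = "vector-borne")
  expect_equal(breakdown_by(prof, att, "route")[["vector-borne"]],
               cohort_summary(prof, att))
})

test_that("summaries are invariant to roster order", {
  sim <- simulate_study(synth_config(n_pathogens = 40, seed = 22))
  prof1 <- sensitivity_profiles(sim$evidence, sim$attributes$pathogen_id)
  prof2 <- sensitivity_profiles(sim$evidence, rev(sim$attributes$pathogen_id))
  s1 <- cohort_summary(prof1)
  s2 <- cohort_summary(prof2)
  expect_equal(s1$driver_frequency, s2$driver_frequency)
  expect_equal(s1$n_sensitive, s2$n_sensitive)
  expect_equal(sort(s1$pair_counts), sort(s2$pair_counts))
})

test_that("attribute validation rejects bad vocabulary and empty routes", {
  expect_error(make_attributes("P1", taxon = "archaea"),
               class = "climsens_vocab_error")
  expect_error(make_attributes("P1", routes = ""),
               class = "climsens_validation_error")
  expect_error(make_attributes("P1", host_class = "wild"),
               class = "climsens_vocab_error")
  expect_error(make_attributes("P1", n_countries = 99),
               class = "climsens_validation_error")
})
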