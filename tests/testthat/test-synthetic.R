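test_that("the generator is deterministic given its seed and leaves the RNG alone", {
  cfg <- synth_config(n_pathogens = 50, seed = 61)
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_study(cfg)
  expect_identical(.Random.seed, before)  # no global RNG state consumed
  s2 <- simulate_study(cfg)
  expect_identical(s1$attributes, s2$attributes)
  expect_identical(s1$evidence, s2$evidence)
  s3 <- simulate_study(synth_config(n_pathogens = 50, seed = 62))
  expect_false(identical(s1$evidence, s3$evidence))
})

test_that("generated tables pass every downstream schema validator", {
  sim <- simulate_study(synth_config(n_pathogens = 60, seed = 63))
  expect_silent(validate_evidence(sim$evidence))
  att <- validate_attributes(sim$attributes)
  expect_true(all(lengths(att$route_list) >= 1))
  prof <- sensitivity_profiles(sim$evidence, att$pathogen_id)
  expect_equal(nrow(prof), 60)
  expect_s3_class(climate_associations(prof, att), "climsens_assoc")
})

test_that("switching sensitivity off yields no positive medians downstream", {
  cfg <- synth_config(
    n_pathogens = 40, driver_base_rate = 0, noise_record_rate = 0,
    route_driver_boost = stats::setNames(rep(1, 8), transmission_routes()),
    seed = 64)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$evidence), 0)
  prof <- sensitivity_profiles(sim$evidence, sim$attributes$pathogen_id)
  expect_true(all(prof$n_drivers == 0))
  expect_true(all(sim$attributes$sensitive_truth == 0))
})

test_that("invalid configurations are rejected with the offending fields named", {
  err <- expect_error(synth_config(driver_base_rate = 1.5, n_pathogens = 0),
                      class = "climsens_validation_error")
  expect_match(conditionMessage(err), "driver_base_rate")
  expect_match(conditionMessage(err), "n_pathogens")
  expect_error(synth_config(taxon_mix = c(bacteria = 1)),
               class = "climsens_validation_error")
  expect_error(synth_config(score_probs_sensitive = c(1, 1, 1, 1, 1)),
               class = "climsens_validation_error")
})

test_that("latent sensitivity matches its closed-form expectation on average", {
  cfg <- synth_config(n_pathogens = 157)
  expected <- expected_sensitive_fraction(cfg)
  fractions <- vapply(1:60, function(s) {
    sim <- simulate_study(synth_config(n_pathogens = 157, seed = 7000 + s))
    mean(sim$attributes$sensitive_truth)
  }, numeric(1))
  expect_lt(abs(mean(fractions) - expected), 0.05)
  # observed (median-positive) sensitivity tracks the latent rate closely
  sim <- simulate_study(synth_config(seed = 65))
  prof <- sensitivity_profiles(sim$evidence, sim$attributes$pathogen_id)
  expect_lt(abs(mean(prof$n_drivers >= 1) - expected), 0.15)
})

test_that("synthetic burden tables round-trip the parser", {
  b1 <- simulate_burden_table(synth_config(seed = 66), n_diseases = 1)
  expect_equal(nrow(b1), 1)
  tab1 <- read_burden_table(b1)
  expect_equal(format_burden_table(tab1)$drivers, b1$drivers)
  b <- simulate_burden_table(synth_config(seed = 66), n_diseases = 20)
  expect_identical(simulate_burden_table(synth_config(seed = 66),
                                         n_diseases = 20), b)
  tab <- read_burden_table(b)
  expect_equal(nrow(tab), 20)
  rep <- attribute_burden(tab, all_cause_total = sum(tab$dalys_thousands))
  expect_lte(rep$fraction_primary_sensitive, rep$fraction_sensitive)
})

test_that("an all-primary-driver burden table equates the two sensitive shares", {
  b <- simulate_burden_table(synth_config(seed = 67), n_diseases = 15)
  tab <- read_burden_table(b)
  # restrict each disease's drivers to primary ones only
  for (i in seq_len(nrow(tab))) {
    keep <- tab$driver_names[[i]] %in% primary_drivers()
    tab$driver_names[[i]] <- tab$driver_names[[i]][keep]
    tab$driver_medians[[i]] <- tab$driver_medians[[i]][keep]
  }
  rep <- attribute_burden(tab)
  expect_equal(rep$fraction_primary_sensitive, rep$fraction_sensitive)
  expect_equal(rep$n_primary, rep$n_any_driver)
  expect_equal(rep$n_secondary_only, 0)
})

test_that("write_simulation emits the CSVs plus provenance", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(synth_config(n_pathogens = 20, seed = 68))
  burden <- simulate_burden_table(synth_config(seed = 68), n_diseases = 5)
  paths <- write_simulation(sim, dir, burden = burden)
  expect_true(all(file.exists(unlist(paths))))
  prov <- jsonlite::read_json(paths[["provenance"]])
  expect_equal(prov$seed, 68)
  expect_equal(prov$config$n_pathogens, 20)
  expect_equal(nrow(read_evidence(paths[["evidence"]])), nrow(sim$evidence))
})
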