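test_that("median_score matches its definition on small multisets", {
  expect_equal(median_score(20), 20)
  expect_equal(median_score(c(5, 40)), 22.5)
  expect_equal(median_score(c(-20, 40, 80)), 40)
  expect_error(median_score(numeric(0)), class = "climsens_value_error")
})

test_that("median_score equals the sort-and-pick oracle on random multisets", {
  set.seed(101)
  grid <- c(rubric_grid(), -rubric_grid())
  for (i in 1:500) {
    x <- sample(grid, sample(1:15, 1), replace = TRUE)
    expect_identical(median_score(x), brute_median(x))
  }
})

test_that("adding a score at or above the median never decreases it", {
  set.seed(102)
  grid <- c(rubric_grid(), -rubric_grid())
  for (i in 1:200) {
    x <- sample(grid, sample(1:10, 1), replace = TRUE)
    m <- median_score(x)
    vals <- grid[grid >= m]
    add <- vals[sample.int(length(vals), 1)]
    expect_gte(median_score(c(x, add)), m)
  }
})

test_that("aggregation pools per (pathogen, driver) pair and nothing else", {
  ev <- evidence_from_list(list(
    P1 = list(rainfall = c(20, 80), moisture = c(60, -60)),
    P2 = list(rainfall = 5)))
  agg <- aggregate_evidence(ev)
  med <- function(p, d) agg$median_score[agg$pathogen_id == p & agg$driver == d]
  expect_equal(med("P1", "rainfall"), 50)
  expect_equal(med("P2", "rainfall"), 5)
  # contradicting evidence cancels to zero, which is not positive evidence
  expect_equal(med("P1", "moisture"), 0)
  expect_equal(agg$positive[agg$pathogen_id == "P1" & agg$driver == "moisture"],
               0L)
  # absent pairs stay absent rather than appearing as zero
  expect_equal(nrow(agg), 3)
})

test_that("evidence validation enforces the rubric grid and vocabulary", {
  bad <- data.frame(pathogen_id = "P1", driver = "rainfall", score = 33)
  expect_error(validate_evidence(bad), class = "climsens_validation_error")
  neg <- data.frame(pathogen_id = "P1", driver = "R", score = -40)
  out <- validate_evidence(neg)
  expect_equal(out$driver, "rainfall")  # codes canonicalised
  expect_error(
    validate_evidence(data.frame(pathogen_id = "P1", driver = "smog",
                                 score = 20)),
    class = "climsens_vocab_error")
})

test_that("profiles cover the full roster and derive flags from positive drivers", {
  ev <- evidence_from_list(list(
    P1 = list(rainfall = 40, altitude = 80),
    P2 = list(altitude = 20),
    P3 = list(moisture = -40)))
  prof <- sensitivity_profiles(ev, roster = c("P1", "P2", "P3", "P4"))
  expect_s3_class(prof, "climsens_profiles")
  expect_equal(prof$n_drivers, c(2L, 1L, 0L, 0L))
  expect_equal(prof$has_primary, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(prof$has_secondary, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(prof$drivers[1], "Alt;R")
  # pathogen with records but non-positive median is not sensitive
  expect_equal(prof$n_drivers[prof$pathogen_id == "P3"], 0L)
})

test_that("profiles reject medians for pathogens outside the roster", {
  ev <- evidence_from_list(list(P9 = list(rainfall = 40)))
  expect_error(sensitivity_profiles(ev, roster = c("P1", "P2")),
               class = "climsens_consistency_error")
  expect_error(build_profiles(aggregate_evidence(ev), roster = c("P9", "P9")),
               class = "climsens_validation_error")
})

test_that("total driver count equals the number of positive pairs", {
  sim <- simulate_study(synth_config(n_pathogens = 80, seed = 11))
  agg <- aggregate_evidence(sim$evidence)
  prof <- build_profiles(agg, sim$attributes$pathogen_id)
  expect_equal(sum(prof$n_drivers), sum(agg$positive))
})

test_that("evidence and profile CSV round-trips preserve content", {
  sim <- simulate_study(synth_config(n_pathogens = 30, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$evidence, path, row.names = FALSE)
  again <- read_evidence(path)
  expect_equal(again$score, sim$evidence$score)
  prof <- sensitivity_profiles(sim$evidence, sim$attributes$pathogen_id)
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_profiles(prof, out1, out2)
  med <- utils::read.csv(out1)
  expect_equal(nrow(med), nrow(aggregate_evidence(sim$evidence)))
  summ <- utils::read.csv(out2)
  expect_equal(summ$n_drivers, prof$n_drivers)
})
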