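test_that("subsite labels classify into oral cavity / oropharynx", {
  expect_equal(classify_site("floor of the mouth"), "oral_cavity")
  expect_equal(classify_site("Hard Palate"), "oral_cavity")
  expect_equal(classify_site("tongue base"), "oropharynx")
  expect_equal(classify_site("soft palate"), "oropharynx")
  expect_message(out <- classify_site("unknown primary"), "unmapped")
  expect_equal(out, "not_specified")
  # user-extensible dictionary
  dict <- c(default_subsite_dictionary(), "ventral tongue" = "oral_cavity")
  expect_equal(classify_site("ventral tongue", dict), "oral_cavity")
})

test_that("age exclusion keeps 15-year-olds and tags the excluded", {
  reg <- make_registry(3, age = c(14, 15, 62))
  out <- apply_age_exclusion(reg)
  expect_equal(out$included$age, c(15, 62))
  expect_equal(out$excluded$age, 14)
  expect_equal(out$excluded$exclusion_reason, "age_under_15")
  expect_equal(out$n_excluded_under_age, 1L)

  all_adult <- apply_age_exclusion(make_registry(5, age = 20))
  expect_equal(nrow(all_adult$excluded), 0L)

  # a 9,887-record cohort with two minors leaves 9,885
  big <- make_registry(9887, age = c(10, 12, rep(60, 9885)))
  expect_equal(nrow(apply_age_exclusion(big)$included), 9885L)
})

test_that("cohort summary reproduces printed registry percentages", {
  cs <- suppressMessages(cohort_summary(expand_table_margins()))
  expect_equal(cs$n_included, 9885L)
  get <- function(block, cat, col) block[[col]][block$category == cat]
  expect_equal(get(cs$sex, "male", "pct"), 71.5)
  expect_equal(get(cs$sex, "female", "pct"), 28.5)
  expect_equal(get(cs$age, ">=65", "pct"), 56.3)
  expect_equal(get(cs$age, "40-64", "pct"), 40.8)
  expect_equal(get(cs$age, "<40", "pct"), 2.9)
  expect_equal(get(cs$status, "alive", "pct"), 40.7)
  expect_equal(get(cs$site, "oral_cavity", "pct"), 52.1)
  expect_equal(get(cs$site, "oropharynx", "pct"), 46.3)
  expect_equal(get(cs$grade, "moderate", "pct"), 49.4)
  # partitions: every block's counts sum to n_included
  for (blk in c("age", "sex", "site", "status", "grade")) {
    expect_equal(sum(cs[[blk]]$n), 9885L)
  }
})

test_that("cohort summary handles edge cohorts", {
  one <- make_registry(1, age = 70, sex = "female", vital_status = "alive")
  cs <- cohort_summary(one)
  expect_equal(cs$sex$pct[cs$sex$category == "female"], 100.0)
  expect_equal(cs$age$pct[cs$age$category == ">=65"], 100.0)
  expect_error(cohort_summary(make_registry(0)), "empty cohort")
})

test_that("percentages round half-up to one decimal", {
  expect_equal(round_half_up(71.45, 1), 71.5)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(56.349, 1), 56.3)
})

test_that("mortality strata partition deaths at the month boundaries", {
  reg <- make_registry(5, vital_status = "dead",
                       survival_months = c(1, 36, 37, 60, 61))
  ms <- mortality_strata(reg)
  expect_equal(ms$deaths_within_36mo, 2)
  expect_equal(ms$deaths_37_to_60mo, 2)
  expect_equal(ms$deaths_after_60mo, 1)
  expect_equal(ms$total_deaths, 5)

  none <- mortality_strata(make_registry(4, vital_status = "alive"))
  expect_equal(unlist(none), c(deaths_within_36mo = 0, deaths_37_to_60mo = 0,
                               deaths_after_60mo = 0, total_deaths = 0))

  # printed strata 3,482 / 617 / 1,760 reconstruct the printed total 5,859
  big <- mortality_strata(expand_table_margins())
  expect_equal(big$deaths_within_36mo, 3482)
  expect_equal(big$deaths_37_to_60mo, 617)
  expect_equal(big$deaths_after_60mo, 1760)
  expect_equal(big$total_deaths, 5859)
  expect_equal(big$deaths_within_36mo + big$deaths_37_to_60mo +
                 big$deaths_after_60mo, big$total_deaths)
})

test_that("dead records need a survival time", {
  reg <- make_registry(2, vital_status = "dead", survival_months = c(5, NA))
  expect_error(mortality_strata(reg), "P00002")
})

test_that("aggregate_counts maps records to areas by stratum", {
  reg <- make_registry(5, area_id = c("A", "A", "A", "B", "B"),
                       vital_status = c("alive", "dead", "dead", "alive", "dead"),
                       survival_months = c(0, 24, 70, 0, 50))
  reg$area_id <- c("A", "A", "A", "B", "B")  # explicit, not recycled
  o <- aggregate_counts(reg, c("A", "B", "C"), stratum = "incidence")
  expect_equal(unname(o), c(3L, 2L, 0L))
  expect_equal(sum(o), nrow(reg))
  expect_equal(unname(aggregate_counts(reg, c("A", "B", "C"), "overall_death")),
               c(2L, 1L, 0L))
  expect_equal(unname(aggregate_counts(reg, c("A", "B", "C"),
                                       "death_within_36mo")), c(1L, 0L, 0L))
  expect_equal(unname(aggregate_counts(reg, c("A", "B", "C"),
                                       "death_within_60mo")), c(1L, 1L, 0L))
  expect_error(aggregate_counts(reg, c("A", "C")), "unknown area_id.*B")
})

test_that("aggregate_counts on a synthetic fixture matches a brute-force count
           and is permutation-invariant", {
  set.seed(14)
  reg <- make_registry(20,
                       area_id = sample(c("A", "B", "C"), 20, replace = TRUE),
                       vital_status = sample(c("alive", "dead"), 20,
                                             replace = TRUE),
                       survival_months = sample(0:100, 20, replace = TRUE))
  reg$area_id <- sample(c("A", "B", "C"), 20, replace = TRUE)
  reg$vital_status <- sample(c("alive", "dead"), 20, replace = TRUE)
  reg$survival_months <- sample(0:100, 20, replace = TRUE)
  got <- aggregate_counts(reg, c("A", "B", "C"), "death_within_60mo")
  hand <- vapply(c("A", "B", "C"), function(a) {
    sum(reg$area_id == a & reg$vital_status == "dead" &
          reg$survival_months <= 60)
  }, numeric(1))
  expect_equal(as.numeric(got), as.numeric(hand))
  shuffled <- reg[sample.int(20), ]
  expect_equal(aggregate_counts(shuffled, c("A", "B", "C"),
                                "death_within_60mo"), got)
})

test_that("registry CSV reading validates the schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  reg <- make_registry(3, age = c(20, 40, 60))
  utils::write.csv(reg, f, row.names = FALSE)
  expect_equal(nrow(read_registry(f)), 3L)
  utils::write.csv(reg[, -2], f, row.names = FALSE)
  expect_error(read_registry(f), "lacks column")
})
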