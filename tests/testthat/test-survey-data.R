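test_that("survey CSV round-trips losslessly and byte-stably", {
  ds <- paper_margins_dataset(seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(ds, p1)
  back <- read_survey_csv(p1)
  expect_equal(back$respondents, ds$respondents)
  expect_identical(back$province_index, ds$province_index)
  write_survey_csv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("survey CSV validation catches malformed input", {
  header <- paste(c("respondent_id", "province", "age_group", "role",
                    "setting", "subspecialty", "annual_volume_group",
                    "technique", "opioid_sparing", "min_age_kind",
                    "min_age_years", "preferred_opioid",
                    "least_preferred_opioid"), collapse = ",")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(header, p)
  expect_equal(n_respondents(read_survey_csv(p)), 0)

  writeLines(c("bad,header"), p)
  expect_error(read_survey_csv(p), "header")

  df <- make_survey_df(2, province = c("XX", "ON"))
  expect_error(survey_dataset(df), "unknown province")
  expect_error(survey_dataset(make_survey_df(2, opioid_sparing = c("2", "1"))),
               "unknown opioid_sparing")
  expect_error(survey_dataset(make_survey_df(2, respondent_id = c("a", "a"))),
               "unique")
  expect_error(survey_dataset(make_survey_df(1, min_age_kind = "numeric",
                                             min_age_years = "25")),
               "outside")
})

test_that("complete-case filter keeps exactly the fully answered respondents", {
  pm <- paper_margins_dataset(seed = 3)
  filtered <- suppressMessages(complete_case_filter(pm))
  expect_equal(n_respondents(filtered), 96)
  # idempotent
  again <- suppressMessages(complete_case_filter(filtered))
  expect_equal(again$respondents, filtered$respondents)

  clean <- survey_dataset(make_survey_df(6))
  expect_equal(complete_case_filter(clean)$respondents, clean$respondents)

  allmiss <- survey_dataset(make_survey_df(3, opioid_sparing = NA_character_))
  expect_warning(out <- suppressMessages(complete_case_filter(allmiss)),
                 "every respondent")
  expect_equal(n_respondents(out), 0)

  expect_error(complete_case_filter(clean, "no_such_field"), "unknown field")
})

test_that("dichotomization follows the documented 0/1 coding", {
  df <- make_survey_df(
    6,
    age_group = c("le40", "gt40", "le40", "gt40", "le40", "gt40"),
    subspecialty = c("pediatric", "general", "other", "pediatric", "general",
                     "other"),
    setting = c("academic", "community", "other", "academic", "community",
                "other"),
    annual_volume_group = c("le50", "gt50", "le50", "gt50", "le50", "gt50"),
    technique = c("extracapsular_monopolar", "cold_steel",
                  "intracapsular_microdebrider", "intracapsular_coblator",
                  "other", "extracapsular_monopolar")
  )
  ds <- survey_dataset(df)
  expect_equal(dichotomize(ds, "age"), c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(dichotomize(ds, "subspecialty"), c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(dichotomize(ds, "setting"), c(1L, 0L, NA, 1L, 0L, NA))
  expect_equal(dichotomize(ds, "setting", setting_other = "community"),
               c(1L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(dichotomize(ds, "volume"), c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(dichotomize(ds, "technique"), c(0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(dichotomize(ds, "technique", microdebrider = "one"),
               c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_error(dichotomize(ds, "gender"), "unknown covariate")

  # total on non-missing inputs, only {0, 1}
  pm <- paper_margins_dataset(seed = 5)
  for (cv in c("age", "subspecialty", "volume", "technique")) {
    d <- dichotomize(pm, cv)
    miss <- is.na(pm$respondents[[c(age = "age_group",
                                    subspecialty = "subspecialty",
                                    volume = "annual_volume_group",
                                    technique = "technique")[[cv]]]])
    expect_true(all(d[!miss] %in% c(0L, 1L)))
    expect_true(all(is.na(d[miss])))
  }
})

test_that("minimum-age summary reproduces the t-interval and counts", {
  # 49 numeric responses standardized to mean 8.6, SD 5.9 exactly
  w <- rep(c(-1, 1), c(25, 24))
  w <- (w - mean(w)) / sd(w)
  ages <- 8.6 + 5.9 * w
  df <- make_survey_df(49, min_age_kind = "numeric",
                       min_age_years = as.character(ages))
  sm <- summarize_min_age(survey_dataset(df))
  expect_equal(sm$n_numeric, 49)
  expect_equal(sm$mean_years, 8.6, tolerance = 1e-12)
  expect_equal(sm$sd_years, 5.9, tolerance = 1e-12)
  expect_equal(round(sm$ci_bounds[1], 1), 6.9)

  # against a direct two-pass computation on a constructed set
  vals <- 2:18
  df2 <- make_survey_df(length(vals), min_age_kind = "numeric",
                        min_age_years = as.character(vals))
  sm2 <- summarize_min_age(survey_dataset(df2))
  expect_equal(sm2$mean_years, sum(vals) / length(vals))
  expect_equal(sm2$sd_years,
               sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1)))

  # all equal: SD 0, interval collapses to the point
  df3 <- make_survey_df(5, min_age_kind = "numeric", min_age_years = "7")
  sm3 <- summarize_min_age(survey_dataset(df3))
  expect_equal(sm3$sd_years, 0)
  expect_equal(sm3$ci_bounds, c(7, 7))

  # fewer than two numeric responses: CI flagged undefined
  df4 <- make_survey_df(3, min_age_kind = c("numeric", "no_limit", "never"),
                        min_age_years = c("6", NA, NA))
  expect_false(summarize_min_age(survey_dataset(df4))$ci_defined)
})

test_that("preference tallies count per respondent and sum correctly", {
  pm <- paper_margins_dataset(seed = 2)
  pref <- tally_preferences(pm, "preferred_opioid")
  expect_equal(pref$percent[pref$category == "morphine"], 82)
  least <- tally_preferences(pm, "least_preferred_opioid")
  expect_equal(least$percent[least$category == "codeine"], 79)
  sparing <- tally_preferences(pm, "opioid_sparing")
  expect_equal(sparing$percent[sparing$category == "1"], 73)
  expect_equal(sum(sparing$count), 100)

  solo <- survey_dataset(make_survey_df(1, preferred_opioid = "fentanyl"))
  t1 <- tally_preferences(solo, "preferred_opioid")
  expect_equal(t1$percent, 100)

  # hand tally with multi-select rows: percentages are per-respondent
  multi <- survey_dataset(make_survey_df(
    4, preferred_opioid = c("morphine;oxycodone", "morphine", "codeine", NA)))
  tm <- tally_preferences(multi, "preferred_opioid")
  expect_equal(tm$count[tm$category == "morphine"], 2)
  expect_equal(tm$percent[tm$category == "morphine"], 200 / 3)
  expect_gt(sum(tm$percent), 100)

  # single-choice tallies sum to 100 up to rounding
  tech <- tally_preferences(pm, "technique")
  expect_equal(sum(tech$percent), 100, tolerance = 1e-9)
})
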