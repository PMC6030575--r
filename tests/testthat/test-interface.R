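test_that("daily table CSV round-trips a hand-written fixture", {
  path <- write_tiny_daily_csv(withr::local_tempfile(fileext = ".csv"))
  tab <- read_long_daily(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(length(unique(tab$person_id)), 1L)
  expect_equal(tab$item1, c(1, 3, 5))
})

test_that("daily table validation rejects bad input with row numbers", {
  path <- write_tiny_daily_csv(withr::local_tempfile(fileext = ".csv"),
                               c("person_id,day,item1,item2",
                                 "a,14,1,2", "a,15,7,3"))
  expect_error(read_long_daily(path), "item1.*row\\(s\\) 2")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,day,item1", "a,1,1"), path2)
  expect_error(read_long_daily(path2), "missing column.*item2")

  path3 <- write_tiny_daily_csv(withr::local_tempfile(fileext = ".csv"),
                                c("person_id,day,item1,item2",
                                  "a,14,1,2", "a,14,2,2"))
  expect_error(read_long_daily(path3), "duplicate")
})

test_that("read/write round-trip is lossless on generator output", {
  flt <- filtered_cohort(3)
  dpath <- withr::local_tempfile(fileext = ".csv")
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_long_daily(flt$daily, dpath)
  write_panel(flt$panel, ppath)
  expect_equal(read_long_daily(dpath, continuous = TRUE), flt$daily)
  back <- read_panel(ppath, continuous = TRUE)
  expect_equal(back, flt$panel, tolerance = 1e-12)
})

test_that("run configuration round-trips through YAML and rejects typos", {
  cfg <- run_config(window_length_days = 10L, anchor_week = 3L, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)
  writeLines("window_lenght_days: 10", path)
  expect_error(read_run_config(path), "unknown run-config key")
})

test_that("sample filters keep eligible persons and log exclusions", {
  # anchor day is 28; window [14, 28)
  daily <- validate_long_daily(data.frame(
    person_id = c("in", "early", "anchorday", "nopanel"),
    day = c(20L, 13L, 28L, 20L),
    item1 = c(2, 2, 2, 2), item2 = c(3, 3, 3, 3)))
  items <- matrix(1, 4, 9, dimnames = list(NULL, paste0("phq9_item", 1:9)))
  panel <- validate_panel(cbind(
    data.frame(person_id = c("in", "early", "anchorday", "noq"), week = 4L),
    as.data.frame(items),
    data.frame(phq9_sum = 9, sds_sum = NA_real_)))
  flt <- apply_sample_filters(daily, panel)
  expect_setequal(unique(flt$daily$person_id), "in")
  expect_equal(
    flt$exclusions$reason[flt$exclusions$person_id == "early"],
    "no in-window daily rating")
  expect_equal(
    flt$exclusions$reason[flt$exclusions$person_id == "anchorday"],
    "no in-window daily rating")
  expect_equal(
    flt$exclusions$reason[flt$exclusions$person_id == "nopanel"],
    "no anchor-week questionnaire")
  # retained + excluded persons partition the input
  expect_equal(nrow(flt$exclusions) + length(unique(flt$panel$person_id)),
               length(unique(c(daily$person_id, panel$person_id))))
})

test_that("a rating at the window's lower edge counts, the anchor day does not", {
  daily <- validate_long_daily(data.frame(
    person_id = "a", day = 14L, item1 = 2, item2 = 2))
  items <- matrix(1, 1, 9, dimnames = list(NULL, paste0("phq9_item", 1:9)))
  panel <- validate_panel(cbind(
    data.frame(person_id = "a", week = 4L), as.data.frame(items),
    data.frame(phq9_sum = 9, sds_sum = NA_real_)))
  expect_equal(nrow(apply_sample_filters(daily, panel)$daily), 1L)
  daily$day <- 28L
  expect_error(apply_sample_filters(validate_long_daily(daily), panel),
               "no eligible persons")
})

test_that("fixture cohort passes filters at full size and filtering is idempotent", {
  coh <- generate_cohort(generator_config(), seed = 5)
  flt <- apply_sample_filters(coh$daily, coh$panel)
  expect_equal(length(unique(flt$daily$person_id)), 545L)
  expect_equal(nrow(flt$daily), 2992L)
  again <- apply_sample_filters(flt$daily, flt$panel)
  expect_equal(again$daily, flt$daily)
  expect_equal(again$panel, flt$panel)
  expect_equal(nrow(again$exclusions), 0L)
})
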