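test_that("bundled count table satisfies its arithmetic invariants", {
  fix <- load_table2_fixture()
  expect_equal(nrow(fix), 36)
  expect_true(all(fix$total == fix$ipsi + fix$contra))
  expect_true(all(fix$homotopic >= 0 & fix$homotopic <= fix$contra))
  expect_false(anyDuplicated(fix$case_id) > 0)

  r <- fix[fix$case_id == "64FB", ]
  expect_equal(unlist(r[c("total", "ipsi", "contra", "homotopic")],
                      use.names = FALSE), c(15919, 11804, 4115, 2374))
  r <- fix[fix$case_id == "13TB", ]
  expect_equal(unlist(r[c("total", "ipsi", "contra", "homotopic")],
                      use.names = FALSE), c(2079, 2030, 49, 3))
})

test_that("aggregation excludes the injected area ipsilaterally only", {
  ds <- toy_dataset()
  agg <- aggregate_counts(ds, "T1")
  expect_equal(agg$total, 16)       # 10 ipsi F2 + 6 contra; deposit excluded
  expect_equal(agg$ipsi, 10)
  expect_equal(agg$contra, 6)
  expect_equal(agg$homotopic, 4)    # contra F7 counted, not excluded
  expect_equal(agg$n_injected_area_ipsi, 5)

  expect_error(aggregate_counts(ds, "nope"),
               class = "cpnquant_reference_error")
})

test_that("degenerate aggregations are flagged, not faked", {
  cases <- data.frame(case_id = "Z", species = "s", sex = "F", age_years = 1,
                      injected_hemisphere = "L", injected_area = "F2",
                      tracer = "DY", amount_ul = 0.2)
  rec_ipsi_only <- data.frame(case_id = "Z", section_um = 0,
                              hemisphere = "ipsi", area = "F6",
                              layer = "deep", count = 7L)
  ds <- labeling_dataset(cases, rec_ipsi_only)
  agg <- aggregate_counts(ds, "Z")
  expect_equal(agg$contra, 0)
  expect_equal(agg$homotopic, 0)

  rec_deposit_only <- data.frame(case_id = "Z", section_um = 0,
                                 hemisphere = "ipsi", area = "F2",
                                 layer = "deep", count = 7L)
  ds2 <- labeling_dataset(cases, rec_deposit_only)
  expect_warning(agg2 <- aggregate_counts(ds2, "Z"), "no countable labeling")
  expect_equal(agg2$total, 0)
  expect_equal(agg2$n_injected_area_ipsi, 7)
})

test_that("write then read is the identity on a validated dataset", {
  ds <- toy_dataset()
  td <- withr::local_tempdir()
  write_dataset(ds, file.path(td, "cases.csv"), file.path(td, "records.csv"))
  back <- read_dataset(file.path(td, "cases.csv"), file.path(td, "records.csv"))
  expect_equal(back$cases, ds$cases)
  expect_equal(back$records, ds$records)
})

test_that("validation errors carry their class and name the offender", {
  cases <- toy_dataset()$cases
  bad_ref <- data.frame(case_id = "XX", section_um = 0, hemisphere = "ipsi",
                        area = "F2", layer = "deep", count = 1L)
  err <- tryCatch(labeling_dataset(cases, bad_ref), error = identity)
  expect_s3_class(err, "cpnquant_reference_error")
  expect_match(conditionMessage(err), "XX")

  expect_error(labeling_dataset(cases[, -1], toy_dataset()$records),
               class = "cpnquant_schema_error")
  bad_count <- toy_dataset()$records
  bad_count$count[1] <- 0L
  expect_error(labeling_dataset(cases, bad_count),
               class = "cpnquant_value_error")
  bad_layer <- toy_dataset()$records
  bad_layer$layer[2] <- "granular"
  expect_error(labeling_dataset(cases, bad_layer),
               class = "cpnquant_value_error")
})

test_that("an empty records table yields a usable dataset with a warning", {
  empty <- data.frame(case_id = character(0), section_um = integer(0),
                      hemisphere = character(0), area = character(0),
                      layer = character(0), count = integer(0))
  expect_warning(ds <- labeling_dataset(toy_dataset()$cases, empty),
                 "empty")
  expect_equal(nrow(ds$records), 0)
})
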