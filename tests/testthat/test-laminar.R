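test_that("superficial fraction counts layer-assigned neurons only", {
  r <- data.frame(section_um = c(0, 300, 600), count = c(80L, 20L, 5L),
                  layer = c("superficial", "deep", "unknown"))
  sf <- superficial_fraction(r)
  expect_equal(sf$s_fraction, 0.8)
  expect_equal(sf$n_unknown, 5)

  r2 <- data.frame(section_um = rep(0, 3), count = c(10L, 10L, 100L),
                   layer = c("superficial", "deep", "unknown"))
  sf2 <- superficial_fraction(r2)
  expect_equal(sf2$s_fraction, 0.5)   # unknowns excluded from the ratio
  expect_equal(sf2$n_unknown, 100)

  r3 <- data.frame(section_um = 0, count = 5L, layer = "unknown")
  expect_true(is.na(superficial_fraction(r3)$s_fraction))
})

test_that("section subsampling keeps only the requested series", {
  r <- data.frame(section_um = c(0, 300, 600, 900), count = rep(10L, 4),
                  layer = c("superficial", "deep", "superficial", "deep"))
  sf600 <- superficial_fraction(r, sampling_um = 600)
  expect_equal(sf600$n_superficial, 20)   # sections 0 and 600
  expect_equal(sf600$n_deep, 0)
  sf_off <- superficial_fraction(r, sampling_um = 600, offset_um = 300)
  expect_equal(sf_off$n_deep, 20)         # sections 300 and 900
  expect_equal(sf_off$n_superficial, 0)
})

test_that("classification thresholds are closed and edges behave", {
  expect_equal(classify_laminar(0.95, 100), "feedforward")
  expect_equal(classify_laminar(0.50, 100), "lateral")
  expect_equal(classify_laminar(0.10, 100), "feedback")
  expect_equal(classify_laminar(0.70, 100), "feedforward")  # boundary attained
  expect_equal(classify_laminar(0.30, 100), "feedback")
  expect_equal(classify_laminar(0.9, 19), "indeterminate")  # below min_neurons
  expect_equal(classify_laminar(NA_real_, 0), "indeterminate")
  expect_error(classify_laminar(0.5, 100, ff_threshold = 0.3, fb_threshold = 0.7),
               class = "cpnquant_value_error")
})

test_that("classification is monotone in the superficial fraction", {
  ranks <- c(feedback = 1, lateral = 2, feedforward = 3)
  s <- seq(0, 1, by = 0.01)
  k <- vapply(s, function(x) classify_laminar(x, 1000), character(1))
  expect_true(all(diff(ranks[k]) >= 0))
})

test_that("laminar summary tags homotopic rows and cross-hemisphere shifts", {
  cases <- data.frame(case_id = "L1", species = "s", sex = "F", age_years = 5,
                      injected_hemisphere = "R", injected_area = "F3",
                      tracer = "FB", amount_ul = 0.2)
  records <- rbind(
    laminar_records("L1", "contra", "F3", n_sup = 90, n_deep = 10),  # homotopic, ff
    laminar_records("L1", "ipsi", "F6", n_sup = 50, n_deep = 50),    # lateral
    laminar_records("L1", "contra", "F6", n_sup = 5, n_deep = 45),   # feedback
    laminar_records("L1", "ipsi", "F3", n_sup = 30, n_deep = 0))     # deposit: dropped
  ds <- labeling_dataset(cases, records)
  sm <- laminar_summary(ds)

  hom <- sm[sm$homotopic, ]
  expect_equal(nrow(hom), 1)
  expect_equal(hom$source_area, "F3")
  expect_equal(hom$klass, "feedforward")
  expect_false(any(sm$hemisphere == "ipsi" & sm$source_area == "F3"))

  f6c <- sm[sm$source_area == "F6" & sm$hemisphere == "contra", ]
  expect_equal(f6c$klass, "feedback")
  expect_true(f6c$differs_from_ipsi)   # ipsi F6 is lateral
  expect_equal(attr(sm, "min_neurons"), 20)
})

test_that("generator-designed laminar patterns are recovered through the summary", {
  cfg <- simulation_config(
    injected_area = "F3", mean_total = 3000, pct_cpn_true = 40,
    pct_homotopic_true = 60, dispersion = 0,
    heterotopic_weights = c(F6 = 1), ipsi_weights = c(F6 = 1, F2 = 1),
    s_fraction_true = c("contra:F3" = 0.9, "contra:F6" = 0.15, default = 0.5),
    unknown_layer_rate = 0.05, seed = 11)
  sm <- laminar_summary(simulate_case(cfg)$dataset)
  expect_equal(sm$klass[sm$homotopic], "feedforward")
  expect_equal(sm$klass[sm$source_area == "F6" & sm$hemisphere == "contra"],
               "feedback")
  expect_equal(sm$klass[sm$source_area == "F2" & sm$hemisphere == "ipsi"],
               "lateral")
})
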