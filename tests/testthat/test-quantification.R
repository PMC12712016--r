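test_that("%CPN reproduces the published percentage columns on sample rows", {
  expect_equal(round_half_up(percent_cpn(list(ipsi = 11804, contra = 4115))), 25.8)
  expect_equal(round_half_up(percent_cpn(list(ipsi = 33566, contra = 246))), 0.7)
  expect_equal(percent_cpn(list(ipsi = 500, contra = 0)), 0)
  expect_error(percent_cpn(list(ipsi = 0, contra = 0)),
               class = "cpnquant_value_error")
  # complement identity, before any rounding
  x <- list(ipsi = 11804, contra = 4115)
  expect_identical(percent_cpn(x) + 100 * x$ipsi / (x$ipsi + x$contra), 100)
})

test_that("homotopic fraction matches published values and flags zero contra", {
  expect_equal(round_half_up(homotopic_fraction(list(contra = 4115, homotopic = 2374))), 57.7)
  expect_equal(round_half_up(homotopic_fraction(list(contra = 2079, homotopic = 1767))), 85.0)
  expect_equal(homotopic_fraction(list(contra = 7, homotopic = 7)), 100)
  expect_warning(v <- homotopic_fraction(list(contra = 0, homotopic = 0)),
                 "undefined")
  expect_true(is.na(v))   # undefined, never coerced to 0
  expect_error(homotopic_fraction(list(contra = 5, homotopic = 6)),
               class = "cpnquant_value_error")
})

make_table <- function(ipsi, contra, injected) {
  structure(list(case_id = "X", injected_area = injected,
                 per_area_ipsi = ipsi, per_area_contra = contra,
                 n_injected_area_ipsi = 0L),
            class = "count_table")
}

test_that("areal distributions normalize after the hemisphere's exclusion", {
  tab <- make_table(c(F2 = 30L, F6 = 50L, `24` = 20L),
                    c(F7 = 40L, F6 = 30L, F2 = 30L), "F7")
  expect_equal(areal_distribution(tab, "ipsi"),
               c(F2 = 30, F6 = 50, `24` = 20))
  # homotopic F7 removed contralaterally, remainder renormalized
  expect_equal(areal_distribution(tab, "contra"), c(F6 = 50, F2 = 50))

  single <- make_table(c(F2 = 12L), c(F2 = 3L), "F7")
  expect_equal(areal_distribution(single, "ipsi"), c(F2 = 100))
  empty <- make_table(integer(0), c(F7 = 5L), "F7")
  expect_warning(d <- areal_distribution(empty, "ipsi"), "no ipsi labeling")
  expect_length(d, 0)
})

test_that("distributions sum to 100 on random count tables", {
  set.seed(42)
  areas <- c("F2", "F3", "F6", "24", "9", "PEip")
  for (i in 1:25) {
    k <- sample(2:6, 1)
    nm <- sample(areas, k)
    tab <- make_table(
      stats::setNames(as.integer(rpois(k, 50) + 1), nm),
      stats::setNames(as.integer(rpois(k, 20)), nm), "F7")
    expect_equal(sum(areal_distribution(tab, "ipsi")), 100, tolerance = 1e-12)
    d <- suppressWarnings(areal_distribution(tab, "contra"))
    if (length(d)) expect_equal(sum(d), 100, tolerance = 1e-12)
  }
})

test_that("laterality index divides contra by ipsi above a strict 1% floor", {
  tab <- make_table(c(F2 = 200L, F6 = 800L), c(F2 = 100L, F6 = 800L), "F7")
  lat <- laterality_index(tab)
  expect_equal(lat[["F2"]], 0.5)
  expect_equal(lat[["F6"]], 1.0)

  # an area at exactly 1.0% of the ipsilateral labeling is excluded
  tab2 <- make_table(c(F2 = 1L, F6 = 99L), c(F2 = 5L, F6 = 10L), "F7")
  expect_false("F2" %in% names(laterality_index(tab2)))

  # contralateral-only areas cannot pass the filter but are reported aside
  tab3 <- make_table(c(F6 = 100L), c(F2 = 9L, F6 = 10L), "F7")
  lat3 <- laterality_index(tab3)
  expect_false("F2" %in% names(lat3))
  expect_equal(attr(lat3, "contra_only"), "F2")
})

test_that("laterality agrees with per-area division on random tables", {
  set.seed(7)
  areas <- c("F2", "F3", "F6", "24", "9")
  for (i in 1:25) {
    nm <- sample(areas, sample(2:5, 1))
    ipsi <- stats::setNames(as.integer(rpois(length(nm), 80) + 1), nm)
    contra <- stats::setNames(as.integer(rpois(length(nm), 30)), nm)
    tab <- make_table(ipsi, contra, "F7")
    lat <- laterality_index(tab)
    share <- 100 * ipsi / sum(ipsi)
    for (a in names(lat)) {
      expect_gt(share[[a]], 1.0)
      expect_equal(lat[[a]], contra[[a]] / ipsi[[a]], tolerance = 1e-12)
    }
    expect_setequal(names(lat), nm[share > 1.0])
  }
})

test_that("profiles assemble the case statistics from either input form", {
  fix <- load_table2_fixture()
  p <- connectivity_profile(fix, "30FB")
  expect_equal(round_half_up(p$pct_cpn), 6.4)
  expect_equal(round_half_up(p$pct_homotopic), 48.7)
  expect_null(p$laterality)
  expect_equal(round_half_up(connectivity_profile(fix, "13TB")$pct_cpn), 2.4)

  p2 <- connectivity_profile(toy_dataset(), "T1")
  expect_equal(p2$pct_cpn, 100 * 6 / 16)   # 37.5
  expect_equal(p2$pct_homotopic, 100 * 4 / 6)
  expect_equal(sum(p2$ipsi_distribution), 100)
  expect_equal(p2$contra_distribution, c(F6 = 100))
})
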