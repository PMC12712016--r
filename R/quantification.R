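#' Percentage of callosal projecting neurons
#'
#' The fraction of all counted labeled neurons that lie in the hemisphere
#' contralateral to the injection, expressed as a percentage:
#' `100 * contra / (ipsi + contra)`. The ipsilateral count is understood to
#' exclude the injected area itself (see [aggregate_counts()]).
#'
#' @param counts data.frame or list with numeric elements `ipsi` and
#'   `contra` (vectorized over rows).
#' @return percentage(s) in `[0, 100]`, full precision. Use
#'   [round_half_up()] for 1-decimal presentation.
#' @examples
#' percent_cpn(list(ipsi = 11804, contra = 4115))  # 25.85...
#' @export
percent_cpn <- function(counts) {
  ipsi <- counts$ipsi; contra <- counts$contra
  if (any(ipsi < 0) || any(contra < 0)) stop_value("negative counts")
  tot <- ipsi + contra
  if (any(tot == 0))
    stop_value("zero total labeled neurons: %CPN undefined")
  100 * contra / tot
}

#' Homotopic fraction of the callosal labeling
#'
#' The percentage of callosal projecting neurons located in the
#' contralateral area homotopic to the injected one:
#' `100 * homotopic / contra`. When a case has no callosal labeling at all
#' (`contra` = 0) the fraction is undefined and returned as `NA` with a
#' warning -- absence of CPNs is not the same thing as 0% homotopic, and
#' downstream reports omit the value rather than plot a zero.
#'
#' @param counts data.frame or list with numeric elements `contra` and
#'   `homotopic` (vectorized).
#' @return percentage(s) in `[0, 100]`, `NA` where `contra` is 0.
#' @export
homotopic_fraction <- function(counts) {
  contra <- counts$contra; homot <- counts$homotopic
  if (any(homot < 0) || any(homot > contra))
    stop_value("homotopic count must lie in [0, contra]")
  out <- ifelse(contra > 0, 100 * homot / contra, NA_real_)
  if (anyNA(out))
    warning("homotopic fraction undefined for case(s) with zero callosal labeling")
  out
}

#' Per-area count table for one case
#'
#' Splits a case's records into per-area counts by hemisphere. Ipsilateral
#' counts exclude the injected area (kept aside in
#' `n_injected_area_ipsi`); contralateral counts keep all areas, including
#' the homotopic one, whose exclusion is a property of the *distribution*
#' computation, not of the raw table.
#'
#' @inheritParams aggregate_counts
#' @return object of class `count_table`: list with `case_id`,
#'   `injected_area` (area-level label), `per_area_ipsi`,
#'   `per_area_contra` (named integer vectors), `n_injected_area_ipsi`.
#' @export
count_table <- function(dataset, case_id) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  i <- match(case_id, dataset$cases$case_id)
  if (is.na(i)) stop_reference(paste0("unknown case: '", case_id, "'"))
  injected <- area_level_of(dataset$parcellation, dataset$cases$injected_area[i])
  rec <- dataset$records[dataset$records$case_id == case_id, , drop = FALSE]
  sum_by_area <- function(r) {
    if (nrow(r) == 0L) return(integer(0))
    v <- tapply(r$count, r$area, sum)
    stats::setNames(as.integer(v), names(v))
  }
  ipsi <- sum_by_area(rec[rec$hemisphere == "ipsi" & rec$area != injected, , drop = FALSE])
  contra <- sum_by_area(rec[rec$hemisphere == "contra", , drop = FALSE])
  n_inj <- sum(rec$count[rec$hemisphere == "ipsi" & rec$area == injected])
  structure(list(case_id = case_id, injected_area = injected,
                 per_area_ipsi = ipsi, per_area_contra = contra,
                 n_injected_area_ipsi = as.integer(n_inj)),
            class = "count_table")
}

#' Areal percentage distribution of the labeling in one hemisphere
#'
#' Percentage of the hemisphere's labeled neurons found in each area, after
#' the standard exclusions: the injected area ipsilaterally (already absent
#' from the count table) and the homotopic area contralaterally. The
#' remaining areas are normalized to sum to 100.
#'
#' @param table a [count_table()].
#' @param hemisphere `"ipsi"` or `"contra"`.
#' @return named numeric vector of percentages summing to 100; empty (with
#'   a warning) if no labeling survives the exclusions.
#' @export
areal_distribution <- function(table, hemisphere = c("ipsi", "contra")) {
  stopifnot(inherits(table, "count_table"))
  hemisphere <- match.arg(hemisphere)
  counts <- if (hemisphere == "ipsi") table$per_area_ipsi else {
    x <- table$per_area_contra
    x[setdiff(names(x), table$injected_area)]
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) == 0L) {
    warning(sprintf("case '%s': no %s labeling after exclusions",
                    table$case_id, hemisphere))
    return(stats::setNames(numeric(0), character(0)))
  }
  100 * counts / sum(counts)
}

#' Laterality index per area
#'
#' For each area whose share of the ipsilateral labeling (injected area
#' excluded) strictly exceeds `min_ipsi_pct` percent, the ratio of the
#' contralateral (callosal) to ipsilateral labeled-neuron counts. The index
#' is 0 when all the area's cells are ipsilateral, 1 when the two
#' hemispheres contribute equally, and can exceed 1 when the contralateral
#' area dominates. The >1% floor keeps the ratio away from unstable
#' denominators; it is strict, so an area at exactly `min_ipsi_pct` is
#' excluded.
#'
#' Areas labeled only contralaterally can never pass the filter; they are
#' reported in the `"contra_only"` attribute so that labeling is not lost
#' silently.
#'
#' @param table a [count_table()].
#' @param min_ipsi_pct minimum ipsilateral share, percent (default 1).
#' @return named numeric vector of indices, with attribute `contra_only`
#'   listing areas with contralateral but no ipsilateral labeling.
#' @export
laterality_index <- function(table, min_ipsi_pct = 1.0) {
  stopifnot(inherits(table, "count_table"))
  dist_ipsi <- suppressWarnings(areal_distribution(table, "ipsi"))
  keep <- names(dist_ipsi)[dist_ipsi > min_ipsi_pct]
  contra <- table$per_area_contra
  idx <- vapply(keep, function(a) {
    ct <- if (a %in% names(contra)) contra[[a]] else 0L
    ct / table$per_area_ipsi[[a]]
  }, numeric(1))
  contra_only <- setdiff(names(contra)[contra > 0],
                         names(table$per_area_ipsi)[table$per_area_ipsi > 0])
  structure(stats::setNames(idx, keep), contra_only = contra_only)
}

#' Full connectivity profile of one case
#'
#' Assembles the case-level statistics: %CPN, homotopic fraction, areal
#' percentage distributions for both hemispheres, and the laterality index
#' map. Accepts either a full `labeling_dataset` (all statistics) or a
#' summary count table such as [load_table2_fixture()] (only %CPN and the
#' homotopic fraction, since per-area detail is absent).
#'
#' @param x a `labeling_dataset` or a data.frame with columns `case_id`,
#'   `ipsi`, `contra`, `homotopic`.
#' @param case_id case identifier.
#' @param min_ipsi_pct passed to [laterality_index()].
#' @return object of class `connectivity_profile`: list with `case_id`,
#'   `pct_cpn`, `pct_homotopic`, `ipsi_distribution`,
#'   `contra_distribution`, `laterality` (the last three `NULL` for
#'   summary-table input).
#' @export
connectivity_profile <- function(x, case_id, min_ipsi_pct = 1.0) {
  if (inherits(x, "labeling_dataset")) {
    agg <- aggregate_counts(x, case_id)
    tab <- count_table(x, case_id)
    prof <- list(case_id = case_id,
                 pct_cpn = percent_cpn(agg),
                 pct_homotopic = homotopic_fraction(agg),
                 ipsi_distribution = suppressWarnings(areal_distribution(tab, "ipsi")),
                 contra_distribution = suppressWarnings(areal_distribution(tab, "contra")),
                 laterality = laterality_index(tab, min_ipsi_pct))
  } else if (is.data.frame(x) && all(c("case_id", "ipsi", "contra") %in% names(x))) {
    row <- x[x$case_id == case_id, , drop = FALSE]
    if (nrow(row) != 1L) stop_reference(paste0("unknown case: '", case_id, "'"))
    prof <- list(case_id = case_id,
                 pct_cpn = percent_cpn(row),
                 pct_homotopic = homotopic_fraction(row),
                 ipsi_distribution = NULL, contra_distribution = NULL,
                 laterality = NULL)
  } else {
    stop_schema("x must be a labeling_dataset or a summary count data.frame")
  }
  structure(prof, class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf("Case %s: %%CPN = %.1f, homotopic = %s\n", x$case_id,
              round_half_up(x$pct_cpn, 1),
              if (is.na(x$pct_homotopic)) "undefined (no CPNs)"
              else sprintf("%.1f%%", round_half_up(x$pct_homotopic, 1))))
  if (length(x$laterality))
    cat("  laterality computed for", length(x$laterality), "area(s)\n")
  invisible(x)
}
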