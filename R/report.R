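#' Case-by-area laterality matrix
#'
#' Stacks each case's [laterality_index()] map into a cases x areas matrix
#' for heatmap-style reporting. Cells for areas that did not pass the >1%
#' ipsilateral floor in a case are `NA` (missing, not zero). The cell where
#' a case's own homotopic area would appear is masked (`NA` plus a `TRUE`
#' in the `mask` attribute): the homotopic projection is quantified by the
#' homotopic fraction, not by a laterality ratio.
#'
#' @param dataset a `labeling_dataset`.
#' @param min_ipsi_pct passed to [laterality_index()].
#' @return numeric matrix (rows = cases, columns = areas in parcellation
#'   order) with attribute `mask`, a logical matrix marking masked
#'   homotopic cells.
#' @export
laterality_matrix <- function(dataset, min_ipsi_pct = 1.0) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  cases <- dataset$cases$case_id
  lat <- lapply(cases, function(cid)
    laterality_index(count_table(dataset, cid), min_ipsi_pct))
  injected <- vapply(dataset$cases$injected_area,
                     function(a) area_level_of(dataset$parcellation, a),
                     character(1))
  # homotopic columns are kept even without passing indices, so their masked
  # cells exist in the matrix
  used <- union(unique(unlist(lapply(lat, names))), injected)
  cols <- intersect(dataset$parcellation$name, used)
  m <- matrix(NA_real_, nrow = length(cases), ncol = length(cols),
              dimnames = list(cases, cols))
  mask <- matrix(FALSE, nrow = length(cases), ncol = length(cols),
                 dimnames = list(cases, cols))
  for (i in seq_along(cases)) {
    v <- lat[[i]]
    m[i, intersect(names(v), cols)] <- v[intersect(names(v), cols)]
    inj <- area_level_of(dataset$parcellation, dataset$cases$injected_area[i])
    if (inj %in% cols) {
      m[i, inj] <- NA_real_
      mask[i, inj] <- TRUE
    }
  }
  structure(m, mask = mask)
}

#' Build the full report bundle
#'
#' Assembles every tabular product of the analysis in one pass: the
#' per-case count-and-percentage table, the case-level %CPN / homotopic
#' series, region summaries, cross-case statistics (the two Pearson
#' correlations and, when the three comparison groups are represented, the
#' negative-binomial rate-ratio regression), and -- for datasets with
#' per-area detail -- areal distributions and the laterality matrix.
#'
#' Accepts either a summary count table with a `region` column (such as
#' [load_table2_fixture()]) or a full `labeling_dataset`.
#'
#' @param x fixture-style data.frame or `labeling_dataset`.
#' @param min_ipsi_pct laterality floor, percent.
#' @return list of class `report_bundle` with elements `table2_like`,
#'   `fig2_like`, `fig7_like` (or `NULL`), `distributions` (or `NULL`),
#'   `region_summaries`, `stats`, `parameters`.
#' @export
build_report_bundle <- function(x, min_ipsi_pct = 1.0) {
  if (inherits(x, "labeling_dataset")) {
    agg <- do.call(rbind, lapply(x$cases$case_id, function(cid)
      suppressWarnings(aggregate_counts(x, cid))))
    agg$injected_area <- vapply(x$cases$injected_area,
                                function(a) area_level_of(x$parcellation, a),
                                character(1))
    agg$region <- vapply(agg$injected_area,
                         function(a) region_of(x$parcellation, a), character(1))
    dists <- do.call(rbind, lapply(x$cases$case_id, function(cid) {
      tab <- count_table(x, cid)
      rows <- lapply(c("ipsi", "contra"), function(h) {
        d <- suppressWarnings(areal_distribution(tab, h))
        if (!length(d)) return(NULL)
        data.frame(case_id = cid, hemisphere = h, area = names(d),
                   percent = unname(d), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
    fig7 <- laterality_matrix(x, min_ipsi_pct)
  } else if (is.data.frame(x) && all(c("case_id", "ipsi", "contra",
                                       "homotopic", "region") %in% names(x))) {
    agg <- x
    dists <- NULL
    fig7 <- NULL
  } else {
    stop_schema("x must be a labeling_dataset or a summary table with a region column")
  }
  if (anyDuplicated(agg$case_id)) stop_value("duplicate case_id in input")

  pct_cpn <- percent_cpn(agg)
  pct_hom <- suppressWarnings(homotopic_fraction(agg))
  table2_like <- data.frame(
    case_id = agg$case_id, injected_area = agg$injected_area,
    region = agg$region, total = agg$ipsi + agg$contra, ipsi = agg$ipsi,
    contra = agg$contra, homotopic = agg$homotopic,
    pct_cpn = pct_cpn, pct_cpn_1dp = round_half_up(pct_cpn, 1),
    pct_homotopic = pct_hom, pct_homotopic_1dp = round_half_up(pct_hom, 1),
    stringsAsFactors = FALSE)
  fig2_like <- table2_like[, c("case_id", "injected_area", "pct_cpn",
                               "pct_homotopic")]

  summaries <- list()
  for (reg in intersect(c("prefrontal", "premotor", "frontal_opercular",
                          "parietal"), unique(agg$region)))
    summaries[[reg]] <- region_summary(agg, reg)
  if ("parietal" %in% agg$region &&
      any(agg$region == "parietal" & agg$injected_area != "PF"))
    summaries[["parietal_excl_PF"]] <-
      region_summary(agg, "parietal", exclude_areas = "PF")

  # correlations need >= 3 cases with variation; small bundles skip them
  stats_out <- list(
    cor_total_vs_pct_cpn =
      if (nrow(table2_like) >= 3 && stats::sd(table2_like$total) > 0 &&
          stats::sd(pct_cpn) > 0)
        pearson_cor(table2_like$total, pct_cpn)
      else NULL,
    cor_pct_cpn_vs_pct_homotopic =
      if (sum(!is.na(pct_hom)) >= 3 && stats::sd(pct_hom, na.rm = TRUE) > 0 &&
          stats::sd(pct_cpn[!is.na(pct_hom)]) > 0)
        pearson_cor(pct_cpn[!is.na(pct_hom)], pct_hom[!is.na(pct_hom)])
      else NULL)
  grp <- agg[agg$region %in% c("prefrontal", "premotor", "parietal"), , drop = FALSE]
  if (length(unique(grp$region)) >= 2 && all(table(grp$region) >= 2))
    stats_out$nb_regression <- nb_rate_regression(
      grp$contra, grp$ipsi + grp$contra,
      factor(grp$region, levels = intersect(c("prefrontal", "premotor", "parietal"),
                                            unique(grp$region))))

  structure(list(table2_like = table2_like, fig2_like = fig2_like,
                 fig7_like = fig7, distributions = dists,
                 region_summaries = summaries, stats = stats_out,
                 parameters = list(
                   min_ipsi_pct = min_ipsi_pct,
                   exclusions = paste("ipsilateral: injected area;",
                                      "contralateral distribution: homotopic area"),
                   rounding = "half-up, 1 decimal (presentation columns only)",
                   package_version = as.character(utils::packageVersion("cpnquant")))),
            class = "report_bundle")
}

#' Write a report bundle to disk
#'
#' Emits the bundle as plain CSV/JSON files under `dir`: `profile.csv`,
#' `fig2.csv`, `region_summary.csv`, `stats.json`, `parameters.json`, and
#' -- when per-area detail exists -- `distribution.csv`, `laterality.csv`
#' (long form), and `laterality_matrix.csv` (wide, masked homotopic cells
#' empty). Identical inputs produce byte-identical CSVs. Missing values are
#' empty cells in CSV and `null` in JSON, never sentinel numbers.
#'
#' @param bundle a [build_report_bundle()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  wcsv(bundle$table2_like, "profile.csv")
  wcsv(bundle$fig2_like, "fig2.csv")
  rs <- do.call(rbind, lapply(names(bundle$region_summaries), function(nm) {
    s <- bundle$region_summaries[[nm]]
    data.frame(group = nm, region = s$region, mean_pct_cpn = s$mean_pct_cpn,
               mean_pct_cpn_rounded = round_half_up(s$mean_pct_cpn, 0),
               min_pct_cpn = s$min_pct_cpn, max_pct_cpn = s$max_pct_cpn,
               n_cases = s$n_cases)
  }))
  if (!is.null(rs)) wcsv(rs, "region_summary.csv")
  if (!is.null(bundle$distributions)) wcsv(bundle$distributions, "distribution.csv")
  if (!is.null(bundle$fig7_like)) {
    m <- bundle$fig7_like
    long <- data.frame(case_id = rep(rownames(m), ncol(m)),
                       area = rep(colnames(m), each = nrow(m)),
                       index = as.vector(m),
                       masked_homotopic = as.vector(attr(m, "mask")))
    long <- long[!is.na(long$index) | long$masked_homotopic, , drop = FALSE]
    wcsv(long, "laterality.csv")
    wide <- data.frame(case_id = rownames(m), m, check.names = FALSE)
    wcsv(wide, "laterality_matrix.csv")
  }
  st <- bundle$stats
  json_stats <- list(
    correlations = lapply(
      Filter(Negate(is.null),
             st[c("cor_total_vs_pct_cpn", "cor_pct_cpn_vs_pct_homotopic")]),
      function(cr) list(r = cr$r, p = cr$p, n = cr$n)),
    nb_regression = if (!is.null(st$nb_regression)) {
      fit <- st$nb_regression
      list(groups = fit$groups, group_sizes = fit$group_sizes,
           rate_ratios = as.list(fit$rate_ratios),
           p_values = as.list(fit$p_values),
           p_adjusted = as.list(fit$p_adjusted),
           dispersion = fit$dispersion)
    })
  p <- file.path(dir, "stats.json")
  jsonlite::write_json(json_stats, p, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "parameters.json")
  jsonlite::write_json(bundle$parameters, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
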