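#' Configuration for a simulated injection case
#'
#' Describes the ground truth of one synthetic retrograde-tracer case: the
#' expected total number of labeled neurons and its negative-binomial
#' overdispersion across replicate cases, the true callosal percentage and
#' homotopic share, areal weights for the heterotopic and ipsilateral
#' labeling, laminar (superficial-layer) fractions per projection, and the
#' sectioning grid neurons are charted on. Overdispersion acts on the
#' case-level total (NB2, variance mu + alpha * mu^2), with multinomial
#' thinning to areas; this mirrors the strongly cross-case-overdispersed
#' totals seen in real material while keeping per-area conditional
#' structure simple.
#'
#' @param parcellation a [parcellation].
#' @param injected_area injected area label (resolved at area level).
#' @param mean_total expected total labeled neurons (ipsi outside the
#'   injected area + contra).
#' @param pct_cpn_true true callosal percentage in `[0, 100]`.
#' @param pct_homotopic_true true homotopic share of the callosal labeling
#'   in `[0, 100]`.
#' @param heterotopic_weights named nonnegative weights over contralateral
#'   source areas (the homotopic area is handled by
#'   `pct_homotopic_true` and must not appear here).
#' @param ipsi_weights named nonnegative weights over ipsilateral source
#'   areas (the injected area must not appear).
#' @param s_fraction_true named vector of true superficial fractions; keys
#'   may be `"hemisphere:area"`, `"area"`, or `"default"` (most specific
#'   wins). Default 0.7 throughout.
#' @param dispersion NB dispersion alpha >= 0 of the case total (0 =
#'   Poisson).
#' @param unknown_layer_rate probability a neuron's layer cannot be
#'   assigned (default 0.05, exercising the exclusion path).
#' @param section_spacing_um spacing of the section grid, micrometers
#'   (default 300, the laminar sampling series; plotting series are
#'   multiples of it).
#' @param n_sections number of sections on the grid.
#' @param seed integer seed; the case is fully reproducible from it.
#' @param case_id,tracer metadata for the generated case table.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(parcellation = default_parcellation(),
                              injected_area, mean_total = 10000,
                              pct_cpn_true = 15, pct_homotopic_true = 50,
                              heterotopic_weights, ipsi_weights,
                              s_fraction_true = c(default = 0.7),
                              dispersion = 0.2, unknown_layer_rate = 0.05,
                              section_spacing_um = 300, n_sections = 100,
                              seed = 1L, case_id = "SIM1", tracer = "FB") {
  injected <- area_level_of(parcellation, injected_area)
  if (pct_cpn_true < 0 || pct_cpn_true > 100 ||
      pct_homotopic_true < 0 || pct_homotopic_true > 100)
    stop_value("pct_cpn_true and pct_homotopic_true must lie in [0, 100]")
  if (dispersion < 0) stop_value("dispersion must be >= 0")
  if (unknown_layer_rate < 0 || unknown_layer_rate > 1)
    stop_value("unknown_layer_rate must lie in [0, 1]")
  if (mean_total <= 0 || n_sections < 1 || section_spacing_um < 1)
    stop_value("mean_total, n_sections, section_spacing_um must be positive")
  check_w <- function(w, label, banned) {
    if (length(w) == 0L || sum(w) <= 0) stop_value(paste0(label, " must have positive total weight"))
    if (any(w < 0)) stop_value(paste0(label, " must be nonnegative"))
    if (is.null(names(w)) || any(!nzchar(names(w)))) stop_value(paste0(label, " must be named"))
    for (a in names(w)) resolve_area(parcellation, a)
    if (banned %in% names(w))
      stop_value(paste0(label, " must not include '", banned,
                        "' (handled separately)"))
  }
  check_w(ipsi_weights, "ipsi_weights", injected)
  check_w(heterotopic_weights, "heterotopic_weights", injected)
  structure(list(parcellation = parcellation, injected_area = injected,
                 mean_total = mean_total, pct_cpn_true = pct_cpn_true,
                 pct_homotopic_true = pct_homotopic_true,
                 heterotopic_weights = heterotopic_weights,
                 ipsi_weights = ipsi_weights,
                 s_fraction_true = s_fraction_true,
                 dispersion = dispersion,
                 unknown_layer_rate = unknown_layer_rate,
                 section_spacing_um = section_spacing_um,
                 n_sections = n_sections, seed = as.integer(seed),
                 case_id = case_id, tracer = tracer),
            class = "simulation_config")
}

s_fraction_for <- function(config, hemisphere, area) {
  s <- config$s_fraction_true
  for (key in c(paste0(hemisphere, ":", area), area, "default"))
    if (key %in% names(s)) return(unname(s[key]))
  0.7
}

#' Simulate one injection case
#'
#' Draws a bilateral labeling dataset from a [simulation_config()]:
#' the case total is negative-binomial (Poisson at dispersion 0); the
#' callosal count is binomial in the total at `pct_cpn_true`; its homotopic
#' part binomial at `pct_homotopic_true`; heterotopic and ipsilateral
#' neurons are multinomial over their areal weights. Each projection's
#' neurons are assigned a layer (unknown with `unknown_layer_rate`, else
#' superficial with its true s-fraction) and spread uniformly over the
#' section grid. Records are emitted aggregated per (section, hemisphere,
#' area, layer) with `count`, which is statistically identical to
#' per-neuron rows and much smaller.
#'
#' The RNG state of the caller is left untouched: the case is drawn from a
#' private stream seeded by `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a `labeling_dataset`) and `truth` (config
#'   echo minus the parcellation, plus realized totals).
#' @export
simulate_case <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    total <- if (config$dispersion > 0)
      stats::rnbinom(1, mu = config$mean_total, size = 1 / config$dispersion)
    else stats::rpois(1, config$mean_total)
    n_contra <- stats::rbinom(1, total, config$pct_cpn_true / 100)
    n_ipsi <- total - n_contra
    n_homot <- stats::rbinom(1, n_contra, config$pct_homotopic_true / 100)
    n_het <- n_contra - n_homot

    alloc <- function(n, w) {
      if (n == 0L) return(stats::setNames(integer(0), character(0)))
      stats::setNames(as.integer(stats::rmultinom(1, n, w / sum(w))), names(w))
    }
    contra_areas <- c(stats::setNames(n_homot, config$injected_area),
                      alloc(n_het, config$heterotopic_weights))
    ipsi_areas <- alloc(n_ipsi, config$ipsi_weights)

    grid <- (seq_len(config$n_sections) - 1L) * config$section_spacing_um
    emit <- function(hemi, area, n) {
      if (n == 0L) return(NULL)
      n_unk <- stats::rbinom(1, n, config$unknown_layer_rate)
      n_sup <- stats::rbinom(1, n - n_unk, s_fraction_for(config, hemi, area))
      n_deep <- n - n_unk - n_sup
      parts <- c(superficial = n_sup, deep = n_deep, unknown = n_unk)
      parts <- parts[parts > 0]
      do.call(rbind, lapply(names(parts), function(layer) {
        per_sec <- as.integer(stats::rmultinom(1, parts[[layer]],
                                               rep(1, config$n_sections)))
        keep <- per_sec > 0
        data.frame(case_id = config$case_id, section_um = grid[keep],
                   hemisphere = hemi, area = area, layer = layer,
                   count = per_sec[keep], stringsAsFactors = FALSE)
      }))
    }
    recs <- c(
      lapply(names(ipsi_areas), function(a) emit("ipsi", a, ipsi_areas[[a]])),
      lapply(names(contra_areas), function(a) emit("contra", a, contra_areas[[a]])))
    records <- do.call(rbind, recs)
    if (is.null(records))
      records <- data.frame(case_id = character(0), section_um = integer(0),
                            hemisphere = character(0), area = character(0),
                            layer = character(0), count = integer(0))
    cases <- data.frame(case_id = config$case_id, species = "synthetic",
                        sex = "F", age_years = 10,
                        injected_hemisphere = "R",
                        injected_area = config$injected_area,
                        tracer = config$tracer, amount_ul = 0.2,
                        stringsAsFactors = FALSE)
    dataset <- suppressWarnings(
      labeling_dataset(cases, records, config$parcellation))
    truth <- list(config = config[setdiff(names(config), "parcellation")],
                  realized = list(total = total, n_ipsi = n_ipsi,
                                  n_contra = n_contra, n_homotopic = n_homot,
                                  ipsi_areas = ipsi_areas,
                                  contra_areas = contra_areas))
    list(dataset = dataset, truth = truth)
  })
}

#' Simulate the full 36-case study design
#'
#' One synthetic case per row of the bundled count table, with each case's
#' expected total set to the printed total and its true callosal and
#' homotopic percentages set to the full-precision printed ratios, so the
#' whole pipeline can be exercised end-to-end at realistic scale and
#' composition. Areal weights are generic (geometric weights over
#' same-region areas, with cingulate area 24 admixed); they are a
#' convenience for pipeline exercise, not a reconstruction of any real
#' chart.
#'
#' @param seed master integer seed; each case gets an independent stream
#'   derived from (seed, case index).
#' @param parcellation a [parcellation].
#' @param dispersion NB dispersion alpha of case totals (default 0.2).
#' @return list of 36 `list(dataset, truth)` pairs, named by case.
#' @export
paper_like_suite <- function(seed = 1L, parcellation = default_parcellation(),
                             dispersion = 0.2) {
  fix <- load_table2_fixture()
  areas <- as.data.frame(parcellation)
  pool_for <- function(injected) {
    reg <- region_of(parcellation, injected)
    pool <- areas$name[areas$region == reg & is.na(areas$parent) &
                         areas$name != injected]
    if (length(pool) < 3)
      pool <- c(pool, setdiff(areas$name[areas$region == "premotor"], injected))
    if (!("24" %in% pool) && injected != "24") pool <- c(pool, "24")
    utils::head(pool, 8)
  }
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    row <- fix[i, ]
    pool <- pool_for(row$injected_area)
    w <- stats::setNames(2^-(seq_along(pool) - 1), pool)
    cfg <- simulation_config(
      parcellation = parcellation, injected_area = row$injected_area,
      mean_total = row$total,
      pct_cpn_true = 100 * row$contra / row$total,
      pct_homotopic_true = 100 * row$homotopic / row$contra,
      heterotopic_weights = w, ipsi_weights = w,
      dispersion = dispersion,
      seed = as.integer((seed + 7919 * i) %% .Machine$integer.max),
      case_id = row$case_id, tracer = "FB")
    out[[i]] <- simulate_case(cfg)
  }
  stats::setNames(out, fix$case_id)
}
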