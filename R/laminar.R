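#' Superficial-layer fraction of a projection
#'
#' For the labeled neurons of one (case, hemisphere, source area), the
#' fraction originating in the superficial layers (II-III) relative to all
#' layer-assigned neurons: `s = n_superficial / (n_superficial + n_deep)`.
#' Laminar analysis samples a coarser/finer section series than plotting,
#' so only records on sections at a fixed spacing are counted: a record
#' enters iff `(section_um - offset_um) %% sampling_um == 0`. Neurons whose
#' laminar position could not be assigned are tallied in `n_unknown` and
#' excluded from the fraction.
#'
#' @param records data.frame of neuron records for one (case, hemisphere,
#'   area): needs columns `section_um`, `layer`, and optionally `count`.
#' @param sampling_um section sampling interval in micrometers (default
#'   300).
#' @param offset_um phase of the sampled series in micrometers (default 0).
#' @return list with `n_superficial`, `n_deep`, `n_unknown`, `s_fraction`
#'   (`NA` if no layer-assigned neurons survive the sampling).
#' @examples
#' r <- data.frame(section_um = c(0, 300, 600), count = c(80, 20, 5),
#'                 layer = c("superficial", "deep", "unknown"))
#' superficial_fraction(r)$s_fraction  # 0.8
#' @export
superficial_fraction <- function(records, sampling_um = 300, offset_um = 0) {
  stopifnot(sampling_um >= 1)
  if (is.null(records$count)) records$count <- 1L
  keep <- (records$section_um - offset_um) %% sampling_um == 0
  r <- records[keep, , drop = FALSE]
  n_sup <- sum(r$count[r$layer == "superficial"])
  n_deep <- sum(r$count[r$layer == "deep"])
  n_unk <- sum(r$count[r$layer == "unknown"])
  s <- if (n_sup + n_deep > 0) n_sup / (n_sup + n_deep) else NA_real_
  list(n_superficial = as.integer(n_sup), n_deep = as.integer(n_deep),
       n_unknown = as.integer(n_unk), s_fraction = s)
}

#' Classify a projection as feedforward, lateral, or feedback
#'
#' Hierarchical classification from the laminar origin of a retrogradely
#' labeled projection: predominantly superficial origin marks a
#' *feedforward* projection, predominantly deep (infragranular) origin a
#' *feedback* projection, and a bilaminar (balanced) origin a *lateral*
#' one. The qualitative criterion is made operational with symmetric
#' closed thresholds on the superficial fraction: `s >= ff_threshold` is
#' feedforward, `s <= fb_threshold` is feedback, anything between is
#' lateral. Projections with fewer than `min_neurons` layer-assigned
#' neurons are `indeterminate` rather than classified from noise.
#'
#' @param s_fraction superficial fraction in `[0, 1]` (may be `NA`).
#' @param n_assigned number of layer-assigned neurons behind it.
#' @param ff_threshold feedforward boundary (default 0.70).
#' @param fb_threshold feedback boundary (default 0.30).
#' @param min_neurons minimum assigned neurons for a call (default 20).
#' @return one of `"feedforward"`, `"lateral"`, `"feedback"`,
#'   `"indeterminate"`.
#' @export
classify_laminar <- function(s_fraction, n_assigned,
                             ff_threshold = 0.70, fb_threshold = 0.30,
                             min_neurons = 20) {
  if (ff_threshold <= fb_threshold)
    stop_value("ff_threshold must exceed fb_threshold")
  if (is.na(s_fraction) || n_assigned < min_neurons) return("indeterminate")
  if (s_fraction >= ff_threshold) "feedforward"
  else if (s_fraction <= fb_threshold) "feedback"
  else "lateral"
}

#' Laminar pattern summary across a dataset
#'
#' One row per (injected/target area, source area, hemisphere) with enough
#' layer-assigned neurons: the laminar counts, superficial fraction, class,
#' a homotopic flag (contralateral source area equal to the injected one),
#' and -- for contralateral rows -- whether the class differs from the same
#' source area's ipsilateral class (the cross-hemisphere comparison
#' convention used when tabulating such patterns).
#'
#' @param dataset a `labeling_dataset` with layer-annotated records.
#' @param sampling_um,offset_um section sampling passed to
#'   [superficial_fraction()].
#' @param ff_threshold,fb_threshold,min_neurons passed to
#'   [classify_laminar()].
#' @return data.frame with columns `case_id`, `target_area`, `source_area`,
#'   `hemisphere`, `n_superficial`, `n_deep`, `n_unknown`, `s_fraction`,
#'   `klass`, `homotopic`, `differs_from_ipsi`, plus the thresholds used as
#'   attributes `ff_threshold`, `fb_threshold`, `min_neurons`.
#' @export
laminar_summary <- function(dataset, sampling_um = 300, offset_um = 0,
                            ff_threshold = 0.70, fb_threshold = 0.30,
                            min_neurons = 20) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  rows <- list()
  for (i in seq_len(nrow(dataset$cases))) {
    cid <- dataset$cases$case_id[i]
    target <- area_level_of(dataset$parcellation, dataset$cases$injected_area[i])
    rec <- dataset$records[dataset$records$case_id == cid, , drop = FALSE]
    if (nrow(rec) == 0L) next
    combos <- unique(rec[, c("hemisphere", "area")])
    # ipsilateral records in the injected area are the deposit, not a projection
    combos <- combos[!(combos$hemisphere == "ipsi" & combos$area == target), , drop = FALSE]
    for (j in seq_len(nrow(combos))) {
      hemi <- combos$hemisphere[j]; src <- combos$area[j]
      sf <- superficial_fraction(
        rec[rec$hemisphere == hemi & rec$area == src, , drop = FALSE],
        sampling_um = sampling_um, offset_um = offset_um)
      klass <- classify_laminar(sf$s_fraction, sf$n_superficial + sf$n_deep,
                                ff_threshold, fb_threshold, min_neurons)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cid, target_area = target, source_area = src,
        hemisphere = hemi, n_superficial = sf$n_superficial,
        n_deep = sf$n_deep, n_unknown = sf$n_unknown,
        s_fraction = sf$s_fraction, klass = klass,
        homotopic = hemi == "contra" & src == target,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), target_area = character(0),
               source_area = character(0), hemisphere = character(0),
               n_superficial = integer(0), n_deep = integer(0),
               n_unknown = integer(0), s_fraction = numeric(0),
               klass = character(0), homotopic = logical(0))
  out <- out[out$klass != "indeterminate", , drop = FALSE]
  # flag contralateral patterns that differ from the ipsilateral pattern of
  # the same source area in the same case
  out$differs_from_ipsi <- NA
  if (nrow(out)) {
    ipsi_key <- paste(out$case_id, out$source_area)[out$hemisphere == "ipsi"]
    ipsi_klass <- out$klass[out$hemisphere == "ipsi"]
    is_contra <- out$hemisphere == "contra"
    m <- match(paste(out$case_id, out$source_area)[is_contra], ipsi_key)
    out$differs_from_ipsi[is_contra] <- ifelse(is.na(m), NA,
                                               out$klass[is_contra] != ipsi_klass[m])
  }
  rownames(out) <- NULL
  structure(out, ff_threshold = ff_threshold, fb_threshold = fb_threshold,
            min_neurons = min_neurons)
}
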