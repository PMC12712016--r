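#' Read a labeling dataset from CSV files
#'
#' A dataset pairs injection-case metadata with per-neuron labeling records.
#' The cases file has columns
#' `case_id,species,sex,age_years,injected_hemisphere,injected_area,tracer,amount_ul`;
#' the records file has columns
#' `case_id,section_um,hemisphere,area,layer,count`. Files are UTF-8,
#' comma-separated with a header row, decimal point ".", and no thousands
#' separators. `hemisphere` is `ipsi`/`contra` relative to the injection;
#' `layer` is `superficial` (II-III), `deep` (V-VI), or `unknown`. Rows
#' default to one neuron each (`count` = 1); aggregated rows with
#' `count` > 1 are allowed so per-neuron charts and pre-summed tables share
#' one schema.
#'
#' Validation is strict: unknown columns are ignored but missing ones are a
#' schema error; records referencing an absent case or an unresolvable area
#' are a referential error naming the offending values and row numbers;
#' non-positive counts or negative section positions are value errors.
#' Nothing is silently dropped.
#'
#' @param cases_path path to the cases CSV.
#' @param records_path path to the records CSV.
#' @param parcellation a [parcellation]; defaults to [default_parcellation()].
#' @return an object of class `labeling_dataset`: a list with elements
#'   `cases`, `records` (data.frames) and `parcellation`.
#' @export
read_dataset <- function(cases_path, records_path,
                         parcellation = default_parcellation()) {
  for (p in c(cases_path, records_path))
    if (!file.exists(p)) stop_schema(paste0("file not found: ", p))
  # text columns are forced to character so labels like sex "F" or a purely
  # numeric case_id never degrade to logical/numeric on the way in
  cases <- utils::read.csv(
    cases_path, stringsAsFactors = FALSE, encoding = "UTF-8",
    colClasses = c(case_id = "character", species = "character",
                   sex = "character", injected_hemisphere = "character",
                   injected_area = "character", tracer = "character"))
  records <- utils::read.csv(
    records_path, stringsAsFactors = FALSE, encoding = "UTF-8",
    colClasses = c(case_id = "character", hemisphere = "character",
                   area = "character", layer = "character"))
  labeling_dataset(cases, records, parcellation)
}

#' Assemble and validate a labeling dataset
#'
#' @param cases data.frame of injection cases (see [read_dataset()]).
#' @param records data.frame of neuron records.
#' @inheritParams read_dataset
#' @return a `labeling_dataset`.
#' @export
labeling_dataset <- function(cases, records,
                             parcellation = default_parcellation()) {
  need_cases <- c("case_id", "injected_hemisphere", "injected_area", "tracer")
  miss <- setdiff(need_cases, names(cases))
  if (length(miss))
    stop_schema(paste0("cases table missing column(s): ", paste(miss, collapse = ", ")))
  need_rec <- c("case_id", "section_um", "hemisphere", "area", "layer")
  miss <- setdiff(need_rec, names(records))
  if (length(miss))
    stop_schema(paste0("records table missing column(s): ", paste(miss, collapse = ", ")))

  cases$case_id <- trimws(as.character(cases$case_id))
  if (anyDuplicated(cases$case_id))
    stop_value(paste0("duplicate case_id: ",
                      paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", ")))
  for (a in unique(cases$injected_area)) resolve_area(parcellation, a)
  bad_hemi <- setdiff(unique(cases$injected_hemisphere), c("L", "R"))
  if (length(bad_hemi))
    stop_value(paste0("injected_hemisphere must be L or R; got: ",
                      paste(bad_hemi, collapse = ", ")))
  if (!is.null(cases$age_years) && any(!is.na(cases$age_years) & cases$age_years < 0))
    stop_value("negative age_years")
  if (!is.null(cases$amount_ul) && any(!is.na(cases$amount_ul) & cases$amount_ul < 0))
    stop_value("negative amount_ul")

  if (nrow(records) == 0L) {
    warning("records table is empty; dataset has cases but no labeling")
    records$count <- integer(0)
  } else {
    records$case_id <- trimws(as.character(records$case_id))
    records$area <- trimws(as.character(records$area))
    if (is.null(records$count)) records$count <- 1L
    records$count[is.na(records$count)] <- 1L

    orphan <- !(records$case_id %in% cases$case_id)
    if (any(orphan))
      stop_reference(paste0("records reference unknown case(s): ",
                            paste(unique(records$case_id[orphan]), collapse = ", "),
                            " (rows ", paste(utils::head(which(orphan), 10L), collapse = ", "), ")"))
    for (a in unique(records$area)) resolve_area(parcellation, a)
    bad <- !(records$hemisphere %in% c("ipsi", "contra"))
    if (any(bad))
      stop_value(paste0("hemisphere must be ipsi/contra; bad rows: ",
                        paste(utils::head(which(bad), 10L), collapse = ", ")))
    bad <- !(records$layer %in% c("superficial", "deep", "unknown"))
    if (any(bad))
      stop_value(paste0("layer must be superficial/deep/unknown; bad rows: ",
                        paste(utils::head(which(bad), 10L), collapse = ", ")))
    if (any(records$section_um < 0))
      stop_value("section_um must be >= 0")
    if (any(records$count < 1))
      stop_value(paste0("count must be >= 1; bad rows: ",
                        paste(utils::head(which(records$count < 1), 10L), collapse = ", ")))
    records$count <- as.integer(records$count)
    records$section_um <- as.integer(records$section_um)
  }
  structure(list(cases = cases, records = records, parcellation = parcellation),
            class = "labeling_dataset")
}

#' Write a labeling dataset back to CSV
#'
#' Inverse of [read_dataset()]; writing then reading a validated dataset is
#' the identity on its cases and records tables.
#'
#' @param dataset a `labeling_dataset`.
#' @param cases_path,records_path output paths.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, cases_path, records_path) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  utils::write.csv(dataset$cases, cases_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$records, records_path, row.names = FALSE, quote = FALSE)
  invisible(c(cases_path, records_path))
}

#' Bundled per-case callosal count table
#'
#' The packaged summary of labeled-neuron counts for the 36 retrograde
#' tracer injections: for each case, the total number of labeled neurons
#' (ipsi + contra, with ipsilateral neurons inside the injected area already
#' excluded), the ipsilateral and contralateral (callosal) counts, the count
#' in the contralateral area homotopic to the injected one, the injected
#' area and its region class, and the published 1-decimal percentage columns
#' for cross-checking.
#'
#' @return data.frame with one row per injection case and columns
#'   `case_id`, `injection_label`, `injected_area`, `region`, `total`,
#'   `ipsi`, `contra`, `homotopic`, `pct_contra_printed`,
#'   `pct_homotopic_printed`.
#' @examples
#' tab <- load_table2_fixture()
#' stopifnot(nrow(tab) == 36, all(tab$total == tab$ipsi + tab$contra))
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_counts.csv", package = "cpnquant",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 36L,
            all(tab$total == tab$ipsi + tab$contra),
            all(tab$homotopic >= 0), all(tab$homotopic <= tab$contra))
  tab
}

#' Aggregate a case's records into hemisphere-level counts
#'
#' Counts labeled neurons for one case: `ipsi` is the sum over ipsilateral
#' areas *excluding the injected area* (tracer uptake at the deposit itself
#' is not an afferent projection; such records are counted separately in
#' `n_injected_area_ipsi`, never silently dropped); `contra` is the sum over
#' all contralateral areas; `homotopic` is the contralateral count in the
#' area homotopic to the injected one. The injected-area exclusion applies
#' only ipsilaterally -- contralaterally the homotopic area is a genuine
#' callosal projection and is counted.
#'
#' @param dataset a `labeling_dataset`.
#' @param case_id a case identifier present in `dataset$cases`.
#' @return one-row data.frame: `case_id`, `total`, `ipsi`, `contra`,
#'   `homotopic`, `n_injected_area_ipsi`.
#' @export
aggregate_counts <- function(dataset, case_id) {
  stopifnot(inherits(dataset, "labeling_dataset"))
  i <- match(case_id, dataset$cases$case_id)
  if (is.na(i))
    stop_reference(paste0("unknown case: '", case_id, "'"))
  injected <- area_level_of(dataset$parcellation, dataset$cases$injected_area[i])
  rec <- dataset$records[dataset$records$case_id == case_id, , drop = FALSE]
  in_inj_ipsi <- rec$hemisphere == "ipsi" & rec$area == injected
  ipsi <- sum(rec$count[rec$hemisphere == "ipsi" & !in_inj_ipsi])
  contra <- sum(rec$count[rec$hemisphere == "contra"])
  homot <- sum(rec$count[rec$hemisphere == "contra" & rec$area == injected])
  if (ipsi + contra == 0L)
    warning(sprintf("case '%s': no countable labeling outside the injected area", case_id))
  data.frame(case_id = case_id, total = ipsi + contra, ipsi = ipsi,
             contra = contra, homotopic = homot,
             n_injected_area_ipsi = sum(rec$count[in_inj_ipsi]))
}

#' @export
print.labeling_dataset <- function(x, ...) {
  cat("Labeling dataset: ", nrow(x$cases), " case(s), ",
      sum(x$records$count), " labeled neuron(s) in ", nrow(x$records),
      " record row(s)\n", sep = "")
  invisible(x)
}
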