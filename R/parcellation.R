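#' Cortical parcellations
#'
#' A parcellation is the closed vocabulary of cortical area labels used to
#' attribute injection sites and labeled neurons, together with a region
#' class for each area. Regions group areas for cross-case statistics:
#' `prefrontal`, `premotor`, `frontal_opercular`, `parietal`, `cingulate`,
#' `F1`, and `other`. F1 (primary motor cortex) is deliberately its own
#' class, distinct from `premotor`, because the frontal motor group used in
#' comparisons excludes it.
#'
#' The homotopy relation between hemispheres is the identity on area names:
#' the area homotopic to area X of one hemisphere is area X of the other.
#' Injected subfields (e.g. "46d rostral") are distinct vocabulary entries,
#' but neuron records are expected to carry area-level labels, so the
#' homotopic counterpart of a subfield injection is the whole contralateral
#' area at the granularity present in the records.
#'
#' @section Region classes:
#' `prefrontal`, `premotor`, `frontal_opercular`, `parietal`, `cingulate`,
#' `F1`, `other`.
#'
#' @param areas data.frame with columns `name`, `region`, and optionally
#'   `notes`.
#' @param version free-text tag identifying the parcellation.
#' @return An object of class `parcellation`: a data.frame of areas with a
#'   `version` attribute.
#' @examples
#' p <- parcellation(data.frame(name = c("F5a", "F2"),
#'                              region = c("premotor", "premotor")))
#' resolve_area(p, "F5a")
#' @export
parcellation <- function(areas, version = "custom") {
  if (!is.data.frame(areas) || !all(c("name", "region") %in% names(areas)))
    stop_schema("`areas` must be a data.frame with columns 'name' and 'region'")
  areas$name <- trimws(as.character(areas$name))
  areas$region <- as.character(areas$region)
  if (anyDuplicated(areas$name))
    stop_value(paste0("duplicate area names: ",
                      paste(unique(areas$name[duplicated(areas$name)]), collapse = ", ")))
  if (any(!nzchar(areas$name)))
    stop_value("empty area name in parcellation")
  bad <- setdiff(unique(areas$region), region_levels())
  if (length(bad))
    stop_value(paste0("unknown region class(es): ", paste(bad, collapse = ", "),
                      "; allowed: ", paste(region_levels(), collapse = ", ")))
  if (is.null(areas$notes)) areas$notes <- ""
  if (is.null(areas$parent)) areas$parent <- NA_character_
  areas$parent <- as.character(areas$parent)
  bad_parent <- !is.na(areas$parent) & !(areas$parent %in% areas$name)
  if (any(bad_parent))
    stop_value(paste0("subfield parent(s) not in parcellation: ",
                      paste(unique(areas$parent[bad_parent]), collapse = ", ")))
  out <- areas[, c("name", "region", "notes", "parent")]
  rownames(out) <- NULL
  structure(out, version = as.character(version),
            class = c("parcellation", "data.frame"))
}

#' @rdname parcellation
#' @export
region_levels <- function() {
  c("prefrontal", "premotor", "frontal_opercular", "parietal",
    "cingulate", "F1", "other")
}

#' Read a parcellation from a JSON file
#'
#' The file holds an object with a `version` string and an `areas` array of
#' `{name, region, notes}` records.
#'
#' @param path path to a JSON parcellation file.
#' @return a [parcellation] object.
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("parcellation file not found: ", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$areas)) stop_schema("parcellation JSON must contain an 'areas' array")
  parcellation(as.data.frame(obj$areas), version = obj$version %||% "unversioned")
}

#' The default macaque frontoparietal parcellation
#'
#' Area labels covering the prefrontal, premotor, frontal opercular,
#' parietal, cingulate, insular, and superior temporal fields used in the
#' bundled count table, including injected-subfield labels such as
#' "46d rostral". Users may substitute their own via [read_parcellation()].
#'
#' @return a [parcellation] object.
#' @export
default_parcellation <- function() {
  read_parcellation(system.file("extdata", "parcellation_default.json",
                                package = "cpnquant", mustWork = TRUE))
}

#' Resolve an area label against a parcellation
#'
#' Matching is exact after trimming surrounding whitespace; it is
#' case-sensitive and performs no fuzzy matching, so a mistyped label fails
#' loudly (with the closest known labels suggested) instead of being
#' silently misattributed.
#'
#' @param parc a [parcellation].
#' @param name an area label.
#' @return one-row data.frame with `name`, `region`, `notes`.
#' @export
resolve_area <- function(parc, name) {
  stopifnot(inherits(parc, "parcellation"))
  key <- trimws(as.character(name))
  if (length(key) != 1L || is.na(key) || !nzchar(key)) {
    stop_reference("unknown area: '' (empty label)")
  }
  i <- match(key, parc$name)
  if (is.na(i)) {
    d <- utils::adist(key, parc$name, ignore.case = TRUE)
    near <- parc$name[order(d)][seq_len(min(3L, nrow(parc)))]
    stop_reference(paste0("unknown area: '", key, "'; closest known labels: ",
                          paste(near, collapse = ", ")))
  }
  as.data.frame(parc)[i, , drop = FALSE]
}

#' Homotopic counterpart of an area
#'
#' The homotopy map between hemispheres is the identity on area names, so
#' this returns the same-named area; it exists to make the mapping an
#' explicit, testable step (and an involution by construction).
#'
#' @inheritParams resolve_area
#' @return the homotopic area label (identical to the resolved input name).
#' @export
homotopic_of <- function(parc, name) {
  resolve_area(parc, name)$name
}

#' Area-level label of a (possibly subfield) label
#'
#' Injection sites are often labeled at subfield granularity
#' ("46d rostral") while neuron records carry area-level labels ("46d").
#' For counting purposes -- in particular for identifying homotopic
#' callosal neurons after a subfield injection -- the subfield maps to its
#' parent area; labels without a parent map to themselves. By convention
#' the homotopic counterpart of a subfield injection is the whole
#' contralateral area at the granularity present in the records (whether a
#' homotopic count after a subfield injection should instead cover only the
#' mirror subfield is undecidable from area-level records; this convention
#' is the coarser, conservative reading).
#'
#' @inheritParams resolve_area
#' @return an area-level label.
#' @export
area_level_of <- function(parc, name) {
  a <- resolve_area(parc, name)
  if (!is.na(a$parent)) a$parent else a$name
}

#' Region class of an area
#'
#' @inheritParams resolve_area
#' @return one of [region_levels()].
#' @export
region_of <- function(parc, name) {
  resolve_area(parc, name)$region
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation '", attr(x, "version"), "': ", nrow(x), " areas (",
      paste(names(table(x$region)), table(x$region), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
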