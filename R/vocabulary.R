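#' Respiratory drug-class vocabulary
#'
#' The pipeline works at drug-class level. Fourteen classes appear in raw
#' exposure records: ten single classes (including oral systemic
#' glucocorticoids) and four fixed-combination inhaler products. After era
#' construction, systemic glucocorticoid eras are resolved into
#' `steroid_burst` (< 30 days) or `steroid_maintenance` (>= 30 days), giving
#' the 15-label set used by events and trajectories.
#'
#' @return Character vector of class names.
#' @export
drug_classes <- function() {
  c("SABA", "SAMA", "LABA", "LAMA", "ICS", "LTRA", "xanthines",
    "PDE4", "biologics", "systemic_glucocorticoid",
    "SABA-SAMA", "LABA-LAMA", "LABA-ICS", "LABA-LAMA-ICS")
}

#' @rdname drug_classes
#' @export
era_classes <- function() {
  c(setdiff(drug_classes(), "systemic_glucocorticoid"),
    "steroid_burst", "steroid_maintenance")
}

#' Canonical label for a set of drug classes
#'
#' A treatment event holds one or more classes at once. The canonical label
#' is the alphabetically sorted class set joined with `+`; fixed-combination
#' products (e.g. `LABA-ICS`) are atomic members, distinct from loose
#' combinations of their parts.
#'
#' @param classes character vector of era-level class names.
#' @return Single string label.
#' @export
canonical_label <- function(classes) {
  stopifnot(length(classes) >= 1)
  paste(sort(unique(classes)), collapse = "+")
}

#' Split a canonical label back into its class set
#' @param label canonical label string.
#' @return Character vector of class names.
#' @export
label_classes <- function(label) {
  strsplit(label, "+", fixed = TRUE)[[1]]
}
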