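#' Region vocabularies
#'
#' The normative reference is fitted for 13 regional volumes: total tissue
#' volume, cortical gray matter, white matter, cerebellum, brainstem,
#' extracerebral CSF, ventricles, and the left/right caudate, lentiform and
#' thalamus. Total tissue volume is never measured directly: it is the sum of
#' cortical gray matter, white matter, cerebellum, brainstem, total deep gray
#' matter, and hippocampus+amygdala. The two summation-only compartments
#' (total deep gray matter, hippocampus+amygdala) are carried through the
#' simulator solely so the summation rule can be honoured; no normative curve
#' is fitted for them.
#'
#' @return `modelled_regions()` returns the 13 region labels a normative
#'   model is fitted for; `ttv_components()` the six compartments whose sum
#'   defines total tissue volume; `simulated_regions()` every column the
#'   simulator produces.
#' @export
modelled_regions <- function() {
  c("total_tissue", "cortical_gm", "white_matter", "cerebellum", "brainstem",
    "csf", "ventricles",
    "caudate_l", "caudate_r", "lentiform_l", "lentiform_r",
    "thalamus_l", "thalamus_r")
}

#' @rdname modelled_regions
#' @export
ttv_components <- function() {
  c("cortical_gm", "white_matter", "cerebellum", "brainstem",
    "deep_gm_total", "hippo_amygdala")
}

#' @rdname modelled_regions
#' @export
simulated_regions <- function() {
  union(setdiff(modelled_regions(), "total_tissue"), ttv_components())
}

# columns preceding the region volumes in a scan table
scan_id_cols <- function() {
  c("subject_id", "group", "sex", "ga_birth_weeks", "pma_scan_weeks",
    "postnatal_days", "timepoint")
}
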