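#' Analysis end points
#'
#' The outcome panel mirrors a typical SVD severity study: a primary DTI
#' marker (mean diffusivity normalized histogram peak height, MDNPH),
#' secondary MRI markers (microbleed and lacune counts, white matter
#' hyperintensity volume as a percentage of brain volume, total brain volume,
#' peak width of skeletonized mean diffusivity), cognition (global cognition,
#' executive function, processing speed), disability (Barthel index) and a
#' simple 0-3 MRI severity score. Every end point is oriented so that a
#' higher value means greater SVD burden / worse cognition, then z-scored.
#'
#' @return `svd_endpoints()` returns the continuous end-point identifiers;
#'   `svd_binary_endpoints()` the derived binary end points;
#'   `default_orientation()` a named sign vector (`-1` where the raw measure
#'   is "higher is better" and must be flipped, e.g. total brain volume
#'   analysed as brain atrophy).
#' @export
svd_endpoints <- function() {
  c("mdnph", "microbleed_count", "lacune_count", "log_wmh", "brain_atrophy",
    "psmd", "global_cognition", "executive_function", "processing_speed",
    "barthel_index", "simple_svd_score")
}

#' @rdname svd_endpoints
#' @export
svd_binary_endpoints <- function() c("microbleed_presence", "lacune_presence")

#' @rdname svd_endpoints
#' @export
default_orientation <- function() {
  c(mdnph = -1, microbleed_count = 1, lacune_count = 1, log_wmh = 1,
    brain_atrophy = -1, psmd = 1, global_cognition = -1,
    executive_function = -1, processing_speed = -1, barthel_index = -1,
    simple_svd_score = 1)
}

# raw measures carried in the subject phenotype table (one column each,
# per visit); log_wmh / brain_atrophy are derived from wmh_percent /
# total_brain_volume at analysis time
raw_outcome_names <- function() {
  c("mdnph", "microbleed_count", "lacune_count", "wmh_percent",
    "total_brain_volume", "psmd", "global_cognition", "executive_function",
    "processing_speed", "barthel_index", "fazekas_grade")
}

# map an end point to the raw measure it is computed from
endpoint_raw_source <- function() {
  c(mdnph = "mdnph", microbleed_count = "microbleed_count",
    lacune_count = "lacune_count", log_wmh = "wmh_percent",
    brain_atrophy = "total_brain_volume", psmd = "psmd",
    global_cognition = "global_cognition",
    executive_function = "executive_function",
    processing_speed = "processing_speed", barthel_index = "barthel_index")
}

# end points a true (planted) effect can be attached to in the simulator:
# continuous ones receive linear effects in SD units, binary presences
# receive log-odds, dementia a log hazard ratio
effect_endpoints <- function() {
  c("mdnph", "log_wmh", "brain_atrophy", "psmd", "global_cognition",
    "executive_function", "processing_speed", "barthel_index",
    "microbleed_presence", "lacune_presence", "dementia")
}
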