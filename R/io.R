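#' Read and write pipeline files
#'
#' All on-disk formats are plain CSV/JSON. `intensities.csv` has features in
#' rows (`feature_id` column) and sample ids in columns; `samples.csv` is the
#' run manifest; `subjects.csv` has one row per subject with follow-up visits
#' flattened to `<outcome>_y<time>` columns; `truth.json` records the planted
#' ground truth.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `write_simulation()` invisibly returns the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "intensities.csv"),
             samples = file.path(dir, "samples.csv"),
             subjects = file.path(dir, "subjects.csv"),
             truth = file.path(dir, "truth.json"))
  write_intensities(sim$raw, paths[["intensities"]])
  readr::write_csv(sim$manifest, paths[["samples"]])
  readr::write_csv(flatten_subjects(sim$subjects, sim$visits),
                   paths[["subjects"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = truth$seed,
         effect_matrix = truth$effect_matrix,
         drift_coefficients = truth$drift_coefficients,
         batch_offsets = truth$batch_offsets,
         bad_features = truth$bad_features),
    paths[["truth"]], digits = NA, auto_unbox = TRUE, na = "null")
  invisible(paths)
}

#' @rdname write_simulation
#' @param x an [intensity_matrix()].
#' @param path file path.
#' @export
write_intensities <- function(x, path) {
  df <- tibble::as_tibble(as.matrix(x), rownames = "feature_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_simulation
#' @param state processing state to stamp on the matrix read back.
#' @param platform platform label.
#' @export
read_intensities <- function(path, state = "raw", platform = "lipid RPC+") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  intensity_matrix(m, state = state, platform = platform)
}

#' @rdname write_simulation
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", subject_id = "c", sample_type = "c",
                    run_order = "i", batch = "i", dilution_fraction = "d",
                    platform = "c"))
}

# one row per subject; visit values become <outcome>_y<time> columns
flatten_subjects <- function(subjects, visits) {
  wide <- tidyr::pivot_wider(visits,
                             names_from = c("outcome", "time"),
                             values_from = "value", names_sep = "_y")
  dplyr::left_join(subjects, wide, by = "subject_id")
}

#' @rdname write_simulation
#' @export
read_subjects <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  visit_cols <- grep("_y[0-9.]+$", names(df), value = TRUE)
  subjects <- df[, setdiff(names(df), visit_cols)]
  visits <- tidyr::pivot_longer(df[, c("subject_id", visit_cols)],
                                -"subject_id",
                                names_to = c("outcome", "time"),
                                names_pattern = "^(.*)_y([0-9.]+)$",
                                values_to = "value")
  visits$time <- as.numeric(visits$time)
  visits <- dplyr::arrange(visits[!is.na(visits$value) | visits$time == 0, ],
                           .data$subject_id, .data$outcome, .data$time)
  list(subjects = tibble::as_tibble(subjects),
       visits = visits[, c("subject_id", "time", "outcome", "value")])
}
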