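#' Generate the analytical run sequence
#'
#' Lays out study samples, pooled QC injections and dilution-series blocks in
#' run order. Study samples are analysed in randomized order and split into
#' `n_batches` contiguous batches. Within each batch the full dilution design
#' is injected at the start and at the end, a pooled QC sample opens the
#' batch, one pooled QC follows every `qc_interval` study samples, and a
#' pooled QC closes the batch.
#'
#' @param config a [sim_config()].
#' @param subject_ids optional character vector of study subject ids (one
#'   serum sample each); defaults to ids derived from `config$n_subjects`.
#' @return A tibble (the sample manifest) with columns `sample_id`,
#'   `subject_id`, `sample_type` (`study`, `pooled_qc`, `dilution_qc`),
#'   `run_order`, `batch`, `dilution_fraction`, `platform`.
#' @export
make_run_sequence <- function(config, subject_ids = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(subject_ids)) subject_ids <- default_subject_ids(config)
  set.seed(child_seed(config$seed, 1))
  ord <- sample(subject_ids)
  n_study <- length(ord)
  nb <- config$n_batches
  # contiguous near-equal batches of the randomized order
  sizes <- rep(n_study %/% nb, nb) + c(rep(1, n_study %% nb),
                                       rep(0, nb - n_study %% nb))
  if (any(config$qc_interval >= sizes)) {
    stop("degenerate QC design: qc_interval (", config$qc_interval,
         ") must be smaller than the number of study samples per batch (",
         min(sizes), ")", call. = FALSE)
  }
  batch_of <- rep(seq_len(nb), sizes)
  rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    subj_b <- ord[batch_of == b]
    dil <- dilution_block(config, b)
    out <- list(dilution_rows(dil, b, "S"),
                qc_row(b, 0L))
    qc_i <- 1L
    k <- config$qc_interval
    for (start in seq(1L, length(subj_b), by = k)) {
      chunk <- subj_b[start:min(start + k - 1L, length(subj_b))]
      out[[length(out) + 1L]] <- study_rows(chunk, b)
      out[[length(out) + 1L]] <- qc_row(b, qc_i)
      qc_i <- qc_i + 1L
    }
    out[[length(out) + 1L]] <- dilution_rows(dil, b, "E")
    rows[[b]] <- dplyr::bind_rows(out)
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$run_order <- seq_len(nrow(manifest))
  manifest$platform <- config$platform
  tibble::as_tibble(manifest[, c("sample_id", "subject_id", "sample_type",
                                 "run_order", "batch", "dilution_fraction",
                                 "platform")])
}

default_subject_ids <- function(config) {
  unlist(lapply(seq_along(config$n_subjects), function(i) {
    sprintf("%s_%04d", names(config$n_subjects)[i],
            seq_len(config$n_subjects[i]))
  }), use.names = FALSE)
}

dilution_block <- function(config, batch) {
  dd <- config$dilution_design
  rep(dd$fraction, dd$replicates)
}

dilution_rows <- function(fractions, batch, tag) {
  data.frame(sample_id = sprintf("DQC_B%d%s_%02d", batch, tag,
                                 seq_along(fractions)),
             subject_id = NA_character_, sample_type = "dilution_qc",
             batch = batch, dilution_fraction = fractions,
             stringsAsFactors = FALSE)
}

qc_row <- function(batch, i) {
  data.frame(sample_id = sprintf("QC_B%d_%03d", batch, i),
             subject_id = NA_character_, sample_type = "pooled_qc",
             batch = batch, dilution_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

study_rows <- function(subjects, batch) {
  data.frame(sample_id = paste0("SMP_", subjects), subject_id = subjects,
             sample_type = "study", batch = batch,
             dilution_fraction = NA_real_, stringsAsFactors = FALSE)
}
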