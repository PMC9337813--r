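# Independent scalar oracles used to cross-check the vectorized pipeline.

# RSD by its definition
oracle_rsd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2 || mean(x) <= 0) return(NA_real_)
  100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
}

# Benjamini-Hochberg step-up by explicit sort / cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- (m / seq_len(m)) * p[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# per-feature scalar recomputation of the three selection criteria (plus the
# missingness rule), straight from the thresholds
oracle_feature_pass <- function(vals, manifest, params, has_dilution) {
  type <- manifest$sample_type[match(names(vals), manifest$sample_id)]
  rsd_qc <- oracle_rsd(vals[type == "pooled_qc"])
  rsd_study <- oracle_rsd(vals[type == "study"])
  study_vals <- vals[type == "study"]
  miss <- mean(is.na(study_vals))
  pass1 <- !is.na(rsd_qc) && rsd_qc < params$rsd_qc_max
  pass2 <- TRUE
  if (has_dilution) {
    dv <- vals[type == "dilution_qc"]
    fr <- manifest$dilution_fraction[match(names(dv), manifest$sample_id)]
    ok <- !is.na(dv)
    r <- if (length(unique(fr[ok])) >= 3 && isTRUE(sd(dv[ok]) > 0)) {
      cor(dv[ok], fr[ok])
    } else NA_real_
    pass2 <- !is.na(r) && r > params$dilution_r_min
  }
  pass3 <- !is.na(rsd_qc) && !is.na(rsd_study) &&
    rsd_study > params$study_to_qc_rsd_ratio_min * rsd_qc
  pass1 && pass2 && pass3 && miss <= params$max_missing_study
}

# small fast simulation configs for unit tests
tiny_cfg <- function(...) {
  sim_config(n_subjects = c(cohort_A = 20, cohort_B = 60), n_features = 15,
             qc_interval = 5, seed = 42, ...)
}
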