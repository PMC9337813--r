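#' Analysis-suite configuration
#'
#' @param adjustments adjustment sets to run: `"demographic"` (cohort,
#'   baseline age, sex) and/or `"extended"` (demographic plus diabetes,
#'   hypertension and hypercholesterolaemia status).
#' @param strata strata to run, from `"all"`, `"cohort_A"`, `"cohort_B"`,
#'   `"age_lt65"`, `"age_ge65"`, `"fazekas_ge2"`.
#' @param analyses model families to run: `"baseline"` (cross-sectional),
#'   `"change"` (annualized change), `"dementia"` (Cox).
#' @param outcomes restrict to these end points (`NULL` = all).
#' @param min_stratum_n strata with fewer subjects are skipped with a
#'   logged reason (default 25).
#' @param min_events minimum dementia events for the Cox family.
#' @param fdr_alpha discovery threshold on the q-value.
#' @return A `suite_config` list.
#' @export
suite_config <- function(adjustments = c("demographic", "extended"),
                         strata = "all",
                         analyses = c("baseline", "change", "dementia"),
                         outcomes = NULL,
                         min_stratum_n = 25,
                         min_events = 10,
                         fdr_alpha = 0.05) {
  adjustments <- match.arg(adjustments, several.ok = TRUE)
  strata <- match.arg(strata, c("all", "cohort_A", "cohort_B", "age_lt65",
                                "age_ge65", "fazekas_ge2"), several.ok = TRUE)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(adjustments = adjustments, strata = strata,
                 analyses = analyses, outcomes = outcomes,
                 min_stratum_n = min_stratum_n, min_events = min_events,
                 fdr_alpha = fdr_alpha),
            class = "suite_config")
}

covariate_frame <- function(subjects, adjustment) {
  base <- data.frame(cohort = factor(subjects$cohort),
                     age = subjects$age,
                     sex = factor(subjects$sex))
  if (adjustment == "extended") {
    base$diabetes <- as.integer(subjects$diabetes)
    base$hypertension <- as.integer(subjects$hypertension)
    base$hypercholesterolaemia <- as.integer(subjects$hypercholesterolaemia)
  }
  base
}

covariate_matrix <- function(subjects, adjustment) {
  df <- covariate_frame(subjects, adjustment)
  mm <- stats::model.matrix(~ ., df)[, -1, drop = FALSE]
  drop_constant_cols(mm)
}

stratum_mask <- function(stratum, subjects, fazekas) {
  switch(stratum,
         all = rep(TRUE, nrow(subjects)),
         cohort_A = subjects$cohort == sort(unique(subjects$cohort))[1],
         cohort_B = subjects$cohort == sort(unique(subjects$cohort))[
           min(2, length(unique(subjects$cohort)))] &
           length(unique(subjects$cohort)) > 1,
         age_lt65 = subjects$age < 65,
         age_ge65 = subjects$age >= 65,
         fazekas_ge2 = !is.na(fazekas[subjects$subject_id]) &
           fazekas[subjects$subject_id] >= 2,
         stop("unknown stratum: ", stratum))
}

#' Run the metabolome-wide association suite
#'
#' Fits every requested metabolite x outcome x model combination:
#' cross-sectional linear models for the z-scored oriented continuous end
#' points, logistic models for the binary end points, linear models for the
#' z-scored oriented annualized changes, and Cox models for incident
#' dementia; under one or both adjustment sets and the requested strata.
#' q-values are Benjamini-Hochberg adjusted within each (analysis, outcome,
#' adjustment, stratum) family across metabolites; non-estimable fits are
#' excluded from their family.
#'
#' @param metabolites matrix, features x subjects (autoscaled; column names
#'   are subject ids), e.g. from [metabolites_by_subject()].
#' @param subjects subject table (see [simulate_subjects()]).
#' @param visits long visit table.
#' @param config a [suite_config()].
#' @param orientation named sign vector for the outcome panel, see
#'   [default_orientation()].
#' @return tibble, one row per (metabolite, outcome, model spec):
#'   `metabolite_id`, `outcome_id`, `analysis`, `family`, `adjustment`,
#'   `stratum`, `n_used`, `effect`, `se`, `ci_low`, `ci_high`, `p`, `q`,
#'   `significant`, `estimable`, `reason`. Skipped strata are recorded in
#'   `attr(, "skipped_strata")`.
#' @export
run_analysis_suite <- function(metabolites, subjects, visits,
                               config = suite_config(),
                               orientation = default_orientation()) {
  empty <- dplyr::mutate(empty_result(), q = double(),
                         significant = logical())
  if (is.null(metabolites) || nrow(metabolites) == 0) return(empty)
  ids <- intersect(colnames(metabolites), subjects$subject_id)
  assert_that(length(ids) > 0, "no overlap between metabolites and subjects")
  subjects <- subjects[match(ids, subjects$subject_id), ]
  M_all <- t(metabolites[, ids, drop = FALSE])  # subjects x features

  panel <- orient_and_scale_outcomes(baseline_outcomes(visits), orientation)
  z <- panel$z[match(ids, panel$z$subject_id), ]
  bin <- panel$binary[match(ids, panel$binary$subject_id), ]

  cont_eps <- setdiff(names(z), "subject_id")
  bin_eps <- svd_binary_endpoints()
  if (!is.null(config$outcomes)) {
    cont_eps <- intersect(cont_eps, config$outcomes)
    bin_eps <- intersect(bin_eps, config$outcomes)
  }

  changes <- NULL
  if ("change" %in% config$analyses) {
    ch <- annualized_changes(visits)
    ch <- ch[match(ids, ch$subject_id), ]
    ori <- orientation
    changes <- tibble::tibble(subject_id = ids)
    for (ep in intersect(names(ch), names(ori))) {
      if (!is.null(config$outcomes) && !ep %in% config$outcomes) next
      v <- ori[[ep]] * ch[[ep]]
      s <- sd_na(v)
      if (is.na(s) || s == 0) next
      changes[[ep]] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }

  out <- list()
  skipped <- list()
  for (stratum in config$strata) {
    mask <- stratum_mask(stratum, subjects, panel$fazekas)
    n_s <- sum(mask, na.rm = TRUE)
    if (n_s < config$min_stratum_n) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(stratum = stratum, n = n_s,
                       reason = sprintf("stratum n = %d below floor %d",
                                        n_s, config$min_stratum_n))
      next
    }
    subj_s <- subjects[mask, ]
    M_s <- M_all[mask, , drop = FALSE]
    for (adjustment in config$adjustments) {
      C <- covariate_matrix(subj_s, adjustment)
      covdf <- as.data.frame(C)
      if ("baseline" %in% config$analyses) {
        for (ep in cont_eps) {
          out[[length(out) + 1L]] <- linear_family(
            M_s, z[[ep]][mask], C, covdf, ep, "baseline", "linear",
            adjustment, stratum)
        }
        for (ep in bin_eps) {
          y <- bin[[ep]][mask]
          out[[length(out) + 1L]] <- dplyr::bind_rows(lapply(
            colnames(M_s), function(f) fit_metabolite_outcome(
              M_s[, f], y, covdf, family = "logistic", metabolite_id = f,
              outcome_id = ep, adjustment = adjustment, stratum = stratum)))
        }
      }
      if ("change" %in% config$analyses && !is.null(changes)) {
        for (ep in setdiff(names(changes), "subject_id")) {
          out[[length(out) + 1L]] <- linear_family(
            M_s, changes[[ep]][mask], C, covdf, ep, "change", "linear",
            adjustment, stratum)
        }
      }
      if ("dementia" %in% config$analyses &&
          sum(subj_s$dementia_event, na.rm = TRUE) > 0) {
        out[[length(out) + 1L]] <- dplyr::bind_rows(lapply(
          colnames(M_s), function(f) fit_dementia_cox(
            M_s[, f], subj_s$dementia_time, subj_s$dementia_event, covdf,
            min_events = config$min_events, metabolite_id = f,
            adjustment = adjustment, stratum = stratum)))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$analysis, .data$outcome_id,
                        .data$adjustment, .data$stratum, .data$metabolite_id)
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$analysis, .data$outcome_id, .data$adjustment,
                    .data$stratum),
    q = bh_fdr(ifelse(.data$estimable, .data$p, NA_real_)))
  res <- dplyr::ungroup(res)
  res$significant <- !is.na(res$q) & res$q < config$fdr_alpha
  attr(res, "skipped_strata") <- dplyr::bind_rows(skipped)
  res
}

# linear family over a metabolite matrix: fast exact path when complete,
# per-metabolite lm() fallback when missing values are present
linear_family <- function(M, y, C, covdf, outcome_id, analysis, family,
                          adjustment, stratum) {
  ok_rows <- !is.na(y) & stats::complete.cases(C)
  if (!anyNA(M[ok_rows, , drop = FALSE])) {
    n <- sum(ok_rows)
    if (n < ncol(C) + 3) {
      return(result_row(colnames(M), outcome_id, analysis, family,
                        adjustment, stratum, n_used = n,
                        reason = "insufficient complete cases"))
    }
    fast <- linear_assoc_matrix(M[ok_rows, , drop = FALSE], y[ok_rows],
                                C[ok_rows, , drop = FALSE])
    return(tibble::tibble(
      metabolite_id = fast$metabolite_id, outcome_id = outcome_id,
      analysis = analysis, family = family, adjustment = adjustment,
      stratum = stratum, n_used = fast$n_used, effect = fast$effect,
      se = fast$se, ci_low = fast$effect - stats::qnorm(0.975) * fast$se,
      ci_high = fast$effect + stats::qnorm(0.975) * fast$se, p = fast$p,
      estimable = fast$estimable, reason = fast$reason))
  }
  dplyr::bind_rows(lapply(colnames(M), function(f) fit_metabolite_outcome(
    M[, f], y, covdf, family = "linear", metabolite_id = f,
    outcome_id = outcome_id, adjustment = adjustment, stratum = stratum,
    analysis = analysis)))
}
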