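#' Association summary grid
#'
#' One cell per metabolite x outcome for a chosen model specification, in
#' the style of an association heatmap: the cell value is
#' `sign(effect) * (-log10 p)` (positive = metabolite associated with
#' greater SVD burden), with a single star at `p < 0.05` and a double star
#' at FDR `q < 0.05`.
#'
#' @param results suite result table from [run_analysis_suite()].
#' @param analysis,adjustment,stratum model specification to summarize.
#' @return tibble: `metabolite_id`, `outcome_id`, `effect`,
#'   `signed_log10_p`, `sig_p`, `sig_q`, `stars`.
#' @export
build_summary_matrix <- function(results, analysis = "baseline",
                                 adjustment = "extended", stratum = "all") {
  sel <- results$analysis == analysis & results$adjustment == adjustment &
    results$stratum == stratum
  if (!any(sel)) {
    avail <- unique(results[, c("analysis", "adjustment", "stratum")])
    stop("no results for the requested model spec; available: ",
         paste(sprintf("(%s, %s, %s)", avail$analysis, avail$adjustment,
                       avail$stratum), collapse = ", "), call. = FALSE)
  }
  r <- results[sel & results$estimable, ]
  out <- tibble::tibble(
    metabolite_id = r$metabolite_id, outcome_id = r$outcome_id,
    effect = r$effect,
    signed_log10_p = sign(r$effect) * (-log10(pmax(r$p, 1e-300))),
    sig_p = r$p < 0.05,
    sig_q = !is.na(r$q) & r$q < 0.05)
  out$stars <- ifelse(out$sig_q, "**", ifelse(out$sig_p, "*", ""))
  dplyr::arrange(out, .data$outcome_id, .data$metabolite_id)
}

#' Hazard-ratio (forest-style) table for incident dementia
#'
#' Exponentiates the Cox log hazard ratios into hazard ratios per 1-SD
#' higher metabolite level with 95% CIs, sorted by p-value, flagging
#' associations at `p < 0.05`. Non-estimable fits are excluded; their count
#' is attached as `attr(, "n_excluded")`.
#'
#' @param results suite result table (rows with `family == "cox"` are used).
#' @param adjustment,stratum model specification.
#' @return tibble: `metabolite_id`, `n_used`, `hr`, `hr_low`, `hr_high`,
#'   `p`, `q`, `sig_p`.
#' @export
build_hazard_table <- function(results, adjustment = "demographic",
                               stratum = "all") {
  r <- results[results$family == "cox" & results$adjustment == adjustment &
                 results$stratum == stratum, ]
  n_excl <- sum(!r$estimable)
  r <- r[r$estimable, ]
  out <- tibble::tibble(
    metabolite_id = r$metabolite_id, n_used = r$n_used,
    hr = exp(r$effect), hr_low = exp(r$ci_low), hr_high = exp(r$ci_high),
    p = r$p, q = r$q, sig_p = r$p < 0.05)
  out <- dplyr::arrange(out, .data$p)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Association heatmap
#'
#' Tile plot of a [build_summary_matrix()] grid (requires ggplot2).
#'
#' @param summary tibble from [build_summary_matrix()].
#' @return a ggplot object.
#' @export
plot_association_heatmap <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_association_heatmap() needs the ggplot2 package",
         call. = FALSE)
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$outcome_id, y = .data$metabolite_id,
                               fill = .data$signed_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = expression(sign(beta) %*% -log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
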