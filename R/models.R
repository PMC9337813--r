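#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values within one testing family (all metabolites
#' tested against one outcome under one model specification). `q < 0.05`
#' declares a discovery.
#'
#' @param p numeric vector of two-sided p-values in `[0, 1]` (NA allowed;
#'   propagated).
#' @return q-values, monotone non-decreasing in `p`, each `>= p`.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) stop("p-values outside [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  # adjust over the tested (non-missing) family members only
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

empty_result <- function() {
  tibble::tibble(metabolite_id = character(), outcome_id = character(),
                 analysis = character(), family = character(),
                 adjustment = character(), stratum = character(),
                 n_used = integer(), effect = double(), se = double(),
                 ci_low = double(), ci_high = double(), p = double(),
                 estimable = logical(), reason = character())
}

result_row <- function(metabolite_id, outcome_id, analysis, family,
                       adjustment, stratum, n_used = NA_integer_,
                       effect = NA_real_, se = NA_real_, p = NA_real_,
                       estimable = FALSE, reason = "") {
  zc <- stats::qnorm(0.975)
  tibble::tibble(metabolite_id = metabolite_id, outcome_id = outcome_id,
                 analysis = analysis, family = family,
                 adjustment = adjustment, stratum = stratum,
                 n_used = as.integer(n_used), effect = effect, se = se,
                 ci_low = effect - zc * se, ci_high = effect + zc * se,
                 p = p, estimable = estimable, reason = reason)
}

# drop covariate columns without variation (e.g. a single-cohort stratum);
# records a warning once per call site via attr
drop_constant_cols <- function(C) {
  if (is.null(dim(C)) || ncol(C) == 0) return(C)
  keep <- apply(C, 2, function(x) length(unique(x[!is.na(x)])) > 1L)
  C[, keep, drop = FALSE]
}

#' Single metabolite-outcome association fit
#'
#' Fits the association of one z-scored (per 1-SD) metabolite with one
#' outcome by ordinary linear regression (continuous outcomes) or logistic
#' regression (binary outcomes), adjusted for the supplied covariates. The
#' effect is the metabolite coefficient (SD of outcome, or log-odds, per
#' 1-SD metabolite) with its Wald two-sided p-value and 95% CI. Collinear
#' designs and perfect separation yield a non-estimable flagged result that
#' is excluded from the FDR family.
#'
#' @param metabolite numeric vector, autoscaled metabolite (1-SD units).
#' @param outcome numeric (linear) or logical/0-1 (logistic) outcome vector.
#' @param covariates data frame of adjustment covariates (constant columns
#'   are dropped automatically).
#' @param family `"linear"` or `"logistic"`.
#' @param metabolite_id,outcome_id,adjustment,stratum,analysis labels
#'   carried into the result row.
#' @return one-row tibble (an association result).
#' @export
fit_metabolite_outcome <- function(metabolite, outcome, covariates,
                                   family = c("linear", "logistic"),
                                   metabolite_id = "met", outcome_id = "y",
                                   adjustment = "demographic",
                                   stratum = "all", analysis = "baseline") {
  family <- match.arg(family)
  df <- data.frame(.y = as.numeric(outcome), .met = metabolite, covariates,
                   check.names = TRUE)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  row <- function(...) result_row(metabolite_id, outcome_id,
                                  analysis = analysis, family = family,
                                  adjustment = adjustment, stratum = stratum,
                                  ...)
  p_design <- ncol(df)  # y + met + covariates
  if (n < p_design + 2) {
    return(row(n_used = n, reason = "insufficient complete cases"))
  }
  X <- df[, -(1:2), drop = FALSE]
  X <- X[, vapply(X, function(x) length(unique(x)) > 1L, logical(1)),
         drop = FALSE]
  dat <- cbind(df[, 1:2], X)
  sep <- FALSE
  fit <- withCallingHandlers(
    if (family == "linear") stats::lm(.y ~ ., data = dat)
    else stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  # any aliased coefficient means the metabolite effect is not the adjusted
  # effect the model specifies (e.g. metabolite identical to a covariate)
  if (anyNA(coef(fit)) || !".met" %in% names(coef(fit))) {
    return(row(n_used = n, reason = "collinear design"))
  }
  co <- summary(fit)$coefficients
  if (family == "logistic" && (sep || co[".met", 2] > 50)) {
    return(row(n_used = n, reason = "possible separation"))
  }
  row(n_used = n, effect = co[".met", 1], se = co[".met", 2],
      p = co[".met", 4], estimable = TRUE)
}

#' Cox model for incident dementia
#'
#' Fits a Cox proportional hazards model for conversion to dementia per
#' 1-SD higher metabolite level, adjusted for the supplied covariates, with
#' ties handled by Efron's method. The effect is the log hazard ratio.
#'
#' @param metabolite z-scored metabolite vector.
#' @param dementia_time follow-up time in years (event or censoring).
#' @param dementia_event logical event indicator.
#' @param covariates data frame of adjustment covariates.
#' @param min_events minimum number of events required for an estimable fit
#'   (default 10).
#' @param metabolite_id,adjustment,stratum labels carried into the result.
#' @return one-row tibble (an association result with `family = "cox"`).
#' @export
fit_dementia_cox <- function(metabolite, dementia_time, dementia_event,
                             covariates, min_events = 10,
                             metabolite_id = "met",
                             adjustment = "demographic", stratum = "all") {
  df <- data.frame(.t = dementia_time, .e = as.integer(dementia_event),
                   .met = metabolite, covariates, check.names = TRUE)
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  n_events <- sum(df$.e)
  row <- function(...) result_row(metabolite_id, outcome_id = "dementia",
                                  analysis = "dementia", family = "cox",
                                  adjustment = adjustment, stratum = stratum,
                                  ...)
  if (n_events == 0) stop("no events", call. = FALSE)
  if (n_events < min_events) {
    return(row(n_used = n, reason = sprintf("only %d events (need >= %d)",
                                            n_events, min_events)))
  }
  X <- df[, -(1:3), drop = FALSE]
  X <- X[, vapply(X, function(x) length(unique(x)) > 1L, logical(1)),
         drop = FALSE]
  dat <- cbind(df[, 1:3], X)
  mono <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(survival::Surv(.t, .e) ~ . - .t - .e, data = dat,
                      ties = "efron"),
      warning = function(w) {
        if (grepl("infinite|did not converge|beta may be",
                  conditionMessage(w))) mono <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || !".met" %in% names(coef(fit)) || anyNA(coef(fit))) {
    return(row(n_used = n, reason = "degenerate Cox fit"))
  }
  co <- summary(fit)$coefficients
  if (mono || co[".met", "se(coef)"] > 50) {
    return(row(n_used = n, reason = "monotone likelihood"))
  }
  row(n_used = n, effect = co[".met", "coef"], se = co[".met", "se(coef)"],
      p = co[".met", "Pr(>|z|)"], estimable = TRUE)
}

# Fast exact linear MWAS for a matrix of metabolites sharing one outcome and
# covariate set (no missing values): residualize outcome and metabolites on
# the covariates once (Frisch-Waugh-Lovell), then per-metabolite slope,
# SE and Wald p identical to the corresponding full lm() coefficient.
linear_assoc_matrix <- function(M, y, C) {
  n <- length(y)
  X <- cbind(rep(1, n), C)
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RM <- qr.resid(qrX, M)
  sxx <- colSums(RM^2)
  sxy <- colSums(RM * ry)
  df <- n - qrX$rank - 1L
  ok <- sxx > 1e-10 * n & df > 0
  beta <- se <- p <- rep(NA_real_, ncol(M))
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- sum(ry^2) - beta[ok]^2 * sxx[ok]
  sigma2 <- pmax(rss, 0) / df
  se[ok] <- sqrt(sigma2 / sxx[ok])
  tval <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tibble::tibble(metabolite_id = colnames(M), effect = beta, se = se, p = p,
                 n_used = n, estimable = ok,
                 reason = ifelse(ok, "", "collinear design"))
}
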