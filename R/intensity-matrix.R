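#' Feature-by-sample intensity matrix
#'
#' A light container for a metabolomics intensity matrix: a numeric matrix
#' with features in rows and analytical samples in columns plus a processing
#' `state` that advances `raw -> corrected -> transformed -> scaled` and a
#' platform label. Row and column names must be unique; values must be
#' non-negative in the `raw` and `corrected` states (missing allowed).
#'
#' @param values numeric matrix, features x samples, with unique dimnames.
#' @param state processing state, one of `"raw"`, `"corrected"`,
#'   `"transformed"`, `"scaled"`.
#' @param platform platform label (e.g. `"lipid RPC+"`, `"HILIC+"`,
#'   `"NMR-1D"`).
#' @return An `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, state = "raw", platform = "lipid RPC+") {
  assert_that(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "feature ids (rownames) must be present and unique")
  assert_that(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "sample ids (colnames) must be present and unique")
  state <- match.arg(state, c("raw", "corrected", "transformed", "scaled"))
  if (state %in% c("raw", "corrected")) {
    assert_that(all(values >= 0, na.rm = TRUE),
                "raw/corrected intensities must be non-negative")
  }
  structure(list(values = values, state = state, platform = platform),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d features x %d samples, state = %s, platform = %s\n",
              nrow(x$values), ncol(x$values), x$state, x$platform))
  invisible(x)
}

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

# state-machine guard: only raw -> corrected -> transformed -> scaled
advance_state <- function(x, from, to) {
  assert_that(inherits(x, "intensity_matrix"), "expected an intensity_matrix")
  assert_that(identical(x$state, from),
              sprintf("matrix must be in state '%s' (is '%s')", from, x$state))
  x$state <- to
  x
}
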