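# small internal helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample standard deviation ignoring NAs, NA when fewer than 2 values
sd_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)

# derive a child RNG seed from a base seed, kept inside 32-bit integer range
child_seed <- function(seed, k) as.integer((as.numeric(seed) + 1000003 * k) %% .Machine$integer.max)
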