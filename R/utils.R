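#' Round half-up at a fixed number of decimals
#'
#' Reported tables round half away from zero (so 0.4185 prints as 0.419),
#' unlike [base::round()]'s round-half-even. Operates on the stored double,
#' so a value such as `(0.039 + 0.032)/2` (stored fractionally below 0.0355)
#' prints as 0.035.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a per-stage random seed from a root seed
#'
#' All stochastic stages draw their seed from one root seed plus a stage
#' label, so any stage can be re-run in isolation and reproduce its part of a
#' pipeline run. The derivation is a small deterministic string hash folded
#' into the root seed, kept below 2^31.
#'
#' @param root_seed integer root seed.
#' @param label character stage label, e.g. `"cohort/BALB/cA"`.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(root_seed, label) {
  stopifnot(length(root_seed) == 1, is.finite(root_seed))
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% m
  as.integer((as.numeric(root_seed) %% m * 48271 + h) %% m)
}

# run expr with a local RNG state seeded by `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# stop with the offending field name in the message
check_in_range <- function(value, lo, hi, field) {
  if (any(!is.finite(value)) || any(value < lo) || any(value > hi)) {
    stop(sprintf("field '%s' must be in [%s, %s]; got %s",
                 field, format(lo), format(hi),
                 paste(format(value), collapse = ", ")), call. = FALSE)
  }
  invisible(value)
}

check_positive <- function(value, field, strict = TRUE) {
  bad <- if (strict) any(!is.finite(value)) || any(value <= 0)
         else any(!is.finite(value)) || any(value < 0)
  if (bad) {
    stop(sprintf("field '%s' must be %s; got %s", field,
                 if (strict) "> 0" else ">= 0",
                 paste(format(value), collapse = ", ")), call. = FALSE)
  }
  invisible(value)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
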