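# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report tables in the zooarchaeological literature round 0.5 away from zero,
#' unlike [base::round()] which rounds half to even. A small relative epsilon
#' absorbs binary floating-point representation error (e.g. 0.15 stored as
#' 0.14999...).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate a function with a temporary RNG state; the caller's state is
# restored on exit so generators are pure functions of (args, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Unweighted k-point moving average, returned without the undefined ends
# (length n - k + 1).
moving_average <- function(x, k = 3) {
  n <- length(x)
  stopifnot(k >= 1, n >= k)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))[((k - 1) / 2 + 1):(n - (k - 1) / 2)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize unicode minus signs (U+2212) and non-breaking spaces that survive
# copy/paste from typeset tables, then coerce to numeric.
parse_numeric <- function(x, what = "value", row = NULL) {
  x <- gsub("−", "-", trimws(as.character(x)))
  x[x %in% c("", "-", "–", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric %s %s at row %s", what, dQuote(x[bad[1]]),
                 if (is.null(row)) bad[1] else row[bad[1]]), call. = FALSE)
  }
  out
}
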