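#' Round half up
#'
#' Deterministic half-up rounding, used for all reported percentages so that
#' e.g. 22.35 -> 22.4 regardless of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over Biostrings for character input.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stop() with a condition class so callers can catch specific failures
stopClassed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
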