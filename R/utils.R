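# Small shared helpers. Coordinates are 1-based inclusive everywhere inside
# the package; BED/bedGraph files are 0-based half-open at the I/O boundary.

#' Reverse complement of a DNA string
#'
#' Operates on plain upper-case character strings over {A,C,G,T,N}.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Derive a deterministic sub-seed for a named pipeline stage
#'
#' All randomness in the package flows from one top-level seed; each stage
#' draws from its own named substream so stages can be rerun in isolation.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
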