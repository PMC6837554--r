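#' Derive a deterministic 31-bit seed for a named random substream
#'
#' Polynomial string hash (base 31, modulus 2^31 - 1) of the top-level seed
#' concatenated with a substream key. Used so that each
#' (protein, comparison, replicate) cell of a simulated screen draws from its
#' own reproducible substream: adding proteins or comparisons to a design
#' never perturbs the draws of existing cells.
#'
#' @param seed integer top-level seed.
#' @param ... key components (coerced to character) identifying the substream.
#' @return an integer in [1, 2^31 - 2], usable with [set.seed()].
#' @keywords internal
#' @noRd
substream_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(key)) {
    # 31 * (m - 1) + code < 2^53, so double arithmetic is exact here
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

#' Geometric mean of a vector of positive ratios
#' @noRd
geom_mean <- function(x) exp(mean(log(x)))

#' Stop with a formatted message
#' @noRd
abort_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Assert strictly positive, finite ratios
#' @noRd
check_ratios <- function(ratio, what = "ratio") {
  bad <- !is.finite(ratio) | ratio <= 0
  if (any(bad)) {
    abort_fmt("%s values must be finite and > 0 (got e.g. %s)",
              what, format(ratio[bad][1]))
  }
  invisible(ratio)
}
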