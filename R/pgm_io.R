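#' Read and write plain-text PGM (P2) grayscale images
#'
#' All imaging operations in this package work on plain numeric matrices;
#' these helpers persist them as ASCII PGM (portable graymap, magic `P2`),
#' a standard plain-text raster format readable by ImageJ/Fiji and most
#' image tools. Intensities are written as 16-bit integers (maxval 65535),
#' rounded and clamped to `[0, maxval]`.
#'
#' @param image numeric matrix, rows = image rows (y).
#' @param path file path.
#' @param maxval maximum gray value declared in the header; default 65535.
#' @return `read_pgm()` returns a numeric matrix; `write_pgm()` returns
#'   `path` invisibly.
#' @name pgm_io
NULL

#' @rdname pgm_io
#' @export
write_pgm <- function(image, path, maxval = 65535L) {
  stopifnot(is.matrix(image))
  vals <- pmin(pmax(round(image), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  # one image row per line
  writeLines(apply(vals, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname pgm_io
#' @export
read_pgm <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!identical(trimws(lines[1]), "P2")) {
    abort_fmt("%s is not an ASCII PGM (P2) file", path)
  }
  tokens <- scan(text = paste(lines[-1], collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  w <- tokens[1]; h <- tokens[2]
  pix <- tokens[-(1:3)]
  if (length(pix) != w * h) {
    abort_fmt("PGM pixel count %d does not match %d x %d header",
              length(pix), w, h)
  }
  matrix(pix, nrow = h, ncol = w, byrow = TRUE)
}
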