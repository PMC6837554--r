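# md5 checksums of the packaged screen tables, recorded at transcription time
fixture_md5 <- c(
  table1.tsv = "4b44ee333a53f6a432f2c5a811071c3e",
  table2.tsv = "78397e877f69d486ee5d67e976e00a08",
  table2_flags_synthetic.tsv = "63b3f4ea80f3b595a6b1f5c00c8ac932"
)

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "pmscreen", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(fixture_md5[[file]]))) {
    abort_fmt("packaged fixture %s fails its checksum (%s)", file, md5)
  }
  path
}

#' Published tier-1 screen table: CHX effect on 33 PM proteins
#'
#' The 33 plasma-membrane proteins whose abundance changed upon a 90-minute
#' cycloheximide treatment of the wild type, with the WT+CHX / WT control
#' fold-change ratio (geometric mean over 6 biological replicates). All 33
#' printed ratios are significant at the published alpha of 0.05; rows are
#' ordered from the greatest decrease (Ptr2, 0.03) to the greatest increase
#' (Zeo1, 16.42). Values are verbatim from the published table; the packaged
#' file is checksum-verified on load.
#'
#' @return tibble with columns `accession` (UniProtKB), `name` (protein
#'   symbol) and `ratio_chx_vs_ctrl`.
#' @export
load_table1 <- function() {
  x <- readr::read_tsv(fixture_path("table1.tsv"),
                       col_types = readr::cols(
                         accession = readr::col_character(),
                         name = readr::col_character(),
                         ratio_chx_vs_ctrl = readr::col_double()
                       ))
  check_ratios(x$ratio_chx_vs_ctrl)
  x
}

#' Published tier-2 screen table: arrestin-deletion effect per protein
#'
#' For each of the 33 CHX-affected proteins, the artNd+CHX / WT+CHX
#' fold-change ratio in each of the 12 arrestin-knockout strains (geometric
#' mean over 3 biological replicates). Ratios are verbatim from the published
#' table.
#'
#' @return tibble with columns `accession`, `name` and one ratio column per
#'   arrestin (`art1` ... `art10`, `bul1`, `bul2`).
#' @export
load_table2 <- function() {
  readr::read_tsv(fixture_path("table2.tsv"),
                  col_types = readr::cols(
                    accession = readr::col_character(),
                    name = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Reconstructed per-cell significance flags for the tier-2 table
#'
#' The published table encodes significance as cell colour (red = ratio
#' significantly above 1, blue = below, white = not significant); colour is
#' formatting and does not survive text extraction, so the full flag matrix
#' cannot be recovered. This synthetic reconstruction records a flag only for
#' the cells whose colour is stated in the running text (e.g. Thi7 stabilized
#' in art2/art9, Ptr2 in bul1, Gas1 and Ras2 decreased in art9/bul2); every
#' other cell carries `flag = "none"` with `source = "unstated"` and must not
#' be read as evidence of non-significance.
#'
#' @return tibble in long form: `accession`, `name`, `arrestin`,
#'   `flag` (`up` / `down` / `none`), `source` (`prose` / `unstated`).
#' @export
load_table2_flags <- function() {
  readr::read_tsv(fixture_path("table2_flags_synthetic.tsv"),
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Count decreased and increased proteins in a tier-1 table
#'
#' @param table1 tibble as returned by [load_table1()].
#' @return named list: `n_decreased` (ratio < 1), `n_increased` (ratio > 1),
#'   `n_total`.
#' @export
summarize_counts <- function(table1 = load_table1()) {
  r <- table1$ratio_chx_vs_ctrl
  list(n_decreased = sum(r < 1), n_increased = sum(r > 1), n_total = length(r))
}

#' Look up a printed fold-change ratio
#'
#' @param table a tibble from [load_table1()] or [load_table2()].
#' @param protein protein symbol or UniProtKB accession (case-insensitive).
#' @param column for the tier-2 table, the arrestin column to read
#'   (e.g. `"art2"`); ignored for the tier-1 table.
#' @return the printed ratio (positive scalar).
#' @export
lookup_ratio <- function(table, protein, column = NULL) {
  keys <- toupper(c(table$name, table$accession))
  i <- match(toupper(protein), keys)
  if (is.na(i)) {
    abort_fmt("unknown protein '%s'; valid names: %s", protein,
              paste(table$name, collapse = ", "))
  }
  i <- ((i - 1L) %% nrow(table)) + 1L
  if ("ratio_chx_vs_ctrl" %in% names(table)) {
    return(table$ratio_chx_vs_ctrl[i])
  }
  valid <- setdiff(names(table), c("accession", "name"))
  column <- tolower(gsub("[^A-Za-z0-9]", "", column %||% ""))
  column <- sub("d$", "", column) # accept e.g. "art2d" for the art2 knockout
  if (!column %in% valid) {
    abort_fmt("unknown arrestin column '%s'; valid columns: %s", column,
              paste(valid, collapse = ", "))
  }
  table[[column]][i]
}

#' Export the packaged screen tables
#'
#' Copies the checksum-verified fixture TSVs into a directory, for use by
#' scripts and external tooling.
#'
#' @param outdir destination directory (created if absent).
#' @return character vector of the exported paths, invisibly.
#' @export
export_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- vapply(names(fixture_md5), function(f) {
    dest <- file.path(outdir, f)
    file.copy(fixture_path(f), dest, overwrite = TRUE)
    dest
  }, "")
  invisible(unname(out))
}
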