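#' Tier-1 screen: proteins affected by CHX in the wild type
#'
#' Selects the pooled results of the wild-type comparison (CHX-treated vs
#' mock-treated WT) and turns them into screen records ordered like the
#' published table: ascending fold change, greatest decrease first.
#'
#' @param pooled output of [pooled_results()] (or any tibble with
#'   `protein_id`, `test`, `reference`, `pooled_ratio`, `call`).
#' @param config a [stats_config()].
#' @param test,reference condition labels of the wild-type comparison.
#' @return tibble of screen records: `protein_id`, `tier1_ratio`,
#'   `tier1_call`, with a `counts` attribute giving the number of records per
#'   call.
#' @export
tier1_screen <- function(pooled, config = stats_config(),
                         test = "WT_CHX", reference = "WT_ctrl") {
  pooled <- tibble::as_tibble(pooled)
  wt <- pooled[pooled$test == test & pooled$reference == reference, ]
  if (nrow(wt) == 0) {
    abort_fmt("no pooled results for the wild-type comparison (%s vs %s)",
              test, reference)
  }
  records <- tibble::tibble(
    protein_id = wt$protein_id,
    tier1_ratio = wt$pooled_ratio,
    tier1_call = wt$call
  )
  records <- records[order(records$tier1_ratio), ]
  counts <- table(factor(records$tier1_call,
                         levels = c("DECREASED", "INCREASED", "UNCHANGED")))
  attr(records, "counts") <- as.list(counts)
  records
}

#' Tier-2 screen: per-arrestin dependence of each CHX-affected protein
#'
#' For every tier-1-affected protein (call not UNCHANGED) and every
#' arrestin-knockout comparison (artNd+CHX vs WT+CHX): `STABILIZED` when the
#' knockout comparison calls the protein INCREASED (more protein left at the
#' PM without the arrestin, read as an internalization defect), `DEPLETED`
#' when DECREASED, `UNAFFECTED` otherwise. A protein not quantified in a
#' knockout comparison is `UNAFFECTED` and flagged unquantified.
#'
#' @param records tier-1 screen records from [tier1_screen()].
#' @param pooled pooled results containing the arrestin-knockout comparisons
#'   (their `reference` must be the tier-1 test condition, e.g. `"WT_CHX"`).
#' @param config a [stats_config()].
#' @param reference reference condition identifying the knockout comparisons.
#' @return long tibble: `protein_id`, `arrestin` (test label with any
#'   `_CHX` suffix stripped), `ratio`, `dependence`, `quantified`.
#' @export
tier2_dependence <- function(records, pooled, config = stats_config(),
                             reference = "WT_CHX") {
  pooled <- tibble::as_tibble(pooled)
  art <- pooled[pooled$reference == reference, ]
  if (nrow(art) == 0) {
    abort_fmt("no arrestin-knockout comparisons (reference %s) in pooled results",
              reference)
  }
  affected <- records[records$tier1_call != "UNCHANGED", ]
  grid <- tidyr::crossing(
    protein_id = affected$protein_id,
    test = unique(art$test)
  )
  grid <- dplyr::left_join(grid, art[c("protein_id", "test", "pooled_ratio",
                                       "call")],
                           by = c("protein_id", "test"))
  tibble::tibble(
    protein_id = grid$protein_id,
    arrestin = sub("_CHX$", "", grid$test),
    ratio = grid$pooled_ratio,
    dependence = dplyr::case_when(
      is.na(grid$call) ~ "UNAFFECTED",
      grid$call == "INCREASED" ~ "STABILIZED",
      grid$call == "DECREASED" ~ "DEPLETED",
      .default = "UNAFFECTED"
    ),
    quantified = !is.na(grid$call)
  )
}

#' Map each arrestin to its candidate endocytic targets
#'
#' A candidate target of an arrestin is a protein that CHX depletes from the
#' PM in the wild type (tier-1 DECREASED) but that stays put when that
#' arrestin is deleted (tier-2 STABILIZED). A protein regulated
#' non-redundantly by several arrestins appears under each of them.
#'
#' @param records tier-1 records from [tier1_screen()].
#' @param dependence tier-2 table from [tier2_dependence()].
#' @return named list: arrestin label -> character vector of protein ids.
#' @export
build_target_map <- function(records, dependence) {
  decreased <- records$protein_id[records$tier1_call == "DECREASED"]
  hits <- dependence[dependence$dependence == "STABILIZED" &
                       dependence$protein_id %in% decreased, ]
  if (nrow(hits) == 0) return(stats::setNames(list(), character(0)))
  split(hits$protein_id, hits$arrestin)
}

#' Run the whole two-tier screen on a peptide-ratio dataset
#'
#' Deterministic composition: [read_dataset()] then [pooled_results()], the
#' tier-1 wild-type screen, tier-2 arrestin dependence and the target map.
#' Optionally writes `table1.tsv` (tier-1 records), `table2.tsv` (tier-2
#' long table) and `targets.tsv` into an output directory; ratios in these
#' files are rounded to 2 decimals as in the published tables, while the
#' returned tibbles keep full precision.
#'
#' @param path peptide-ratio dataset TSV (see [write_dataset()]).
#' @param config a [stats_config()].
#' @param outdir optional output directory.
#' @param test,reference labels of the wild-type comparison.
#' @return list with `pooled`, `records`, `dependence`, `target_map`.
#' @export
run_screen <- function(path, config = stats_config(), outdir = NULL,
                       test = "WT_CHX", reference = "WT_ctrl") {
  pooled <- pooled_results(read_dataset(path), config)
  records <- tier1_screen(pooled, config, test = test, reference = reference)
  dependence <- tier2_dependence(records, pooled, config, reference = test)
  target_map <- build_target_map(records, dependence)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    t1 <- dplyr::mutate(records, tier1_ratio = round(.data$tier1_ratio, 2))
    readr::write_tsv(t1, file.path(outdir, "table1.tsv"))
    t2 <- dplyr::mutate(dependence, ratio = round(.data$ratio, 2))
    readr::write_tsv(t2, file.path(outdir, "table2.tsv"))
    targets <- tibble::tibble(
      arrestin = names(target_map),
      proteins = vapply(target_map, paste, "", collapse = ",")
    )
    readr::write_tsv(targets, file.path(outdir, "targets.tsv"))
  }
  list(pooled = pooled, records = records, dependence = dependence,
       target_map = target_map)
}

#' Replay the published screen from the packaged tables
#'
#' Fixture mode for when no raw mass-spectrometry data are available: tier-1
#' calls come from the published tier-1 table (every printed row is
#' significant, so the call is the side of 1 its ratio falls on) and tier-2
#' calls from the reconstructed per-cell significance flags (`up` ->
#' STABILIZED, `down` -> DEPLETED, `none` -> UNAFFECTED). When a pipeline
#' run supplies computed significance, that run's calls take precedence over
#' these printed flags.
#'
#' @return list with `records`, `dependence`, `target_map` shaped like the
#'   corresponding elements of [run_screen()].
#' @export
screen_from_fixtures <- function() {
  t1 <- load_table1()
  records <- tibble::tibble(
    protein_id = t1$name,
    tier1_ratio = t1$ratio_chx_vs_ctrl,
    tier1_call = ifelse(t1$ratio_chx_vs_ctrl < 1, "DECREASED",
                        ifelse(t1$ratio_chx_vs_ctrl > 1, "INCREASED",
                               "UNCHANGED"))
  )
  counts <- table(factor(records$tier1_call,
                         levels = c("DECREASED", "INCREASED", "UNCHANGED")))
  attr(records, "counts") <- as.list(counts)
  t2 <- load_table2()
  flags <- load_table2_flags()
  ratios <- tidyr::pivot_longer(t2, -c("accession", "name"),
                                names_to = "arrestin", values_to = "ratio")
  dep <- dplyr::left_join(flags, ratios, by = c("accession", "name", "arrestin"))
  dependence <- tibble::tibble(
    protein_id = dep$name,
    arrestin = dep$arrestin,
    ratio = dep$ratio,
    dependence = dplyr::case_when(
      dep$flag == "up" ~ "STABILIZED",
      dep$flag == "down" ~ "DEPLETED",
      .default = "UNAFFECTED"
    ),
    quantified = TRUE
  )
  list(records = records, dependence = dependence,
       target_map = build_target_map(records, dependence))
}
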