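#' Construct a screen design
#'
#' A screen design states which condition comparisons are measured, with how
#' many biological replicates each, and which proteins are quantified with how
#' many peptides. It is the skeleton that the synthetic peptide-ratio
#' generator fills in.
#'
#' @param comparisons data frame with columns `test`, `reference` (condition
#'   labels) and `replicates` (positive integer count of biological
#'   replicates).
#' @param proteins data frame with columns `protein_id` and `n_peptides`
#'   (positive integer count of quantified peptides per protein).
#' @return an object of class `screen_design`: a list with tibbles
#'   `comparisons` and `proteins`.
#' @seealso [default_design()], [simulate_peptide_ratios()]
#' @export
screen_design <- function(comparisons, proteins) {
  comparisons <- tibble::as_tibble(comparisons)
  proteins <- tibble::as_tibble(proteins)
  stopifnot(all(c("test", "reference", "replicates") %in% names(comparisons)),
            all(c("protein_id", "n_peptides") %in% names(proteins)))
  if (any(comparisons$replicates < 1)) {
    abort_fmt("every comparison needs at least 1 replicate")
  }
  if (any(proteins$n_peptides < 1)) {
    abort_fmt("every protein needs at least 1 peptide")
  }
  key <- paste(comparisons$test, comparisons$reference)
  if (anyDuplicated(key)) abort_fmt("comparison labels must be unique")
  if (anyDuplicated(proteins$protein_id)) {
    abort_fmt("protein identifiers must be unique")
  }
  if (any(comparisons$test == comparisons$reference)) {
    abort_fmt("a comparison cannot test a condition against itself")
  }
  structure(list(comparisons = comparisons, proteins = proteins),
            class = "screen_design")
}

#' Arrestin deletion strains covered by the screen
#'
#' The twelve alpha-arrestin knockouts profiled against the CHX-treated
#' wild type: the arrestin-related trafficking adaptors Art1-10 and the
#' fungal Bul1/Bul2 variants (Bul3 was not screened).
#'
#' @return character vector of 12 arrestin labels.
#' @export
arrestin_labels <- function() c(paste0("art", 1:10), "bul1", "bul2")

# Fixed default peptide-count table. Spans 1..40 so that the peptide-count
# weighting of the z combination is exercised across its realistic range;
# assigned to the 33 screen proteins in a fixed order (no randomness).
default_peptide_counts <- function() {
  c(12L, 40L, 8L, 21L, 1L, 15L, 28L, 5L, 33L, 10L,
    18L, 2L, 25L, 7L, 36L, 14L, 4L, 22L, 30L, 6L,
    16L, 9L, 38L, 11L, 20L, 3L, 26L, 13L, 31L, 5L,
    17L, 24L, 40L)
}

#' Default screen design matching the published experiment
#'
#' One CHX-vs-mock wild-type comparison at 6 biological replicates, plus
#' twelve arrestin-knockout comparisons (artNd+CHX vs WT+CHX) at 3 biological
#' replicates each. The 33 proteins are the published CHX-affected PM
#' proteins; peptide counts come from a fixed documented table spanning 1-40.
#' Fully deterministic.
#'
#' @return a [screen_design()].
#' @export
default_design <- function() {
  arts <- arrestin_labels()
  comparisons <- tibble::tibble(
    test = c("WT_CHX", paste0(arts, "_CHX")),
    reference = c("WT_ctrl", rep("WT_CHX", length(arts))),
    replicates = c(6L, rep(3L, length(arts)))
  )
  proteins <- tibble::tibble(
    protein_id = load_table1()$name,
    n_peptides = default_peptide_counts()
  )
  screen_design(comparisons, proteins)
}

#' State the ground truth for a synthetic screen
#'
#' The generative model is multiplicative log-normal noise at the peptide
#' level around a protein-level true fold change, plus an additive
#' per-replicate offset on the log2 scale shared by all peptides of a
#' (protein, comparison, replicate) cell:
#' \deqn{log2(ratio_{p,c,r,j}) \sim N(log2(f_{p,c}) + \delta_{p,c,r},\;
#'   \sigma_{pep}^2), \quad \delta_{p,c,r} \sim N(0, \sigma_{rep}^2)}
#'
#' @param fold_change either a single positive number applied to every
#'   (protein, comparison) cell of `design`, or a data frame with columns
#'   `protein_id`, `test`, `reference`, `true_fold_change`.
#' @param design the [screen_design()] the truth must cover (required when
#'   `fold_change` is scalar).
#' @param peptide_noise_sd standard deviation of peptide-level log2 ratios
#'   around the replicate mean; default 0.5 log2 units.
#' @param replicate_effect_sd standard deviation of the per-replicate log2
#'   offset; default 0.2 log2 units.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(fold_change, design = NULL,
                         peptide_noise_sd = 0.5,
                         replicate_effect_sd = 0.2) {
  if (is.numeric(fold_change) && length(fold_change) == 1) {
    if (is.null(design)) {
      abort_fmt("a design is required when fold_change is a scalar")
    }
    fc <- fold_change
    fold_change <- tidyr::crossing(
      design$comparisons[c("test", "reference")],
      protein_id = design$proteins$protein_id
    )
    fold_change$true_fold_change <- fc
  }
  fold_change <- tibble::as_tibble(fold_change)
  stopifnot(all(c("protein_id", "test", "reference", "true_fold_change")
                %in% names(fold_change)))
  check_ratios(fold_change$true_fold_change, "true_fold_change")
  if (peptide_noise_sd <= 0) abort_fmt("peptide_noise_sd must be > 0")
  if (replicate_effect_sd < 0) abort_fmt("replicate_effect_sd must be >= 0")
  structure(list(fold_change = fold_change,
                 peptide_noise_sd = peptide_noise_sd,
                 replicate_effect_sd = replicate_effect_sd),
            class = "ground_truth")
}

#' Overwrite the true fold change of selected (protein, comparison) cells
#'
#' Convenience for planting known effects into an otherwise null truth, e.g.
#' a protein endocytosed in the wild type (fold 0.2 in WT+CHX vs control) but
#' stabilized in one knockout (fold 5 in that artNd+CHX vs WT+CHX).
#'
#' @param truth a [ground_truth()].
#' @param protein_id,test protein and test-condition labels selecting cells.
#' @param fold_change positive replacement value.
#' @return the modified `ground_truth`.
#' @export
plant_fold_change <- function(truth, protein_id, test, fold_change) {
  stopifnot(inherits(truth, "ground_truth"))
  check_ratios(fold_change, "fold_change")
  hit <- truth$fold_change$protein_id %in% protein_id &
    truth$fold_change$test %in% test
  if (!any(hit)) abort_fmt("no (protein, comparison) cell matches")
  truth$fold_change$true_fold_change[hit] <- fold_change
  truth
}

#' Simulate peptide-level abundance ratios for a designed screen
#'
#' Stand-in for the isobaric-label (iTRAQ) experiment: for every
#' (protein, comparison, replicate) cell a replicate offset is drawn, then
#' each peptide log2 ratio around `log2(true_fold_change) + offset` with the
#' stated peptide-level noise. Each cell draws from its own seed-derived
#' substream, so the same (design, truth, seed) triple is bit-reproducible
#' and extending the design leaves existing cells untouched.
#'
#' @param design a [screen_design()].
#' @param truth a [ground_truth()] covering every (protein, comparison) cell
#'   of the design.
#' @param seed integer seed for the whole dataset.
#' @return tibble with columns `protein_id`, `test`, `reference`,
#'   `replicate`, `peptide`, `ratio` (natural-scale, positive).
#' @export
simulate_peptide_ratios <- function(design, truth, seed) {
  stopifnot(inherits(design, "screen_design"), inherits(truth, "ground_truth"))
  cells <- tidyr::crossing(design$comparisons, design$proteins)
  cells <- dplyr::left_join(
    cells, truth$fold_change,
    by = c("protein_id", "test", "reference")
  )
  if (anyNA(cells$true_fold_change)) {
    miss <- cells[is.na(cells$true_fold_change), ][1, ]
    abort_fmt("ground truth missing for protein '%s' in comparison (%s vs %s)",
              miss$protein_id, miss$test, miss$reference)
  }
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    reps <- vector("list", cell$replicates)
    for (r in seq_len(cell$replicates)) {
      set.seed(substream_seed(seed, cell$protein_id, cell$test,
                              cell$reference, r))
      offset <- rnorm(1, 0, truth$replicate_effect_sd)
      log2r <- rnorm(cell$n_peptides,
                     log2(cell$true_fold_change) + offset,
                     truth$peptide_noise_sd)
      reps[[r]] <- tibble::tibble(
        protein_id = cell$protein_id,
        test = cell$test,
        reference = cell$reference,
        replicate = r,
        peptide = seq_len(cell$n_peptides),
        ratio = 2^log2r
      )
    }
    out[[i]] <- dplyr::bind_rows(reps)
  }
  dplyr::bind_rows(out)
}

#' Write a peptide-ratio dataset to tab-separated text
#'
#' Schema: `protein_id`, `test`, `reference`, `replicate`, `peptide`,
#' `ratio`; UTF-8, header row. Round-trips losslessly through
#' [read_dataset()].
#'
#' @param peptide_ratios tibble as produced by [simulate_peptide_ratios()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(peptide_ratios, path) {
  peptide_ratios <- tibble::as_tibble(peptide_ratios)
  cols <- c("protein_id", "test", "reference", "replicate", "peptide", "ratio")
  if (!all(cols %in% names(peptide_ratios))) {
    abort_fmt("dataset must have columns: %s", paste(cols, collapse = ", "))
  }
  if (nrow(peptide_ratios) == 0) {
    abort_fmt("refusing to write an empty peptide-ratio dataset")
  }
  check_ratios(peptide_ratios$ratio)
  readr::write_tsv(peptide_ratios[cols], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
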