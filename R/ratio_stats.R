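#' Configuration of the screen statistics
#'
#' @param alpha family-wise significance level applied to Bonferroni-adjusted
#'   pooled p-values; default 0.05.
#' @param min_peptides minimum peptide evidence for a per-replicate p-value
#'   (emulates the identification stringency of the upstream search engine);
#'   default 2. Replicates below it contribute to the pooled ratio but not to
#'   the combined z.
#' @param min_replicates minimum number of p-value-carrying replicates for a
#'   protein to be tested at all; default 2. Proteins below it are reported
#'   with a pooled ratio only.
#' @param family_size Bonferroni family: `"per_comparison"` (the number of
#'   proteins tested within one comparison, i.e. one published table column is
#'   one family) or an explicit positive integer.
#' @param z_combination how per-replicate z-scores are combined:
#'   `"stouffer"` (default) is the weighted Stouffer-Liptak statistic
#'   `sum(w*z)/sqrt(sum(w^2))`, which stays standard normal under the null;
#'   `"mean"` is the plain weighted mean `sum(w*z)/sum(w)`, provided for
#'   comparison only (it is not a valid z-score and is not recommended).
#' @return a list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, min_peptides = 2L, min_replicates = 2L,
                         family_size = "per_comparison",
                         z_combination = c("stouffer", "mean")) {
  z_combination <- match.arg(z_combination)
  stopifnot(alpha > 0, alpha < 1, min_peptides >= 1, min_replicates >= 1)
  if (!identical(family_size, "per_comparison")) {
    stopifnot(is.numeric(family_size), length(family_size) == 1,
              family_size >= 1)
  }
  structure(list(alpha = alpha,
                 min_peptides = as.integer(min_peptides),
                 min_replicates = as.integer(min_replicates),
                 family_size = family_size,
                 z_combination = z_combination),
            class = "stats_config")
}

#' Read a peptide-ratio dataset written by [write_dataset()]
#'
#' @param path TSV file with header `protein_id`, `test`, `reference`,
#'   `replicate`, `peptide`, `ratio`.
#' @return tibble of peptide ratios, validated positive and finite.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort_fmt("no such dataset file: %s", path)
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  cols <- c("protein_id", "test", "reference", "replicate", "peptide", "ratio")
  missing <- setdiff(cols, header)
  if (length(missing)) {
    abort_fmt("dataset is missing column(s): %s", paste(missing, collapse = ", "))
  }
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      test = readr::col_character(),
      reference = readr::col_character(),
      replicate = readr::col_integer(),
      peptide = readr::col_integer(),
      ratio = readr::col_double()
    )
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    # readr reports file rows (header included), so this is already the line
    abort_fmt("malformed dataset row at line %d (expected %s)",
              probs$row[1], probs$expected[1])
  }
  if (anyNA(x[cols])) {
    bad <- which(rowSums(is.na(x[cols])) > 0)[1]
    abort_fmt("malformed dataset row at line %d (missing value)", bad + 1L)
  }
  if (any(x$ratio <= 0 | !is.finite(x$ratio))) {
    bad <- which(x$ratio <= 0 | !is.finite(x$ratio))[1]
    abort_fmt("non-positive ratio at line %d", bad + 1L)
  }
  x[cols]
}

#' Per-replicate protein ratio and p-value from peptide ratios
#'
#' The protein ratio within one biological replicate is the geometric mean of
#' its peptide ratios. The per-replicate p-value is a two-sided one-sample
#' t-test of the log2 peptide ratios against 0, computed only when the
#' replicate carries at least `min_peptides` peptides. When all log2 ratios
#' are exactly 0 the p-value is 1; when they are constant but non-zero the
#' t statistic degenerates and the p-value is clamped to the smallest
#' positive double.
#'
#' @param ratios numeric vector of positive peptide ratios for one
#'   (protein, comparison, replicate) cell.
#' @param config a [stats_config()].
#' @return one-row tibble: `ratio`, `n_peptides`, `p_value` (`NA` when the
#'   peptide evidence is below `min_peptides`).
#' @export
replicate_protein_ratio <- function(ratios, config = stats_config()) {
  if (length(ratios) == 0) abort_fmt("no peptide ratios supplied")
  check_ratios(ratios, "peptide ratio")
  l2 <- log2(ratios)
  n <- length(ratios)
  p <- NA_real_
  if (n >= config$min_peptides) {
    if (sd(l2) == 0) {
      p <- if (l2[1] == 0) 1 else .Machine$double.xmin
    } else {
      p <- t.test(l2, mu = 0)$p.value
    }
  }
  tibble::tibble(ratio = geom_mean(ratios), n_peptides = n, p_value = p)
}

#' Pool per-replicate results for one protein and comparison
#'
#' The cross-replicate ratio is the logarithmic (geometric) mean of the
#' per-replicate ratios. Each replicate's two-sided p-value is converted to a
#' signed z-score, `z = sign(log ratio) * qnorm(1 - p/2)`, and the z-scores
#' are combined with peptide counts as weights (see [stats_config()]); the
#' combined z is converted back to a two-sided normal p-value. Proteins with
#' fewer than `min_replicates` usable replicates are flagged untested and
#' keep only the pooled ratio.
#'
#' @param rep_results tibble of per-replicate rows (`ratio`, `n_peptides`,
#'   `p_value`) for one (protein, comparison).
#' @param config a [stats_config()].
#' @return one-row tibble: `pooled_ratio`, `combined_z`, `pooled_p`,
#'   `n_replicates`, `tested`.
#' @export
pool_replicates <- function(rep_results, config = stats_config()) {
  rep_results <- tibble::as_tibble(rep_results)
  if (nrow(rep_results) == 0) abort_fmt("no replicate results supplied")
  check_ratios(rep_results$ratio)
  pooled_ratio <- geom_mean(rep_results$ratio)
  usable <- rep_results[!is.na(rep_results$p_value), ]
  if (nrow(usable) < config$min_replicates) {
    return(tibble::tibble(pooled_ratio = pooled_ratio,
                          combined_z = NA_real_, pooled_p = NA_real_,
                          n_replicates = nrow(rep_results), tested = FALSE))
  }
  z <- sign(log(usable$ratio)) * qnorm(usable$p_value / 2, lower.tail = FALSE)
  w <- usable$n_peptides
  combined_z <- switch(config$z_combination,
    stouffer = sum(w * z) / sqrt(sum(w^2)),
    mean = sum(w * z) / sum(w)
  )
  pooled_p <- 2 * pnorm(abs(combined_z), lower.tail = FALSE)
  pooled_p <- max(pooled_p, .Machine$double.xmin) # keep in (0, 1]
  tibble::tibble(pooled_ratio = pooled_ratio, combined_z = combined_z,
                 pooled_p = pooled_p, n_replicates = nrow(rep_results),
                 tested = TRUE)
}

#' Bonferroni-adjust pooled p-values within each comparison
#'
#' `adjusted_p = min(1, m * pooled_p)` where the family size `m` defaults to
#' the number of proteins actually tested within the same comparison (each
#' published table column is its own family); an explicit integer family can
#' be set in the config.
#'
#' @param pooled tibble of pooled results carrying `test`, `reference`,
#'   `pooled_p` and `tested` columns (see [pooled_results()]).
#' @param config a [stats_config()].
#' @return `pooled` with an `adjusted_p` column (`NA` for untested rows).
#' @export
bonferroni_adjust <- function(pooled, config = stats_config()) {
  pooled <- tibble::as_tibble(pooled)
  if (!"tested" %in% names(pooled)) pooled$tested <- !is.na(pooled$pooled_p)
  pooled |>
    dplyr::group_by(.data$test, .data$reference) |>
    dplyr::mutate(
      adjusted_p = {
        m <- if (identical(config$family_size, "per_comparison")) {
          sum(.data$tested)
        } else {
          as.integer(config$family_size)
        }
        ifelse(.data$tested, pmin(1, m * .data$pooled_p), NA_real_)
      }
    ) |>
    dplyr::ungroup()
}

#' Call the direction of change of each pooled result
#'
#' `DECREASED` when the adjusted p-value is below alpha and the pooled ratio
#' is below 1; `INCREASED` when above 1; `UNCHANGED` otherwise. A pooled
#' ratio exactly equal to 1 has no direction and is `UNCHANGED` regardless of
#' significance; untested proteins are `UNCHANGED`.
#'
#' @param pooled tibble carrying `pooled_ratio` and `adjusted_p`.
#' @param config a [stats_config()].
#' @return `pooled` with a `call` column.
#' @export
classify_change <- function(pooled, config = stats_config()) {
  pooled <- tibble::as_tibble(pooled)
  sig <- !is.na(pooled$adjusted_p) & pooled$adjusted_p < config$alpha
  pooled$call <- dplyr::case_when(
    sig & pooled$pooled_ratio < 1 ~ "DECREASED",
    sig & pooled$pooled_ratio > 1 ~ "INCREASED",
    .default = "UNCHANGED"
  )
  pooled
}

#' Full peptide-to-protein statistical pipeline
#'
#' Runs, per (protein, comparison): geometric-mean per-replicate ratios with
#' t-test p-values, logarithmic-mean pooling with peptide-count-weighted
#' z-score combination, per-comparison Bonferroni correction, and direction
#' calls.
#'
#' @param peptide_ratios tibble as produced by [simulate_peptide_ratios()] or
#'   [read_dataset()].
#' @param config a [stats_config()].
#' @return tibble with one row per (protein, comparison): `protein_id`,
#'   `test`, `reference`, `pooled_ratio`, `combined_z`, `pooled_p`,
#'   `adjusted_p`, `call`, `n_replicates`, `tested`.
#' @export
pooled_results <- function(peptide_ratios, config = stats_config()) {
  peptide_ratios <- tibble::as_tibble(peptide_ratios)
  reps <- peptide_ratios |>
    dplyr::group_by(.data$protein_id, .data$test, .data$reference,
                    .data$replicate) |>
    dplyr::reframe(replicate_protein_ratio(.data$ratio, config))
  pooled <- reps |>
    dplyr::group_by(.data$protein_id, .data$test, .data$reference) |>
    dplyr::reframe(pool_replicates(
      dplyr::pick(dplyr::everything()), config
    ))
  pooled |>
    bonferroni_adjust(config) |>
    classify_change(config)
}

#' Write pooled results to tab-separated text
#'
#' Full numeric precision is retained; the published tables round ratios to
#' two decimals for display only.
#'
#' @param pooled output of [pooled_results()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(pooled, path) {
  cols <- c("protein_id", "test", "reference", "pooled_ratio", "combined_z",
            "pooled_p", "adjusted_p", "call", "n_replicates")
  readr::write_tsv(tibble::as_tibble(pooled)[cols], path)
  invisible(path)
}
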