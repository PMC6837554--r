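#' Construct a concentric ellipse pair delimiting one cell
#'
#' Mirrors the manual quantification convention: an outer ellipse drawn
#' around the whole cell and an inner ellipse delimiting the inside while
#' excluding the plasma membrane, so that the annulus between them is the PM
#' region.
#'
#' @param cell_id cell identifier.
#' @param outer,inner numeric vectors `c(cx, cy, a, b, theta)`: center in
#'   pixels (0-based grid), semi-axes in pixels, rotation in radians.
#' @param condition,time optional labels carried through to measurements.
#' @return one-row tibble with columns `cell_id`, `condition`, `time`,
#'   `outer_cx` ... `inner_theta`.
#' @export
ellipse_pair <- function(cell_id, outer, inner, condition = NA_character_,
                         time = NA_real_) {
  stopifnot(length(outer) == 5, length(inner) == 5)
  if (any(outer[3:4] <= 0) || any(inner[3:4] <= 0)) {
    abort_fmt("ellipse semi-axes must be > 0")
  }
  # inner must sit strictly inside outer: check a dense sample of its boundary
  phi <- seq(0, 2 * pi, length.out = 128)
  bx <- inner[1] + inner[3] * cos(phi) * cos(inner[5]) -
    inner[4] * sin(phi) * sin(inner[5])
  by <- inner[2] + inner[3] * cos(phi) * sin(inner[5]) +
    inner[4] * sin(phi) * cos(inner[5])
  if (any(ellipse_q(bx, by, outer) >= 1)) {
    abort_fmt("inner ellipse of cell '%s' is not strictly contained in outer",
              cell_id)
  }
  tibble::tibble(cell_id = as.character(cell_id), condition = condition,
                 time = time,
                 outer_cx = outer[1], outer_cy = outer[2], outer_a = outer[3],
                 outer_b = outer[4], outer_theta = outer[5],
                 inner_cx = inner[1], inner_cy = inner[2], inner_a = inner[3],
                 inner_b = inner[4], inner_theta = inner[5])
}

# quadratic form of the ellipse inequality; < 1 means inside
ellipse_q <- function(x, y, e) {
  dx <- x - e[1]; dy <- y - e[2]
  u <- dx * cos(e[5]) + dy * sin(e[5])
  v <- -dx * sin(e[5]) + dy * cos(e[5])
  (u / e[3])^2 + (v / e[4])^2
}

ellipse_vec <- function(pair, which) {
  as.numeric(pair[1, paste0(which, c("_cx", "_cy", "_a", "_b", "_theta"))])
}

# logical masks over the pixel grid; pixel centers at 0-based integer coords
pair_masks <- function(dim_img, pair) {
  x <- matrix(rep(0:(dim_img[2] - 1), each = dim_img[1]), nrow = dim_img[1])
  y <- matrix(rep(0:(dim_img[1] - 1), times = dim_img[2]), nrow = dim_img[1])
  outer <- ellipse_q(x, y, ellipse_vec(pair, "outer")) < 1
  inner <- ellipse_q(x, y, ellipse_vec(pair, "inner")) < 1
  list(inner = inner, annulus = outer & !inner)
}

#' Render a synthetic field of cells with known intensity ratios
#'
#' Each cell is painted as a bright ring (the PM) at `ring_level` over the
#' annulus between its two ellipses and a flat interior at `interior_level`,
#' on a uniform background; optional Gaussian pixel noise on top. The ground
#' truth internal-over-PM ratio of a cell is `interior_level / ring_level`.
#'
#' @param cells tibble with the [ellipse_pair()] columns plus
#'   `interior_level` and `ring_level` per cell.
#' @param width,height image size in pixels.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensity units); 0 for a noiseless field.
#' @param background background intensity; must satisfy
#'   `0 <= background < levels`.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return list: `image` (numeric matrix, rows = y), `truth` (tibble
#'   `cell_id`, `true_ratio`).
#' @export
synthesize_field <- function(cells, width, height, noise_sd = 0,
                             background = 0, seed = 1) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("interior_level", "ring_level") %in% names(cells)))
  if (background < 0 || any(cells$interior_level <= background) ||
      any(cells$ring_level <= background)) {
    abort_fmt("cell levels must exceed the background, and background >= 0")
  }
  img <- matrix(background, nrow = height, ncol = width)
  painted <- matrix(FALSE, nrow = height, ncol = width)
  for (i in seq_len(nrow(cells))) {
    m <- pair_masks(dim(img), cells[i, ])
    footprint <- m$inner | m$annulus
    if (any(painted & footprint)) {
      abort_fmt("cell '%s' overlaps a previously placed cell",
                cells$cell_id[i])
    }
    img[m$annulus] <- cells$ring_level[i]
    img[m$inner] <- cells$interior_level[i]
    painted <- painted | footprint
  }
  if (noise_sd > 0) {
    set.seed(substream_seed(seed, "field_noise"))
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = height)
  }
  truth <- tibble::tibble(cell_id = cells$cell_id,
                          true_ratio = cells$interior_level / cells$ring_level)
  list(image = img, truth = truth)
}

#' Measure one cell's internal-over-PM intensity ratio
#'
#' Pixel membership is decided by a pixel-center test against the ellipse
#' inequality on the 0-based integer grid. Internal intensity is the mean
#' over the inner ellipse; PM intensity the mean over the annulus between
#' the ellipses.
#'
#' @param image numeric matrix (rows = y, 0-based pixel centers).
#' @param pair one-row tibble from [ellipse_pair()].
#' @return one-row tibble: `cell_id`, `condition`, `time`,
#'   `internal_intensity`, `pm_intensity`, `ratio`.
#' @export
measure_cell <- function(image, pair) {
  m <- pair_masks(dim(image), pair)
  if (!any(m$annulus)) {
    abort_fmt("cell '%s': the annulus between the ellipses contains no pixel",
              pair$cell_id)
  }
  if (!any(m$inner)) {
    abort_fmt("cell '%s': the inner ellipse contains no pixel", pair$cell_id)
  }
  internal <- mean(image[m$inner])
  pm <- mean(image[m$annulus])
  if (pm <= 0) abort_fmt("cell '%s': PM intensity is not positive", pair$cell_id)
  tibble::tibble(cell_id = pair$cell_id, condition = pair$condition,
                 time = pair$time, internal_intensity = internal,
                 pm_intensity = pm, ratio = internal / pm)
}

#' Measure every cell of a region-of-interest table
#'
#' @param image numeric matrix.
#' @param rois tibble of [ellipse_pair()] rows.
#' @return tibble of per-cell measurements (one row per ROI).
#' @export
measure_cells <- function(image, rois) {
  rois <- tibble::as_tibble(rois)
  dplyr::bind_rows(lapply(seq_len(nrow(rois)), function(i) {
    measure_cell(image, rois[i, ])
  }))
}

#' Detect cells in an image and fit ellipse pairs to them
#'
#' Convenience stand-in for manual ellipse drawing: thresholds the image at
#' an intensity quantile, labels connected components (8-connectivity), and
#' fits each component's outer ellipse from its second-order moments (for a
#' filled ellipse the moment eigenvalues equal a^2/4 and b^2/4). The inner
#' ellipse is the outer one with both semi-axes shrunk by a PM-thickness
#' margin. Deterministic.
#'
#' @param image numeric matrix; must not be constant.
#' @param threshold_quantile intensity quantile separating cells from
#'   background.
#' @param pm_margin PM thickness in pixels subtracted from the fitted
#'   semi-axes to form the inner ellipse.
#' @param min_area minimum component area in pixels.
#' @return tibble of [ellipse_pair()] rows (possibly empty).
#' @export
detect_cells <- function(image, threshold_quantile = 0.8, pm_margin = 2,
                         min_area = 25) {
  if (diff(range(image)) == 0) abort_fmt("cannot detect cells in a constant image")
  bw <- image > quantile(image, threshold_quantile)
  labels <- label_components(bw)
  ids <- setdiff(unique(as.vector(labels)), 0L)
  out <- list()
  for (k in ids) {
    idx <- which(labels == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    x <- idx[, "col"] - 1; y <- idx[, "row"] - 1
    cx <- mean(x); cy <- mean(y)
    cov <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x)
    eig <- eigen(cov, symmetric = TRUE)
    a <- 2 * sqrt(max(eig$values[1], 1e-9))
    b <- 2 * sqrt(max(eig$values[2], 1e-9))
    theta <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
    inner_a <- max(a - pm_margin, a * 0.2)
    inner_b <- max(b - pm_margin, b * 0.2)
    out[[length(out) + 1]] <- ellipse_pair(
      cell_id = sprintf("cell_%03d", length(out) + 1L),
      outer = c(cx, cy, a, b, theta),
      inner = c(cx, cy, inner_a, inner_b, theta)
    )
  }
  if (length(out) == 0) {
    return(ellipse_pair("none", c(0, 0, 1, 1, 0), c(0, 0, .5, .5, 0))[0, ])
  }
  dplyr::bind_rows(out)
}

# connected-component labelling of a logical matrix, 8-connectivity,
# iterative flood fill (no recursion; images here are small)
label_components <- function(bw) {
  labels <- matrix(0L, nrow = nrow(bw), ncol = ncol(bw))
  nr <- nrow(bw); nc <- ncol(bw)
  current <- 0L
  for (start in which(bw)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          q <- (c2 - 1L) * nr + r2
          if (bw[q] && labels[q] == 0L) {
            labels[q] <- current
            stack <- c(stack, q)
          }
        }
      }
    }
  }
  labels
}

#' Summarize one condition by its median ratio with a bootstrap 95% CI
#'
#' The confidence interval is the percentile bootstrap of the median
#' (`n_bootstrap` resamples, seeded), since no analytic CI is assumed for
#' the per-cell ratio distribution.
#'
#' @param measurements tibble with a `ratio` column (one condition's cells).
#' @param n_bootstrap number of bootstrap resamples; default 2000.
#' @param seed integer seed.
#' @return one-row tibble: `n_cells`, `median_ratio`, `ci_low`, `ci_high`.
#' @export
summarize_condition <- function(measurements, n_bootstrap = 2000, seed = 1) {
  r <- tibble::as_tibble(measurements)$ratio
  if (length(r) == 0) abort_fmt("cannot summarize a condition with no cells")
  set.seed(substream_seed(seed, "bootstrap_median", length(r)))
  boots <- replicate(n_bootstrap, median(sample(r, replace = TRUE)))
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  tibble::tibble(n_cells = length(r), median_ratio = median(r),
                 ci_low = ci[1], ci_high = ci[2])
}

#' Normalize ratios to each variant's time-0 baseline
#'
#' Divides every cell's ratio by the median ratio of the same condition
#' (variant) at the baseline time point, so time courses of different
#' mutants start at 1 and become comparable.
#'
#' @param measurements tibble with `condition`, `time` and `ratio` columns.
#' @param baseline_time the time label of the baseline group; default 0.
#' @return `measurements` with `ratio` replaced by the normalized ratio and
#'   the raw value kept in `raw_ratio`.
#' @export
normalize_to_baseline <- function(measurements, baseline_time = 0) {
  m <- tibble::as_tibble(measurements)
  baselines <- m |>
    dplyr::filter(.data$time == baseline_time) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(baseline = median(.data$ratio), .groups = "drop")
  missing <- setdiff(unique(m$condition), baselines$condition)
  if (length(missing)) {
    abort_fmt("no time-%s baseline group for variant(s): %s",
              format(baseline_time), paste(missing, collapse = ", "))
  }
  m |>
    dplyr::left_join(baselines, by = "condition") |>
    dplyr::mutate(raw_ratio = .data$ratio,
                  ratio = .data$ratio / .data$baseline) |>
    dplyr::select(-"baseline")
}

#' Pairwise Wilcoxon comparisons of conditions, Holm-adjusted
#'
#' Two-sided Wilcoxon rank-sum test for every requested pair of condition
#' groups: exact enumeration when both groups have at most 10 observations
#' and the pooled data carry no ties, normal approximation with tie and
#' continuity correction otherwise. The Holm step-down adjustment is applied
#' over the requested family of pairs.
#'
#' @param measurements tibble with `condition` and `ratio` columns.
#' @param pairs optional 2-column character matrix (or list of length-2
#'   vectors) of condition pairs; defaults to all pairwise combinations.
#' @return tibble: `group1`, `group2`, `n1`, `n2`, `p_value`, `p_holm`,
#'   `exact`.
#' @export
compare_conditions <- function(measurements, pairs = NULL) {
  m <- tibble::as_tibble(measurements)
  groups <- split(m$ratio, m$condition)
  if (length(groups) < 2) abort_fmt("need at least two condition groups")
  if (any(lengths(groups) == 0)) abort_fmt("a condition group is empty")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(groups), 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs[i, 1]; g2 <- pairs[i, 2]
    if (!g1 %in% names(groups) || !g2 %in% names(groups)) {
      abort_fmt("unknown condition in pair (%s, %s)", g1, g2)
    }
    x <- groups[[g1]]; y <- groups[[g2]]
    use_exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    w <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = !use_exact)
    )
    tibble::tibble(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
                   p_value = w$p.value, exact = use_exact)
  })
  res <- dplyr::bind_rows(res)
  res$p_holm <- p.adjust(res$p_value, method = "holm")
  res[c("group1", "group2", "n1", "n2", "p_value", "p_holm", "exact")]
}
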