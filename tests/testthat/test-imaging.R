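# one well-separated cell per grid slot; returns rois + field
make_grid_field <- function(n_cells, interior, ring, noise_sd = 0, seed = 1,
                            cell_px = 36) {
  per_row <- ceiling(sqrt(n_cells))
  rois <- dplyr::bind_rows(lapply(seq_len(n_cells) - 1L, function(i) {
    cx <- (i %% per_row) * cell_px + cell_px / 2
    cy <- (i %/% per_row) * cell_px + cell_px / 2
    ellipse_pair(sprintf("c%02d", i + 1), outer = c(cx, cy, 13, 10, 0.4),
                 inner = c(cx, cy, 9, 6.5, 0.4), condition = "cond", time = 0)
  }))
  cells <- cbind(rois, interior_level = interior, ring_level = ring)
  field <- synthesize_field(cells, width = per_row * cell_px,
                            height = ceiling(n_cells / per_row) * cell_px,
                            noise_sd = noise_sd, seed = seed)
  list(rois = rois, field = field)
}

test_that("ellipse pairs enforce containment and positive axes", {
  expect_error(ellipse_pair("x", c(10, 10, 5, 5, 0), c(10, 10, 5, 5, 0)),
               "contained")
  expect_error(ellipse_pair("x", c(10, 10, 5, 5, 0), c(13, 10, 3, 3, 0)),
               "contained")
  expect_error(ellipse_pair("x", c(10, 10, -5, 5, 0), c(10, 10, 3, 3, 0)),
               "semi-axes")
  expect_silent(ellipse_pair("x", c(10, 10, 5, 5, 0), c(10, 10, 3, 3, 0)))
})

test_that("noiseless synthetic cells measure their constructed ratio exactly", {
  g <- make_grid_field(1, interior = 100, ring = 100)
  expect_equal(measure_cell(g$field$image, g$rois[1, ])$ratio, 1.0)
  g <- make_grid_field(1, interior = 200, ring = 100)
  m <- measure_cell(g$field$image, g$rois[1, ])
  expect_equal(m$ratio, 2.0)
  expect_equal(m$internal_intensity, 200)
  expect_equal(m$pm_intensity, 100)
  # constant image: ratio 1 for any valid pair
  const <- matrix(37, 40, 40)
  p <- ellipse_pair("c", c(20, 20, 12, 9, 1.1), c(20, 20, 7, 5, 1.1))
  expect_equal(measure_cell(const, p)$ratio, 1.0)
})

test_that("ratio is invariant under gain but not under offset", {
  g <- make_grid_field(1, interior = 180, ring = 90, noise_sd = 4, seed = 3)
  base <- measure_cell(g$field$image, g$rois[1, ])$ratio
  for (gain in c(0.25, 3, 1000)) {
    expect_equal(measure_cell(gain * g$field$image, g$rois[1, ])$ratio, base,
                 tolerance = 1e-12)
  }
  # additive offset is a documented sensitivity, not an invariant
  shifted <- measure_cell(g$field$image + 50, g$rois[1, ])$ratio
  expect_false(isTRUE(all.equal(shifted, base, tolerance = 1e-6)))
  expect_lt(abs(shifted - 1), abs(base - 1)) # offsets pull the ratio toward 1
})

test_that("field synthesis is seeded-deterministic and rejects overlap", {
  g1 <- make_grid_field(2, 200, 100, noise_sd = 10, seed = 42)
  g2 <- make_grid_field(2, 200, 100, noise_sd = 10, seed = 42)
  expect_identical(g1$field$image, g2$field$image)
  g3 <- make_grid_field(2, 200, 100, noise_sd = 10, seed = 43)
  expect_false(identical(g1$field$image, g3$field$image))
  overlapping <- dplyr::bind_rows(
    ellipse_pair("a", c(20, 20, 12, 10, 0), c(20, 20, 8, 6, 0)),
    ellipse_pair("b", c(30, 20, 12, 10, 0), c(30, 20, 8, 6, 0))
  )
  expect_error(
    synthesize_field(cbind(overlapping, interior_level = 200, ring_level = 100),
                     width = 60, height = 40),
    "overlap")
  expect_error(
    synthesize_field(cbind(make_grid_field(1, 200, 100)$rois,
                           interior_level = 50, ring_level = 100),
                     width = 36, height = 36, background = 60),
    "background")
})

test_that("cell detection recovers synthetic geometry", {
  g <- make_grid_field(1, interior = 200, ring = 100)
  det <- detect_cells(g$field$image, threshold_quantile = 0.5, pm_margin = 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$outer_cx - g$rois$outer_cx), 1)
  expect_lt(abs(det$outer_cy - g$rois$outer_cy), 1)
  g2 <- make_grid_field(2, interior = 200, ring = 100)
  det2 <- detect_cells(g2$field$image, threshold_quantile = 0.5, pm_margin = 3)
  expect_equal(nrow(det2), 2)
  blank <- matrix(0, 30, 30)
  expect_error(detect_cells(blank), "constant")
  speck <- blank; speck[15, 15] <- 1 # below min_area: no component returned
  expect_equal(nrow(detect_cells(speck, threshold_quantile = 0.99)), 0)
})

test_that("noisy recovery: median ratio within 5% of truth at 30 cells", {
  for (truth in c(0.5, 2)) {
    g <- make_grid_field(30, interior = truth * 100, ring = 100,
                         noise_sd = 10, seed = 7) # noise = 10% of ring level
    m <- measure_cells(g$field$image, g$rois)
    expect_equal(nrow(m), 30)
    s <- summarize_condition(m, seed = 11)
    expect_lt(abs(s$median_ratio - truth) / truth, 0.05)
    expect_true(s$ci_low <= s$median_ratio && s$median_ratio <= s$ci_high)
  }
})

test_that("condition summaries: median, degenerate CI, seeded bootstrap", {
  expect_equal(summarize_condition(tibble::tibble(ratio = c(1, 2, 3)))$median_ratio, 2)
  s <- summarize_condition(tibble::tibble(ratio = rep(4.2, 8)))
  expect_equal(c(s$ci_low, s$ci_high), c(4.2, 4.2))
  set.seed(99)
  r <- tibble::tibble(ratio = rlnorm(50))
  s1 <- summarize_condition(r, seed = 5)
  s2 <- summarize_condition(r, seed = 5)
  expect_identical(s1, s2)
  expect_error(summarize_condition(tibble::tibble(ratio = numeric(0))),
               "no cells")
})

test_that("baseline normalization divides by each variant's time-0 median", {
  m <- tibble::tibble(
    condition = rep(c("wt", "mut"), each = 4),
    time = rep(c(0, 0, 180, 180), 2),
    ratio = c(1, 3, 4, 6, 0.5, 0.5, 1.5, 2.5)
  )
  norm <- normalize_to_baseline(m)
  # time-0 groups renormalize to median 1
  expect_equal(median(norm$ratio[norm$condition == "wt" & norm$time == 0]), 1)
  # mut t0 median 0.5, t180 ratio 1.5 -> normalized 3.0
  expect_equal(norm$ratio[norm$condition == "mut" & norm$time == 180],
               c(3, 5))
  expect_error(normalize_to_baseline(m[m$time != 0 | m$condition != "mut", ]),
               "mut")
})

test_that("exact Wilcoxon agrees with exhaustive enumeration up to n = 6", {
  set.seed(314)
  for (m in 1:6) for (n in m:6) {
    vals <- sample(seq(0.05, 50, by = 0.05), m + n) # distinct: no ties
    x <- vals[seq_len(m)]; y <- vals[-seq_len(m)]
    got <- compare_conditions(tibble::tibble(
      condition = rep(c("g1", "g2"), c(m, n)), ratio = c(x, y)
    ))
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_wilcox_exact(x, y), tolerance = 1e-12,
                 label = sprintf("exact p for sizes (%d, %d)", m, n))
  }
})

test_that("Wilcoxon handles symmetric nulls, extremes and tied data", {
  same <- tibble::tibble(condition = rep(c("a", "b"), each = 4),
                         ratio = c(1, 2, 3, 4, 4, 3, 2, 1))
  # identical multisets carry ties -> normal approximation, p near 1
  expect_gt(compare_conditions(same)$p_value, 0.9)
  sep <- tibble::tibble(condition = rep(c("a", "b"), each = 3),
                        ratio = c(1, 2, 3, 4, 5, 6))
  expect_equal(compare_conditions(sep)$p_value, 0.1) # 2/20 orderings
  big <- tibble::tibble(condition = rep(c("a", "b"), each = 12),
                        ratio = c(rnorm(12), rnorm(12)))
  expect_false(compare_conditions(big)$exact) # n > 10: approximation
  expect_error(compare_conditions(tibble::tibble(condition = "a", ratio = 1)),
               "two condition")
})

test_that("Holm adjustment matches its closed form and is monotone", {
  expect_equal(oracle_holm(c(0.01, 0.04)), c(0.02, 0.04))
  m <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 5),
                      ratio = c(1:5, 3:7, 10:14) + 0.1 * runif(15))
  cc <- compare_conditions(m)
  expect_equal(cc$p_holm, oracle_holm(cc$p_value), tolerance = 1e-12)
  expect_true(all(cc$p_holm >= cc$p_value))
  o <- order(cc$p_value)
  expect_true(all(diff(cc$p_holm[o]) >= 0))
})

test_that("PGM round-trip preserves integer images", {
  img <- matrix(sample(0:65535, 30 * 20), nrow = 20)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(img, path)
  expect_identical(read_pgm(path), img + 0) # numeric storage
  expect_error(read_pgm(withr::local_tempfile(lines = "P5")), "P2")
})
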