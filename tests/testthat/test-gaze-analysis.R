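rect_default <- image_rect(c(1280, 1024), 824)

test_that("binning matches direct enumeration and the stated geometry", {
  # 824 px image, G = 10 -> 82.4 px cells
  h0 <- bin_fixations(data.frame(x = numeric(0), y = numeric(0)),
                      rect_default, 10)
  expect_equal(attr(h0, "cell_px"), 82.4)

  # single fixation at the image center -> exactly one cell of count 1
  cx <- rect_default$x0 + 412; cy <- rect_default$y0 + 412
  h1 <- bin_fixations(data.frame(x = cx, y = cy), rect_default, 10)
  expect_equal(sum(h1), 1)
  expect_equal(sum(unclass(h1) > 0), 1)

  # 7 hand-placed fixations against an enumeration oracle (half-open
  # cells, last closed): offsets in image px -> (row, col), 1-based
  off <- data.frame(
    x = c(0,    82.39, 82.4, 411, 823.9, 824,  100),
    y = c(0,    0,     0,    500, 823.9, 824,  100))
  fx <- data.frame(x = rect_default$x0 + off$x, y = rect_default$y0 + off$y)
  h7 <- bin_fixations(fx, rect_default, 10)
  want <- matrix(0, 10, 10)
  for (i in seq_len(nrow(off))) {
    # oracle enumerates from the same screen coordinates the binner sees
    ox <- fx$x[i] - rect_default$x0
    oy <- fx$y[i] - rect_default$y0
    col <- min(floor(ox / 82.4), 9) + 1
    row <- min(floor(oy / 82.4), 9) + 1
    want[row, col] <- want[row, col] + 1
  }
  expect_equal(unclass(h7), want, ignore_attr = TRUE)
  expect_equal(attr(h7, "n_fixations"), 7)

  # fixations outside the image are discarded and counted, not clipped
  out <- data.frame(x = c(rect_default$x0 - 1, cx),
                    y = c(cy, rect_default$y0 + 825))
  ho <- bin_fixations(out, rect_default, 10)
  expect_equal(sum(ho), 0)
  expect_equal(attr(ho, "n_discarded"), 2)
})

test_that("state machine: normalization and correlation reject wrong states", {
  counts <- counts_heatmap(matrix(1:4, 2, 2))
  norm <- normalize_heatmap(counts)
  expect_error(normalize_heatmap(norm), "state 'raw_counts'")
  expect_error(subtract_bias(counts, matrix(0, 2, 2)),
               "state 'normalized'")
  expect_error(correlate_styles_for_image(
    list(A = norm, B = norm), style_set(c("A", "B"))),
    "state 'bias_subtracted'")
  expect_error(grand_bias(list(counts)), "state 'normalized'")
})

test_that("normalization conserves mass and rejects empty maps", {
  counts <- counts_heatmap(matrix(rpois(100, 2), 10, 10))
  norm <- normalize_heatmap(counts)
  expect_equal(sum(norm), 1, tolerance = 1e-12)
  u <- normalize_heatmap(counts_heatmap(matrix(3, 10, 10)))
  expect_true(all(abs(unclass(u) - 0.01) < 1e-15))
  expect_error(normalize_heatmap(counts_heatmap(matrix(0, 10, 10))),
               "no fixations")
})

test_that("grand bias is the unweighted mean and subtraction zeroes mass", {
  a <- normalize_heatmap(counts_heatmap(matrix(c(4, 0, 0, 0), 2, 2)))
  b <- normalize_heatmap(counts_heatmap(matrix(c(0, 0, 0, 4), 2, 2)))
  bias <- grand_bias(list(a, b))
  expect_equal(bias, (unclass(a) + unclass(b)) / 2, ignore_attr = TRUE)
  expect_equal(sum(bias), 1, tolerance = 1e-12)

  # identical maps: bias equals the map, subtraction gives all zeros
  bias_a <- grand_bias(list(a, a))
  za <- subtract_bias(a, bias_a)
  expect_equal(unclass(za), matrix(0, 2, 2), ignore_attr = TRUE)

  # 2x2 hand example: cell-wise difference
  d <- subtract_bias(a, bias)
  expect_equal(unclass(d), unclass(a) - bias, ignore_attr = TRUE)
  expect_equal(sum(d), 0, tolerance = 1e-12)
  expect_error(subtract_bias(a, matrix(0.25, 3, 3)), "mismatch")
})

test_that("per-image Pearson correlation matches the product-moment oracle", {
  set.seed(7)
  m1 <- matrix(rnorm(100), 10, 10)
  m2 <- 0.6 * m1 + 0.4 * matrix(rnorm(100), 10, 10)
  mk <- function(m, s) styletree:::new_heatmap(
    m, "bias_subtracted", "m1", s, 10L, 0L, 82.4)
  sc <- correlate_styles_for_image(
    list(A = mk(m1, "A"), B = mk(m2, "B"), C = mk(-m1, "C"),
         D = mk(m1, "D")),
    style_set(c("A", "B", "C", "D")))
  # product-moment oracle on the flattened vectors
  v1 <- as.vector(t(m1)); v2 <- as.vector(t(m2))
  r_oracle <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(sc$r["A", "B"], r_oracle, tolerance = 1e-12)
  expect_equal(sc$r["A", "C"], -1)          # map vs its negation
  expect_equal(sc$r["A", "D"], 1)           # identical maps
  expect_equal(sc$r, t(sc$r))
  expect_equal(unname(diag(sc$r)), rep(1, 4))
  expect_true(all(sc$p >= 0 & sc$p <= 1, na.rm = TRUE))
  # p-value against cor.test itself on a known pair
  expect_equal(sc$p["A", "B"], cor.test(v1, v2)$p.value)
})

test_that("zero-variance maps yield NA with a warning, never silent zero", {
  flat <- styletree:::new_heatmap(matrix(0, 5, 5), "bias_subtracted",
                                  "m1", "A", 5L, 0L, 82.4)
  ok <- styletree:::new_heatmap(matrix(rnorm(25), 5, 5),
                                "bias_subtracted", "m1", "B", 5L, 0L, 82.4)
  expect_warning(
    sc <- correlate_styles_for_image(list(A = flat, B = ok),
                                     style_set(c("A", "B"))),
    "zero-variance")
  expect_true(is.na(sc$r["A", "B"]))
})

test_that("averaging correlations is cell-wise over defined images", {
  labs <- c("A", "B")
  mk_sc <- function(r_ab) {
    r <- matrix(c(1, r_ab, r_ab, 1), 2, dimnames = list(labs, labs))
    styletree:::new_style_correlation(
      r, matrix(NA_real_, 2, 2, dimnames = list(labs, labs)),
      matrix(1L, 2, 2, dimnames = list(labs, labs)))
  }
  one <- average_correlations(list(mk_sc(0.4)))
  expect_equal(one$r["A", "B"], 0.4)
  # +1 and -1 in equal shares average to 0
  mix <- average_correlations(list(mk_sc(1), mk_sc(-1), mk_sc(1),
                                   mk_sc(-1)))
  expect_equal(mix$r["A", "B"], 0)
  # three hand-specified values
  three <- average_correlations(list(mk_sc(0.1), mk_sc(0.5), mk_sc(0.9)))
  expect_equal(three$r["A", "B"], 0.5)
  expect_equal(three$n_images["A", "B"], 3L)
  # NA cells do not enter the mean
  na_sc <- mk_sc(NA_real_)
  avg <- average_correlations(list(mk_sc(0.2), na_sc))
  expect_equal(avg$r["A", "B"], 0.2)
  expect_equal(avg$n_images["A", "B"], 1L)
})

test_that("accumulated style maps expose style structure and conserve mass", {
  # single-image dataset: the lone map defines the bias, accumulation zero
  a <- normalize_heatmap(counts_heatmap(matrix(c(4, 1, 1, 2), 2, 2),
                                        style = "A"))
  expect_warning(
    acc1 <- accumulate_style_heatmaps(list(a), style_set(c("A", "B"))),
    "no heatmaps for style B")
  expect_equal(unclass(acc1$A), matrix(0, 2, 2), ignore_attr = TRUE)

  # all styles sharing one field: accumulated maps are all zero
  b <- normalize_heatmap(counts_heatmap(matrix(c(4, 1, 1, 2), 2, 2),
                                        style = "B"))
  acc2 <- suppressWarnings(
    accumulate_style_heatmaps(list(a, b), style_set(c("A", "B"))))
  expect_lt(max(abs(unclass(acc2$A))), 1e-12)
  expect_lt(max(abs(unclass(acc2$B))), 1e-12)

  # distinct fields: accumulated maps differ and each sums to zero
  c1 <- normalize_heatmap(counts_heatmap(matrix(c(9, 0, 0, 1), 2, 2),
                                         style = "A", motif = "m2"))
  c2 <- normalize_heatmap(counts_heatmap(matrix(c(0, 1, 9, 0), 2, 2),
                                         style = "B", motif = "m2"))
  acc3 <- accumulate_style_heatmaps(list(a, b, c1, c2),
                                    style_set(c("A", "B")))
  expect_gt(max(abs(unclass(acc3$A) - unclass(acc3$B))), 0.1)
  expect_equal(sum(acc3$A), 0, tolerance = 1e-12)
  expect_equal(sum(acc3$B), 0, tolerance = 1e-12)
})

test_that("density map peaks where the data are", {
  one <- data.frame(subject = "s1", x = 400, y = 300)
  dm <- density_map(one)
  expect_lt(abs(dm$peak["x"] - 400), 15)
  expect_lt(abs(dm$peak["y"] - 300), 15)
  # density integrates to ~1 over the screen
  dx <- diff(dm$x[1:2]); dy <- diff(dm$y[1:2])
  expect_equal(sum(dm$z) * dx * dy, 1, tolerance = 0.05)

  # center-biased simulation: pooled peak within the central 20% of image
  tax <- small_taxonomy()
  model <- gaze_behavior_model(weight_content = 0, weight_style = 0,
                               weight_center = 1, seed = 17)
  fix <- simulate_fixations(
    make_gaze_design(motifs_per_style = 2, n_subjects = 8, seed = 17),
    tax, model)
  dmc <- density_map(fix)
  expect_lt(abs(dmc$peak["x"] - 640), 0.1 * 824)
  expect_lt(abs(dmc$peak["y"] - 512), 0.1 * 824)
})

test_that("gaze pipeline with neither style nor content signal gives r ~ 0", {
  # center bias + sampling noise only: bias subtraction leaves pure noise
  tax <- small_taxonomy()
  model <- gaze_behavior_model(weight_content = 0, weight_style = 0,
                               weight_center = 1, seed = 23)
  fix <- simulate_fixations(
    make_gaze_design(motifs_per_style = 6, n_subjects = 16, seed = 23),
    tax, model)
  res <- gaze_pipeline(fix)
  r <- res$correlation$r
  expect_equal(unname(diag(r)), rep(1, 8))
  # per-pair t statistics of the per-image correlations around 0
  tstats <- pair_t_stats(res$per_image, center = 0)
  expect_lt(max(abs(tstats)), 4.5)
})

test_that("gaze pipeline with content but no style signal is uniform across pairs", {
  # shared motif content correlates every pair equally; with zero style
  # weight the pair means are statistically indistinguishable and the
  # dendrogram heights collapse
  tax <- small_taxonomy()
  model <- gaze_behavior_model(weight_content = 0.6, weight_style = 0,
                               weight_center = 0.4, seed = 23)
  fix <- simulate_fixations(
    make_gaze_design(motifs_per_style = 6, n_subjects = 16, seed = 23),
    tax, model)
  res <- gaze_pipeline(fix)
  r <- res$correlation$r
  ut <- upper.tri(r)
  grand <- mean(r[ut])
  expect_gt(grand, 0.05)                  # content residual correlates all
  tstats <- pair_t_stats(res$per_image, center = grand)
  expect_lt(max(abs(tstats)), 4.5)
  # merge heights nearly equal relative to their level
  h <- res$tree$height
  expect_lt(max(h) - min(h), 0.2 * mean(1 - r[ut]) + 0.05)
})

test_that("gaze pipeline is deterministic and validates inputs", {
  tax <- small_taxonomy()
  model <- gaze_behavior_model(seed = 29)
  fix <- simulate_fixations(
    make_gaze_design(motifs_per_style = 2, n_subjects = 8, seed = 29),
    tax, model)
  r1 <- gaze_pipeline(fix)
  r2 <- gaze_pipeline(fix)
  expect_equal(r1$correlation$r, r2$correlation$r)
  expect_equal(r1$tree$height, r2$tree$height)
  bad <- fix; bad$style[1] <- "XX"
  expect_error(gaze_pipeline(bad), "unknown style")
})
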