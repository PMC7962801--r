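#' Style-by-style correlation of gaze heatmaps
#'
#' A `style_correlation` holds a symmetric matrix of Pearson coefficients
#' between styles' bias-subtracted fixation heatmaps (unit diagonal), the
#' matching two-sided p-values, and the number of images each cell was
#' averaged over.
#'
#' @name style_correlation
NULL

new_style_correlation <- function(r, p, n_images) {
  structure(list(r = r, p = p, n_images = n_images),
            class = "style_correlation")
}

#' @export
print.style_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("Style correlation over %s image(s)\n",
              paste(range(x$n_images[upper.tri(x$n_images)]),
                    collapse = "-")))
  print(round(x$r, digits))
  invisible(x)
}

# row-major flattening: concatenate grid rows left-to-right, top-down
flatten_rowmajor <- function(m) as.vector(t(unclass(m)))

#' Pearson correlations between the style heatmaps of one image
#'
#' Flattens each style's bias-subtracted heatmap of one motif into a 1D
#' vector (row-major) and computes the pairwise Pearson correlation
#' coefficient and its two-sided p-value. Zero-variance maps yield `NA`
#' cells with a warning (never a silent 0).
#'
#' @param heatmaps named list (by style) of `heatmap_grid`s in state
#'   `bias_subtracted`, all from the same motif.
#' @param styles style roster fixing the matrix order.
#' @return a `style_correlation` with `n_images = 1` for cells backed by
#'   both maps, 0 otherwise.
#' @export
correlate_styles_for_image <- function(heatmaps, styles = style_set()) {
  styles <- as_style_set(styles)
  if (length(heatmaps) < 2) {
    stop("need heatmaps of at least 2 styles to correlate", call. = FALSE)
  }
  for (h in heatmaps) check_state(h, "bias_subtracted",
                                  "correlate_styles_for_image()")
  check_styles_known(names(heatmaps), styles)
  n <- length(styles)
  labs <- as.character(styles)
  r <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  p <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  nim <- matrix(0L, n, n, dimnames = list(labs, labs))
  diag(r) <- 1
  vecs <- lapply(heatmaps, flatten_rowmajor)
  present <- labs[labs %in% names(vecs)]
  for (ai in seq_along(present)) {
    for (bi in seq_along(present)) {
      if (bi <= ai) next
      a <- present[ai]; b <- present[bi]
      va <- vecs[[a]]; vb <- vecs[[b]]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning(sprintf(
          "zero-variance heatmap for pair (%s, %s); correlation undefined",
          a, b), call. = FALSE)
        next
      }
      ct <- stats::cor.test(va, vb, method = "pearson")
      r[a, b] <- r[b, a] <- unname(ct$estimate)
      p[a, b] <- p[b, a] <- ct$p.value
      nim[a, b] <- nim[b, a] <- 1L
    }
  }
  new_style_correlation(r, p, nim)
}

#' Average per-image correlation matrices over a dataset
#'
#' Cell-wise arithmetic mean of the Pearson coefficients over the images
#' in which the cell is defined; per-cell image counts are recorded.
#' p-values are computed per image but not meta-combined; the averaged
#' object carries `NA` p-values.
#'
#' @param correlations list of per-image `style_correlation`s on the same
#'   roster.
#' @return a dataset-level `style_correlation`; a cell defined in no image
#'   is `NA`.
#' @export
average_correlations <- function(correlations) {
  if (length(correlations) < 1) {
    stop("need at least one per-image correlation matrix", call. = FALSE)
  }
  labs <- rownames(correlations[[1]]$r)
  n <- length(labs)
  sum_r <- matrix(0, n, n, dimnames = list(labs, labs))
  count <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (sc in correlations) {
    stopifnot(inherits(sc, "style_correlation"))
    if (!identical(rownames(sc$r), labs)) {
      stop("correlation matrices have mismatched rosters", call. = FALSE)
    }
    ok <- !is.na(sc$r)
    sum_r[ok] <- sum_r[ok] + sc$r[ok]
    count[ok] <- count[ok] + 1L
  }
  r <- sum_r / count
  r[count == 0] <- NA_real_
  p <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  new_style_correlation(r, p, count)
}

#' Convert a style correlation matrix to clustering distances
#'
#' The standard monotone conversion `d = 1 - r` (configurable hook for
#' alternatives), with zero diagonal. More correlated gaze patterns mean
#' more similar styles, hence smaller distances.
#'
#' @param correlation a `style_correlation`.
#' @param rule `"one_minus_r"` (default) or `"sqrt_one_minus_r"`
#'   (`sqrt((1 - r) / 2)`, proportional to the Euclidean distance between
#'   standardized vectors).
#' @return a symmetric `pair_matrix` with statistic `"distance"`.
#' @export
correlation_distance <- function(correlation,
                                 rule = c("one_minus_r",
                                          "sqrt_one_minus_r")) {
  rule <- match.arg(rule)
  stopifnot(inherits(correlation, "style_correlation"))
  r <- correlation$r
  d <- switch(rule,
              one_minus_r = 1 - r,
              sqrt_one_minus_r = sqrt(pmax(1 - r, 0) / 2))
  diag(d) <- 0
  pair_matrix(d, rownames(r), "distance")
}

#' Full gaze analysis pipeline
#'
#' Runs the Experiment-2-style analysis end to end: per-(motif, style)
#' binning of fixations into a G x G grid over the image, normalization to
#' unit mass, grand-bias estimation and subtraction, per-image Pearson
#' correlations between styles, averaging over images, conversion to
#' distances, and average-linkage clustering; accumulated per-style maps
#' are produced from the same normalized maps. Maps with zero fixations
#' are excluded from correlation with bookkeeping, and a missing averaged
#' cell aborts clustering with an error naming the pair.
#'
#' @param fixations fixation records (see [read_fixations()] or
#'   [simulate_fixations()]).
#' @param styles style roster.
#' @param config a [run_config()]; the fields `screen_px`, `image_px`,
#'   `grid_size`, `cor_to_distance`, `linkage` are honored.
#' @return a list with `correlation` (averaged `style_correlation`),
#'   `per_image` (list of per-image `style_correlation`s),
#'   `style_heatmaps` (accumulated per-style maps), `bias`, `tree`,
#'   `distance`, and `report` (counts of maps, discarded fixations,
#'   excluded empty maps).
#' @export
gaze_pipeline <- function(fixations, styles = style_set(),
                          config = run_config(styles = styles)) {
  styles <- as_style_set(styles)
  check_styles_known(fixations$style, styles)
  rect <- image_rect(config$screen_px, config$image_px)

  key <- interaction(fixations$motif, fixations$style, drop = TRUE,
                     sep = "\r")
  groups <- split(fixations, key)
  n_empty <- 0L
  n_discarded <- 0L
  normalized <- list()
  for (grp in groups) {
    h <- bin_fixations(grp, rect, config$grid_size)
    n_discarded <- n_discarded + attr(h, "n_discarded")
    if (sum(h) < 1) {
      warning(sprintf("map (%s, %s) has no fixations inside the image",
                      attr(h, "motif"), attr(h, "style")), call. = FALSE)
      n_empty <- n_empty + 1L
      next
    }
    normalized[[length(normalized) + 1]] <- normalize_heatmap(h)
  }
  if (length(normalized) < 2) {
    stop("fewer than two usable heatmaps; cannot correlate", call. = FALSE)
  }
  bias <- grand_bias(normalized)
  map_motif <- vapply(normalized, function(h) attr(h, "motif"),
                      character(1))
  map_style <- vapply(normalized, function(h) attr(h, "style"),
                      character(1))
  per_image <- list()
  for (m in unique(map_motif)) {
    sel <- which(map_motif == m)
    if (length(sel) < 2) next
    maps <- lapply(normalized[sel], subtract_bias, bias = bias)
    names(maps) <- map_style[sel]
    per_image[[m]] <- correlate_styles_for_image(maps, styles)
  }
  if (length(per_image) < 1) {
    stop("no motif was seen in two or more styles; cannot correlate",
         call. = FALSE)
  }
  corr <- average_correlations(per_image)
  dist <- correlation_distance(corr, config$cor_to_distance)
  d <- pm_values(dist)
  miss <- which(is.na(d) & row(d) != col(d), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf("correlation undefined for pair (%s, %s); cannot cluster",
                 rownames(d)[miss[1, 1]], colnames(d)[miss[1, 2]]),
         call. = FALSE)
  }
  tree <- average_linkage(d, method = config$linkage)
  style_maps <- accumulate_style_heatmaps(normalized, styles, bias)
  list(correlation = corr, per_image = per_image,
       style_heatmaps = style_maps, bias = bias, distance = dist,
       tree = tree,
       report = list(n_maps = length(normalized),
                     n_empty_maps = n_empty,
                     n_images_correlated = length(per_image),
                     n_fixations = nrow(fixations),
                     n_discarded_outside = n_discarded))
}
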