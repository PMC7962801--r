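#' Fixation heatmap grids
#'
#' A heatmap grid is a G x G matrix of fixation mass over the image
#' rectangle, carrying a `state` that enforces the processing order:
#' `raw_counts` (from [bin_fixations()]) -> `normalized` (sums to 1) ->
#' `bias_subtracted` (sums to 0). Correlations are only accepted from
#' bias-subtracted maps, normalization only from raw counts.
#'
#' @name heatmap_grid
NULL

new_heatmap <- function(mass, state, motif, style, n_fixations,
                        n_discarded, cell_px) {
  structure(mass, state = state, motif = motif, style = style,
            n_fixations = n_fixations, n_discarded = n_discarded,
            cell_px = cell_px, class = c("heatmap_grid", class(mass)))
}

heatmap_state <- function(h) attr(h, "state")

check_state <- function(h, expected, what) {
  if (!inherits(h, "heatmap_grid")) {
    stop(sprintf("%s requires a heatmap_grid", what), call. = FALSE)
  }
  if (!identical(heatmap_state(h), expected)) {
    stop(sprintf("%s requires a heatmap in state '%s', got '%s'",
                 what, expected, heatmap_state(h)), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.heatmap_grid <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Heatmap grid %dx%d [%s] motif=%s style=%s n_fixations=%d discarded=%d\n",
    nrow(x), ncol(x), attr(x, "state"), attr(x, "motif"),
    attr(x, "style"), attr(x, "n_fixations"), attr(x, "n_discarded")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Bin fixations of one stimulus into a spatial grid
#'
#' Sorts the fixations of one (motif, style) stimulus into a `grid_size` x
#' `grid_size` grid over the image rectangle. Cells are half-open
#' intervals, with the last row/column closed at the image edge; grid rows
#' run top-down (screen y), columns left-right (screen x). With the
#' default geometry (824 px image, G = 10) each cell covers
#' 82.4 x 82.4 px. Fixations outside the image rectangle are discarded and
#' counted, not clipped into edge cells.
#'
#' @param fixations data.frame with `x`, `y` in screen px (one stimulus).
#' @param rect image rectangle from [image_rect()].
#' @param grid_size cells per side (default 10).
#' @param motif,style identifiers stored on the grid (default taken from
#'   the data when unique, else `"ALL"`).
#' @return a `heatmap_grid` in state `raw_counts`; attributes
#'   `n_fixations` (counted) and `n_discarded` (outside the image).
#' @export
bin_fixations <- function(fixations, rect = image_rect(),
                          grid_size = 10, motif = NULL, style = NULL) {
  grid_size <- check_count(grid_size, "grid_size", min = 2)
  if (rect$w <= 0 || rect$h <= 0) stop("empty image rectangle",
                                       call. = FALSE)
  grab <- function(given, col) {
    if (!is.null(given)) return(as.character(given))
    v <- unique(fixations[[col]])
    if (length(v) == 1) as.character(v) else "ALL"
  }
  motif <- grab(motif, "motif")
  style <- grab(style, "style")

  x <- fixations$x - rect$x0
  y <- fixations$y - rect$y0
  inside <- x >= 0 & x <= rect$w & y >= 0 & y <= rect$h
  cw <- rect$w / grid_size
  ch <- rect$h / grid_size
  j <- pmin(floor(x[inside] / cw), grid_size - 1) + 1  # column, x
  i <- pmin(floor(y[inside] / ch), grid_size - 1) + 1  # row, y
  counts <- matrix(
    tabulate((j - 1) * grid_size + i, nbins = grid_size^2),
    grid_size, grid_size)
  new_heatmap(counts, "raw_counts", motif, style,
              n_fixations = sum(inside), n_discarded = sum(!inside),
              cell_px = rect$w / grid_size)
}

#' Normalize a raw-count heatmap to unit mass
#'
#' @param h a `heatmap_grid` in state `raw_counts` with at least one
#'   fixation.
#' @return the grid in state `normalized`, cells summing to 1.
#' @export
normalize_heatmap <- function(h) {
  check_state(h, "raw_counts", "normalize_heatmap()")
  total <- sum(h)
  if (total < 1) {
    stop(sprintf(
      "heatmap for motif %s style %s has no fixations; map undefined",
      attr(h, "motif"), attr(h, "style")), call. = FALSE)
  }
  new_heatmap(unclass(h) / total, "normalized", attr(h, "motif"),
              attr(h, "style"), attr(h, "n_fixations"),
              attr(h, "n_discarded"), attr(h, "cell_px"))
}

#' Grand spatial bias of a fixation dataset
#'
#' The unweighted arithmetic mean of all normalized heatmaps across every
#' (motif, style) map in the dataset. It is dominated by the central
#' fixation bias and is subtracted from each map to isolate
#' style-specific gaze structure.
#'
#' @param heatmaps list of `heatmap_grid`s in state `normalized`.
#' @return a matrix summing to 1 (the bias field).
#' @export
grand_bias <- function(heatmaps) {
  if (length(heatmaps) < 1) stop("need at least one normalized heatmap",
                                 call. = FALSE)
  for (h in heatmaps) check_state(h, "normalized", "grand_bias()")
  Reduce(`+`, lapply(heatmaps, unclass)) / length(heatmaps)
}

#' Subtract the grand bias from a normalized heatmap
#'
#' @param h a `heatmap_grid` in state `normalized`.
#' @param bias bias field from [grand_bias()] (same grid size).
#' @return the grid in state `bias_subtracted`, cells summing to 0.
#' @export
subtract_bias <- function(h, bias) {
  check_state(h, "normalized", "subtract_bias()")
  if (!all(dim(h) == dim(bias))) {
    stop(sprintf("grid size mismatch: heatmap %dx%d vs bias %dx%d",
                 nrow(h), ncol(h), nrow(bias), ncol(bias)), call. = FALSE)
  }
  new_heatmap(unclass(h) - unclass(bias), "bias_subtracted",
              attr(h, "motif"), attr(h, "style"), attr(h, "n_fixations"),
              attr(h, "n_discarded"), attr(h, "cell_px"))
}

#' Accumulated per-style heatmaps
#'
#' For each style, averages that style's normalized per-image maps and
#' subtracts the grand bias of the whole dataset, exposing where a style
#' attracts gaze relative to the dataset-wide pattern. Each accumulated
#' map sums to 0, since both the style average and the bias are unit-mass
#' fields.
#'
#' @param heatmaps list of `heatmap_grid`s in state `normalized`, each
#'   carrying its `style` attribute.
#' @param styles style roster (styles with no maps are dropped with a
#'   warning).
#' @param bias optional precomputed bias; defaults to
#'   `grand_bias(heatmaps)`.
#' @return a named list of `heatmap_grid`s (state `bias_subtracted`,
#'   motif `"ALL"`), one per style present.
#' @export
accumulate_style_heatmaps <- function(heatmaps, styles = style_set(),
                                      bias = NULL) {
  styles <- as_style_set(styles)
  for (h in heatmaps) check_state(h, "normalized",
                                  "accumulate_style_heatmaps()")
  if (is.null(bias)) bias <- grand_bias(heatmaps)
  map_styles <- vapply(heatmaps, function(h) attr(h, "style"), character(1))
  check_styles_known(map_styles, styles)
  out <- list()
  for (s in as.character(styles)) {
    sel <- heatmaps[map_styles == s]
    if (length(sel) == 0) {
      warning("no heatmaps for style ", s, "; accumulated map missing",
              call. = FALSE)
      next
    }
    avg <- Reduce(`+`, lapply(sel, unclass)) / length(sel)
    nf <- sum(vapply(sel, function(h) attr(h, "n_fixations"), numeric(1)))
    out[[s]] <- new_heatmap(avg - bias, "bias_subtracted", "ALL", s,
                            n_fixations = nf, n_discarded = 0L,
                            cell_px = attr(sel[[1]], "cell_px"))
  }
  out
}

#' Kernel-smoothed fixation density map with peak location
#'
#' A 2D kernel density estimate of fixation positions over the screen
#' (via [MASS::kde2d()]), for a single subject or all subjects pooled.
#' Reports the location of the density peak alongside the screen center,
#' mirroring the visual check that gaze mass concentrates centrally.
#'
#' @param fixations data.frame with `x`, `y` (screen px) and `subject`.
#' @param subject a subject identifier, or `"ALL"` (default) to pool.
#' @param screen_px screen size `c(width, height)`.
#' @param bandwidth kernel bandwidth in px (scalar, used for both axes);
#'   default 60.
#' @param n evaluation grid resolution per axis.
#' @return a list with `x`, `y`, `z` (density surface integrating to 1),
#'   `peak` (c(x, y) of the maximum), `center` (screen center) and
#'   `n_fixations`.
#' @export
density_map <- function(fixations, subject = "ALL",
                        screen_px = c(1280, 1024), bandwidth = 60,
                        n = 128) {
  if (!identical(subject, "ALL")) {
    fixations <- fixations[fixations$subject == subject, , drop = FALSE]
  }
  if (nrow(fixations) < 1) stop("no fixations to map", call. = FALSE)
  kd <- MASS::kde2d(fixations$x, fixations$y,
                    h = c(bandwidth, bandwidth) * 4, n = n,
                    lims = c(0, screen_px[1], 0, screen_px[2]))
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)[1, ]
  list(x = kd$x, y = kd$y, z = kd$z,
       peak = c(x = kd$x[peak[1]], y = kd$y[peak[2]]),
       center = c(x = screen_px[1] / 2, y = screen_px[2] / 2),
       n_fixations = nrow(fixations))
}
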