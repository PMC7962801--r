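#' Planted style taxonomy for synthetic data generation
#'
#' Wraps a linkage tree together with a positive `distance_scale` mapping
#' its cophenetic distances into normalized planted distances in `[0, 1]`.
#' The planted distance is the quantity the behavioral simulators condition
#' on and that the analysis pipelines should recover.
#'
#' @param tree a `linkage_tree` (e.g. [reference_taxonomy()] or the result
#'   of [average_linkage()]), or a newick string.
#' @param distance_scale positive scale; defaults to the maximum cophenetic
#'   distance so planted distances span `[0, 1]`. For an all-zero tree
#'   (every height 0) the scale defaults to 1 and all planted distances are
#'   0 (the "star" null taxonomy).
#' @return an object of class `planted_taxonomy` with fields `tree`,
#'   `distance_scale`, `distances` (normalized symmetric matrix) and
#'   `styles`.
#' @examples
#' tax <- planted_taxonomy(reference_taxonomy())
#' range(tax$distances)
#' @export
planted_taxonomy <- function(tree, distance_scale = NULL) {
  if (is.character(tree)) tree <- from_newick(text = tree)
  stopifnot(inherits(tree, "linkage_tree") || inherits(tree, "hclust"))
  coph <- cophenetic_matrix(tree)
  if (is.null(distance_scale)) {
    distance_scale <- max(coph)
    if (distance_scale == 0) distance_scale <- 1
  }
  check_pos(distance_scale, "distance_scale")
  d <- coph / distance_scale
  if (any(d > 1 + 1e-9)) {
    stop("distance_scale too small: normalized planted distances exceed 1",
         call. = FALSE)
  }
  d <- pmin(d, 1)
  structure(
    list(tree = tree, distance_scale = distance_scale,
         distances = d, styles = style_set(tree$labels)),
    class = "planted_taxonomy")
}

#' Degenerate "star" taxonomy with all planted distances zero
#'
#' Used for null calibration: under zero planted distance the search
#' simulator produces chance-level accuracy and the gaze simulator gives
#' every style the same expected fixation field.
#'
#' @param styles a style roster (default the eight-style roster).
#' @return a `planted_taxonomy` whose `distances` are identically 0.
#' @export
planted_star <- function(styles = style_set()) {
  styles <- as_style_set(styles)
  n <- length(styles)
  d <- matrix(0, n, n, dimnames = list(styles, styles))
  planted_taxonomy(average_linkage(d), distance_scale = 1)
}

# distance lookup for (target, distractor) label vectors
planted_distance <- function(taxonomy, a, b) {
  stopifnot(inherits(taxonomy, "planted_taxonomy"))
  check_styles_known(c(a, b), taxonomy$styles)
  taxonomy$distances[cbind(as.character(a), as.character(b))]
}

#' @export
print.planted_taxonomy <- function(x, ...) {
  cat(sprintf("Planted taxonomy over %d styles (scale %.4g)\n",
              length(x$styles), x$distance_scale))
  print(x$tree)
  invisible(x)
}
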