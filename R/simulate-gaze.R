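# Latent-field machinery for the gaze simulator.

# Smooth standardized Gaussian random field on a g x g grid: white noise
# smoothed by a separable Gaussian kernel, then standardized across cells.
smooth_field <- function(g, smoothness) {
  z <- matrix(stats::rnorm(g * g), g, g)
  idx <- seq_len(g)
  k <- outer(idx, idx, function(a, b) stats::dnorm(a - b, sd = smoothness))
  k <- k / rowSums(k)
  f <- k %*% z %*% t(k)
  (f - mean(f)) / stats::sd(f)
}

#' Latent style fields diffused along the planted tree
#'
#' Generates one smooth Gaussian field per style by accumulating
#' independent fields along the branches of the planted tree, each branch
#' contribution scaled by the square root of its length relative to the
#' taxonomy's `distance_scale`. Styles sharing a long root-ward path share
#' most of their field, so the expected correlation between the fields of
#' styles `s` and `t` equals `1 - D(s, t)`, the complement of the
#' normalized planted distance.
#'
#' @param taxonomy a [planted_taxonomy()].
#' @param model a [gaze_behavior_model()] (supplies grid and smoothness).
#' @param seed integer seed (defaults to the model's seed).
#' @return a named list of `field_grid` x `field_grid` matrices, one per
#'   style, approximately standardized.
#' @export
style_fields <- function(taxonomy, model, seed = model$seed) {
  stopifnot(inherits(taxonomy, "planted_taxonomy"),
            inherits(model, "gaze_behavior_model"))
  g <- model$field_grid
  sm <- model$field_smoothness
  tree <- taxonomy$tree
  n <- length(tree$labels)
  scale <- taxonomy$distance_scale
  H <- if (length(tree$height)) max(tree$height) else 0

  with_stream_seed(seed, "style_fields", {
    out <- stats::setNames(vector("list", n), tree$labels)
    # shared component above the root fills the gap between the tree depth
    # and the distance scale, so leaf-field variances stay at 1
    base <- if (scale > H + 1e-12) {
      sqrt((scale - H) / scale) * smooth_field(g, sm)
    } else {
      matrix(0, g, g)
    }
    descend <- function(node, parent_field, parent_height) {
      if (node < 0) {
        len <- parent_height
        out[[-node]] <<- parent_field +
          sqrt(max(len, 0) / scale) * smooth_field(g, sm)
      } else {
        len <- parent_height - tree$height[node]
        f <- parent_field + sqrt(max(len, 0) / scale) * smooth_field(g, sm)
        descend(tree$merge[node, 1], f, tree$height[node])
        descend(tree$merge[node, 2], f, tree$height[node])
      }
    }
    root <- n - 1L
    descend(tree$merge[root, 1], base, tree$height[root])
    descend(tree$merge[root, 2], base, tree$height[root])
    out
  })
}

# exponential transform of a latent field into a positive density (sums to 1)
field_density <- function(field, gain) {
  w <- exp(gain * field)
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("degenerate fixation density",
                                    call. = FALSE)
  w / s
}

# central Gaussian bias density on the image grid
center_density <- function(g, sd_frac) {
  pos <- (seq_len(g) - 0.5) / g - 0.5        # cell centers in [-0.5, 0.5]
  w1 <- stats::dnorm(pos, sd = sd_frac)
  d <- outer(w1, w1)
  d / sum(d)
}

#' Simulate free-viewing fixations from a planted taxonomy
#'
#' For each motif one content field is drawn (shared across styles). The
#' style field of a (motif, style) stimulus combines a global per-style
#' component and a per-motif component, both drawn via [style_fields()]
#' and mixed by `style_field_stability`, so the expected inter-style field
#' correlation stays `1 - D` while averages over many motifs converge to
#' it. Each stimulus gets the mixture density
#' `w_content * content + w_style * style + w_center * center bias`,
#' normalized on the image grid. For every scheduled viewing the fixation
#' count is Poisson and positions are i.i.d. from the stimulus density
#' (cell sampled by mass, position uniform within the cell), reported in
#' screen-pixel coordinates (origin top-left). All fixations fall inside
#' the image rectangle and hence the screen.
#'
#' @param design schedule from [make_gaze_design()].
#' @param taxonomy a [planted_taxonomy()] covering all design styles.
#' @param model a [gaze_behavior_model()].
#' @return a data.frame of fixation records with columns `subject`,
#'   `motif`, `style`, `x`, `y` (screen px), `duration_ms` (NA; durations
#'   are not modeled).
#' @export
simulate_fixations <- function(design, taxonomy, model) {
  stopifnot(inherits(taxonomy, "planted_taxonomy"),
            inherits(model, "gaze_behavior_model"))
  need <- c("subject", "motif", "style")
  if (!all(need %in% names(design))) {
    stop("`design` must come from make_gaze_design()", call. = FALSE)
  }
  check_styles_known(design$style, taxonomy$styles)
  g <- model$field_grid
  rect <- image_rect(model$screen_px, model$image_px)
  cell <- model$image_px / g

  sf_global <- style_fields(taxonomy, model)
  stab <- model$style_field_stability
  with_stream_seed(model$seed, "fixations", {
    motifs <- sort(unique(design$motif))
    content <- stats::setNames(
      lapply(motifs, function(m) smooth_field(g, model$field_smoothness)),
      motifs)
    # per-motif style-field components, diffused along the same tree
    local_sf <- stats::setNames(
      lapply(motifs, function(m) {
        if (stab >= 1) return(NULL)
        style_fields(taxonomy, model,
                     seed = derive_seed(model$seed, paste0("local:", m)))
      }),
      motifs)
    center <- center_density(g, model$center_sd_frac)

    counts <- stats::rpois(nrow(design), model$fixations_per_subject_mean)
    key <- paste(design$motif, design$style, sep = "\r")
    groups <- split(seq_len(nrow(design)), key)
    groups <- groups[order(names(groups))]   # deterministic iteration

    pieces <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      m <- design$motif[rows[1]]
      s <- design$style[rows[1]]
      style_field <- if (stab >= 1) sf_global[[s]] else {
        sqrt(stab) * sf_global[[s]] +
          sqrt(1 - stab) * local_sf[[m]][[s]]
      }
      dens <- model$weight_content *
        field_density(content[[m]], model$field_gain) +
        model$weight_style * field_density(style_field,
                                           model$field_gain) +
        model$weight_center * center
      tot <- sum(dens)
      if (!is.finite(tot) || tot <= 0) {
        stop("degenerate fixation density for motif ", m, " style ", s,
             call. = FALSE)
      }
      dens <- dens / tot
      n_fix <- sum(counts[rows])
      if (n_fix == 0) next
      idx <- sample.int(g * g, n_fix, replace = TRUE, prob = as.vector(dens))
      i <- ((idx - 1L) %% g) + 1L            # grid row (y)
      j <- ((idx - 1L) %/% g) + 1L           # grid column (x)
      x <- rect$x0 + (j - 1 + stats::runif(n_fix)) * cell
      y <- rect$y0 + (i - 1 + stats::runif(n_fix)) * cell
      pieces[[gi]] <- data.frame(
        subject = rep(design$subject[rows], counts[rows]),
        motif = m, style = s, x = x, y = y, duration_ms = NA_real_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) {
      out <- data.frame(subject = character(), motif = character(),
                        style = character(), x = numeric(), y = numeric(),
                        duration_ms = numeric(), stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
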