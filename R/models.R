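#' Behavioral model for singleton-search simulation
#'
#' Parameterizes the data-generating assumptions of the search simulator:
#' accuracy follows the psychometric form
#' \deqn{p_{correct}(D) = c + (1 - c)\,(1 - e^{-\lambda D})}
#' with chance level \eqn{c} (1/4 with four response locations) and
#' discrimination gain \eqn{\lambda}, so accuracy is nondecreasing in the
#' planted style distance \eqn{D \in [0, 1]}; reaction times are lognormal
#' with location \eqn{\mu_0 - \beta D} (log-seconds), so mean RT decreases
#' as styles grow more distant. A small fraction of trials are fast guesses
#' (uniform RT on `[0.05, 0.15)` s, response uniform over the four
#' locations) and a small fraction of regular RTs are inflated by a
#' heavy-tailed (Pareto) factor, emulating attention lapses.
#'
#' Defaults are set to match the reported scale of the human experiment:
#' mean correct RT near 2.2 s, overall accuracy near 75%, and an outlier
#' band of a few percent.
#'
#' @param chance_level probability of a correct response at distance 0
#'   (default 0.25, four locations).
#' @param discrimination_gain \eqn{\lambda > 0}, accuracy growth rate in
#'   planted distance.
#' @param rt_location \eqn{\mu_0}, log-seconds at distance 0.
#' @param rt_similarity_slope \eqn{\beta > 0}, log-seconds of RT decrease
#'   per unit planted distance.
#' @param rt_sigma lognormal scale \eqn{\sigma > 0}.
#' @param fast_guess_rate probability a trial is a fast guess.
#' @param outlier_rate probability a regular RT is multiplied by a
#'   heavy-tail factor.
#' @param outlier_shape Pareto tail index of the inflation factor (> 1).
#' @param seed integer master seed for the trial stream.
#' @return an object of class `search_behavior_model`.
#' @export
search_behavior_model <- function(chance_level = 0.25,
                                  discrimination_gain = 2,
                                  rt_location = log(2.0),
                                  rt_similarity_slope = 0.8,
                                  rt_sigma = 0.5,
                                  fast_guess_rate = 0.02,
                                  outlier_rate = 0.01,
                                  outlier_shape = 1.5,
                                  seed = 1L) {
  model <- list(
    chance_level = check_prob(chance_level, "chance_level"),
    discrimination_gain = check_pos(discrimination_gain,
                                    "discrimination_gain", strict = FALSE),
    rt_location = rt_location,
    rt_similarity_slope = check_pos(rt_similarity_slope,
                                    "rt_similarity_slope", strict = FALSE),
    rt_sigma = check_pos(rt_sigma, "rt_sigma"),
    fast_guess_rate = check_prob(fast_guess_rate, "fast_guess_rate"),
    outlier_rate = check_prob(outlier_rate, "outlier_rate"),
    outlier_shape = check_pos(outlier_shape, "outlier_shape"),
    seed = check_count(seed, "seed", min = 0))
  structure(model, class = "search_behavior_model")
}

#' Probability of a correct singleton-search response
#'
#' @param model a [search_behavior_model()].
#' @param distance planted style distance(s) in `[0, 1]`.
#' @return probabilities in `[chance_level, 1]`, nondecreasing in distance.
#' @export
p_correct <- function(model, distance) {
  stopifnot(inherits(model, "search_behavior_model"))
  c0 <- model$chance_level
  c0 + (1 - c0) * (1 - exp(-model$discrimination_gain * distance))
}

#' Behavioral model for free-viewing gaze simulation
#'
#' Each stimulus is an image of size `image_px` centered on a screen of
#' size `screen_px`. The fixation density on a stimulus shown as
#' (motif, style) is a convex mixture of three normalized fields on the
#' image: a content field specific to the motif and shared across styles, a
#' style field shared across motifs, and a central Gaussian bias. Style
#' fields are generated by diffusing independent smooth Gaussian fields
#' along the branches of the planted tree, so that the expected correlation
#' between the latent fields of styles `s` and `t` equals
#' `1 - D(s, t)` where `D` is the normalized planted distance -- the rule
#' linking planted taxonomy to gaze similarity. Per subject and image the
#' fixation count is Poisson with mean `fixations_per_subject_mean`;
#' positions are i.i.d. draws from the mixed density.
#'
#' The default mixture puts more weight on content and center bias than on
#' style, reflecting the empirical observation that content-driven and
#' center-bias structure dominates style-specific gaze structure.
#'
#' @param screen_px screen size, `c(width, height)` in pixels.
#' @param image_px side length of the square image in pixels.
#' @param weight_content,weight_style,weight_center nonnegative mixture
#'   weights summing to 1.
#' @param field_grid resolution of the latent fields (cells per image side).
#' @param field_smoothness Gaussian smoothing bandwidth in field cells.
#' @param center_sd_frac SD of the central bias as a fraction of image size.
#' @param field_gain contrast of the exponential transform turning latent
#'   Gaussian fields into positive densities.
#' @param style_field_stability fraction of the style-field variance shared
#'   across motifs (the rest is redrawn per motif). Both components diffuse
#'   along the planted tree, so the expected inter-style field correlation
#'   is `1 - D` regardless; the shared part makes accumulated per-style
#'   maps distinct, the per-motif part lets averages over many images
#'   converge to the expected correlation.
#' @param fixations_per_subject_mean Poisson mean fixation count per subject
#'   per image (default 16).
#' @param subjects_per_image number of subjects viewing each (motif, style)
#'   under the rotation design (informational; the design determines it).
#' @param seed integer master seed for the fixation stream.
#' @return an object of class `gaze_behavior_model`.
#' @export
gaze_behavior_model <- function(screen_px = c(1280, 1024),
                                image_px = 824,
                                weight_content = 0.5,
                                weight_style = 0.15,
                                weight_center = 0.35,
                                field_grid = 20,
                                field_smoothness = 2.5,
                                center_sd_frac = 0.22,
                                field_gain = 1.5,
                                style_field_stability = 0.3,
                                fixations_per_subject_mean = 16,
                                subjects_per_image = 8,
                                seed = 1L) {
  w <- c(weight_content, weight_style, weight_center)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(screen_px) != 2 || any(screen_px <= 0)) {
    stop("`screen_px` must be c(width, height) in pixels", call. = FALSE)
  }
  check_pos(image_px, "image_px")
  if (image_px > min(screen_px)) {
    stop("image does not fit on the screen", call. = FALSE)
  }
  structure(list(
    screen_px = as.numeric(screen_px),
    image_px = as.numeric(image_px),
    weight_content = weight_content,
    weight_style = weight_style,
    weight_center = weight_center,
    field_grid = check_count(field_grid, "field_grid", min = 2),
    field_smoothness = check_pos(field_smoothness, "field_smoothness"),
    center_sd_frac = check_pos(center_sd_frac, "center_sd_frac"),
    field_gain = check_pos(field_gain, "field_gain"),
    style_field_stability = check_prob(style_field_stability,
                                       "style_field_stability"),
    fixations_per_subject_mean = check_pos(fixations_per_subject_mean,
                                           "fixations_per_subject_mean"),
    subjects_per_image = check_count(subjects_per_image,
                                     "subjects_per_image"),
    seed = check_count(seed, "seed", min = 0)),
    class = "gaze_behavior_model")
}

#' Image rectangle on screen
#'
#' The square image is centered on the screen; the rectangle is half-open
#' in screen-pixel coordinates (origin top-left, x rightward, y downward).
#'
#' @param screen_px `c(width, height)` in pixels.
#' @param image_px image side length in pixels.
#' @return a list with `x0`, `y0` (top-left corner) and `w`, `h`.
#' @export
image_rect <- function(screen_px = c(1280, 1024), image_px = 824) {
  if (image_px > min(screen_px)) {
    stop("image does not fit on the screen", call. = FALSE)
  }
  if (image_px <= 0) stop("empty image rectangle", call. = FALSE)
  list(x0 = (screen_px[1] - image_px) / 2,
       y0 = (screen_px[2] - image_px) / 2,
       w = as.numeric(image_px), h = as.numeric(image_px))
}
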