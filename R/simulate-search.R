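QUADRANTS <- c("TL", "TR", "BL", "BR")

#' Simulate singleton-search trials from a planted taxonomy
#'
#' For every subject the design's trials are replayed (trial order shuffled
#' per subject, as in the human sessions) and responses generated from the
#' behavioral model: with probability `fast_guess_rate` the trial is a fast
#' guess (RT uniform on `[0.05, 0.15)` s, response uniform over the four
#' locations); otherwise the response is correct with probability
#' [p_correct()] at the pair's planted distance, and the RT is lognormal
#' with location decreasing in planted distance, occasionally inflated by a
#' heavy-tailed factor. Fully reproducible from the model's seed.
#'
#' @param design schedule from [make_search_design()].
#' @param taxonomy a [planted_taxonomy()] covering all design styles.
#' @param model a [search_behavior_model()].
#' @param n_subjects number of simulated subjects (default 1).
#' @return a data.frame of trial records with columns `subject`, `block`,
#'   `target_style`, `distractor_style`, `target_location`,
#'   `response_location`, `rt` (seconds), `motif`.
#' @export
simulate_search_trials <- function(design, taxonomy, model,
                                   n_subjects = 1) {
  stopifnot(inherits(taxonomy, "planted_taxonomy"),
            inherits(model, "search_behavior_model"))
  n_subjects <- check_count(n_subjects, "n_subjects")
  need <- c("block", "trial", "target_style", "distractor_style", "motif")
  if (!all(need %in% names(design))) {
    stop("`design` must come from make_search_design()", call. = FALSE)
  }
  check_styles_known(c(design$target_style, design$distractor_style),
                     taxonomy$styles)

  with_stream_seed(model$seed, "search_trials", {
    per_subject <- lapply(seq_len(n_subjects), function(subj) {
      d <- design[sample.int(nrow(design)), , drop = FALSE]
      d$subject <- sprintf("s%03d", subj)
      d
    })
    trials <- do.call(rbind, per_subject)
    n <- nrow(trials)

    dist <- planted_distance(taxonomy, trials$target_style,
                             trials$distractor_style)
    fast <- stats::runif(n) < model$fast_guess_rate
    correct <- stats::runif(n) < p_correct(model, dist)
    rt <- stats::rlnorm(n,
                        meanlog = model$rt_location -
                          model$rt_similarity_slope * dist,
                        sdlog = model$rt_sigma)
    lapse <- stats::runif(n) < model$outlier_rate
    if (any(lapse)) {
      # Pareto(shape) multiplicative factor >= 1: heavy right tail
      u <- stats::runif(sum(lapse))
      rt[lapse] <- rt[lapse] * u^(-1 / model$outlier_shape)
    }
    target_location <- sample(QUADRANTS, n, replace = TRUE)
    response_location <- target_location
    wrong <- !correct & !fast
    if (any(wrong)) {
      # uniform over the three non-target locations
      shift <- sample.int(3, sum(wrong), replace = TRUE)
      ti <- match(target_location[wrong], QUADRANTS)
      response_location[wrong] <- QUADRANTS[((ti - 1 + shift) %% 4) + 1]
    }
    if (any(fast)) {
      rt[fast] <- stats::runif(sum(fast), 0.05, 0.15)
      response_location[fast] <- sample(QUADRANTS, sum(fast),
                                        replace = TRUE)
    }
    out <- data.frame(
      subject = trials$subject, block = trials$block,
      target_style = trials$target_style,
      distractor_style = trials$distractor_style,
      target_location = target_location,
      response_location = response_location,
      rt = rt, motif = trials$motif, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
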