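#' Exclude fast guesses from trial records
#'
#' Trials with reaction time below the threshold (default 150 ms) are
#' removed before any further analysis; such responses are too quick to
#' reflect discrimination (typically accidental double-presses).
#'
#' @param trials data.frame of trial records with an `rt` column (seconds).
#' @param threshold seconds; trials with `rt < threshold` are dropped.
#' @return a list with `trials` (retained rows, order preserved) and
#'   `n_excluded`.
#' @examples
#' tr <- data.frame(rt = c(0.05, 0.149, 0.150, 2.0))
#' exclude_fast_guesses(tr)$n_excluded  # 2
#' @export
exclude_fast_guesses <- function(trials, threshold = 0.150) {
  check_pos(threshold, "threshold")
  keep <- trials$rt >= threshold
  list(trials = trials[keep, , drop = FALSE],
       n_excluded = sum(!keep))
}

#' Winsorize reaction times
#'
#' Clamps reaction times deviating by more than `k` standard deviations
#' from the mean to the boundary values `mean +/- k * SD`. Mean and SD are
#' computed once on the input sample, so re-applying the projection with
#' the original moments is idempotent and no output deviates from the
#' original mean by more than `k` original SDs.
#'
#' @param trials data.frame with an `rt` column (seconds).
#' @param k SD multiplier (default 3.5).
#' @return a list with `trials` (clamped copy) and `report`, a
#'   `winsorize_report` carrying `mean`, `sd`, `k`, `lower`, `upper`,
#'   `n_clamped_low`, `n_clamped_high`, `pct_clamped` and a `degenerate`
#'   flag (single trial or zero SD: data passed through unchanged).
#' @export
winsorize_rts <- function(trials, k = 3.5) {
  check_pos(k, "k")
  rt <- trials$rt
  n <- length(rt)
  m <- mean(rt)
  s <- if (n >= 2) stats::sd(rt) else NA_real_
  degenerate <- n < 2 || is.na(s) || s == 0
  if (degenerate) {
    warning("winsorization skipped: fewer than 2 trials or zero SD",
            call. = FALSE)
    report <- structure(
      list(mean = m, sd = s, k = k, lower = NA_real_, upper = NA_real_,
           n_clamped_low = 0L, n_clamped_high = 0L, pct_clamped = 0,
           n_trials = n, degenerate = TRUE),
      class = "winsorize_report")
    return(list(trials = trials, report = report))
  }
  lower <- m - k * s
  upper <- m + k * s
  low <- rt < lower
  high <- rt > upper
  out <- trials
  out$rt <- pmin(pmax(rt, lower), upper)
  report <- structure(
    list(mean = m, sd = s, k = k, lower = lower, upper = upper,
         n_clamped_low = sum(low), n_clamped_high = sum(high),
         pct_clamped = 100 * (sum(low) + sum(high)) / n,
         n_trials = n, degenerate = FALSE),
    class = "winsorize_report")
  list(trials = out, report = report)
}

#' @export
print.winsorize_report <- function(x, ...) {
  cat(sprintf(
    "Winsorization at +/-%.2f SD: mean %.4f s, SD %.4f s, band [%.4f, %.4f]\n",
    x$k, x$mean, x$sd, x$lower, x$upper))
  cat(sprintf("  clamped: %d low, %d high (%.2f%% of %d trials)%s\n",
              x$n_clamped_low, x$n_clamped_high, x$pct_clamped, x$n_trials,
              if (x$degenerate) " [degenerate: passed through]" else ""))
  invisible(x)
}

# shared grouping: per ordered (target, distractor) cell aggregation
cell_aggregate <- function(trials, styles, value, fun) {
  styles <- as_style_set(styles)
  check_styles_known(trials$target_style, styles, "target style")
  check_styles_known(trials$distractor_style, styles, "distractor style")
  n <- length(styles)
  out <- matrix(NA_real_, n, n)
  ti <- match(trials$target_style, styles)
  di <- match(trials$distractor_style, styles)
  idx <- (di - 1L) * n + ti
  agg <- tapply(value, idx, fun)
  out[as.integer(names(agg))] <- agg
  out
}

#' Accuracy matrix over style pairs
#'
#' Cell (t, d) is the fraction of trials with target style t among
#' distractors of style d in which the chosen location equals the target
#' location. Values are proportions in `[0, 1]`; render as percent only
#' for display. The diagonal is undefined (`NA`); ordered pairs without
#' trials are `NA` (missing).
#'
#' @param trials trial records with `target_style`, `distractor_style`,
#'   `target_location`, `response_location`.
#' @param styles style roster.
#' @return a `pair_matrix` with statistic `"accuracy"`.
#' @export
accuracy_matrix <- function(trials, styles) {
  correct <- as.numeric(trials$response_location == trials$target_location)
  pair_matrix(cell_aggregate(trials, styles, correct, mean),
              styles, "accuracy")
}

#' Mean reaction-time matrix over style pairs
#'
#' Cell (t, d) is the mean reaction time in seconds over the qualifying
#' trials of the ordered pair. By default all retained trials enter
#' (correct and incorrect); `correct_only = TRUE` restricts to correct
#' trials.
#'
#' @param trials trial records.
#' @param styles style roster.
#' @param correct_only use only correct trials (default `FALSE`).
#' @return a `pair_matrix` with statistic `"mean_rt"` (seconds); empty
#'   cells are `NA`.
#' @export
rt_matrix <- function(trials, styles, correct_only = FALSE) {
  if (correct_only) {
    trials <- trials[trials$response_location == trials$target_location, ,
                     drop = FALSE]
  }
  pair_matrix(cell_aggregate(trials, styles, trials$rt, mean),
              styles, "mean_rt")
}

#' Effective reaction time: RT penalized by accuracy
#'
#' The joint performance measure: cell-wise quotient of mean reaction time
#' by accuracy. Long RTs paired with low accuracy are penalized upward,
#' while RTs at accuracy 1 are left unchanged. Zero-accuracy cells map to
#' `Inf` (a pair never discriminated: maximally similar; its downstream
#' distance is 0).
#'
#' @param rt `pair_matrix` of mean RTs (seconds).
#' @param acc `pair_matrix` of accuracies in `[0, 1]`.
#' @return a `pair_matrix` with statistic `"effective_rt"`.
#' @export
effective_rt <- function(rt, acc) {
  check_same_roster(rt, acc)
  a <- pm_values(acc)
  r <- pm_values(rt)
  if (any(a < 0 | a > 1, na.rm = TRUE)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  eff <- r / a
  eff[!is.na(a) & a == 0 & !is.na(r)] <- Inf
  pair_matrix(eff, rownames(r), "effective_rt")
}

#' Symmetric style distances from effective reaction times
#'
#' Cell-wise inverse of the effective-RT matrix (the inverse of `Inf` is
#' 0), symmetrized as the arithmetic mean of the two ordered cells, with
#' zero diagonal. Larger effective RT (harder discrimination) yields
#' smaller distance (more similar styles).
#'
#' @param eff `pair_matrix` of effective RTs (positive or `Inf`).
#' @return a symmetric `pair_matrix` with statistic `"distance"` and zero
#'   diagonal; `NA` cells propagate as `NA`.
#' @export
distance_from_effective_rt <- function(eff) {
  e <- pm_values(eff)
  off <- row(e) != col(e)
  if (any(e[off] <= 0, na.rm = TRUE)) {
    stop("effective RTs must be positive", call. = FALSE)
  }
  inv <- 1 / e
  inv[is.infinite(e)] <- 0
  d <- (inv + t(inv)) / 2
  diag(d) <- 0
  pair_matrix(d, rownames(e), "distance")
}

#' Directional asymmetries of effective reaction time
#'
#' Cell (i, j) is `eff(i as target, j as distractor) - eff(j as target,
#' i as distractor)`; the matrix is antisymmetric. A strict hierarchical
#' relation edge is emitted from the style with the larger target-role
#' effective RT toward the smaller whenever the asymmetry magnitude
#' exceeds `threshold` (default 0: sign only).
#'
#' @param eff `pair_matrix` of effective RTs.
#' @param threshold nonnegative asymmetry magnitude below which no edge is
#'   drawn.
#' @return a list with `matrix` (antisymmetric `pair_matrix`,
#'   statistic `"asymmetry"`) and `edges` (data.frame `from`, `to`,
#'   `asymmetry`, one row per unordered pair with an edge).
#' @export
asymmetry_matrix <- function(eff, threshold = 0) {
  check_pos(threshold + 1e-300, "threshold")  # nonnegative
  e <- pm_values(eff)
  a <- e - t(e)
  pm <- pair_matrix(a, rownames(e), "asymmetry")
  labs <- rownames(e)
  n <- length(labs)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      v <- a[i, j]
      if (!is.na(v) && abs(v) > threshold) {
        from <- if (v > 0) labs[i] else labs[j]
        to <- if (v > 0) labs[j] else labs[i]
        rows[[length(rows) + 1]] <- data.frame(
          from = from, to = to, asymmetry = abs(v),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(),
               asymmetry = numeric(), stringsAsFactors = FALSE)
  list(matrix = pm, edges = edges)
}

#' Full singleton-search analysis pipeline
#'
#' Runs the Experiment-1-style analysis end to end: fast-guess exclusion,
#' then winsorization of the retained RTs, accuracy and mean-RT matrices,
#' effective RT, inverse-distance conversion, asymmetry relations, and
#' average-linkage clustering of the symmetrized distances. Missing cells
#' (ordered pairs without trials) abort clustering with an error naming
#' the pair.
#'
#' @param trials trial records (see [read_trials()] or
#'   [simulate_search_trials()]).
#' @param styles style roster.
#' @param config a [run_config()]; the fields `fast_guess_threshold`,
#'   `winsorize_k`, `rt_correct_only`, `linkage`, `asymmetry_threshold`
#'   are honored.
#' @return a list with `trials` (cleaned), `n_fast_guesses`,
#'   `winsorize` (report), `accuracy`, `rt`, `effective_rt`, `distance`,
#'   `asymmetry` (list of matrix + edges), `tree` (a `linkage_tree`), and
#'   `config`.
#' @export
search_pipeline <- function(trials, styles = style_set(),
                            config = run_config(styles = styles)) {
  styles <- as_style_set(styles)
  fg <- exclude_fast_guesses(trials, config$fast_guess_threshold)
  wz <- winsorize_rts(fg$trials, config$winsorize_k)
  clean <- wz$trials
  acc <- accuracy_matrix(clean, styles)
  rt <- rt_matrix(clean, styles, correct_only = config$rt_correct_only)
  eff <- effective_rt(rt, acc)
  dist <- distance_from_effective_rt(eff)
  asym <- asymmetry_matrix(eff, config$asymmetry_threshold)
  d <- pm_values(dist)
  miss <- which(is.na(d) & row(d) != col(d), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf(
      "no trials for ordered pair (%s, %s); cannot cluster",
      rownames(d)[miss[1, 1]], colnames(d)[miss[1, 2]]), call. = FALSE)
  }
  tree <- average_linkage(d, method = config$linkage)
  list(trials = clean, n_fast_guesses = fg$n_excluded,
       winsorize = wz$report, accuracy = acc, rt = rt,
       effective_rt = eff, distance = dist, asymmetry = asym,
       tree = tree, config = config)
}
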