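#' Run configuration
#'
#' Bundles every analysis parameter with the defaults of the reference
#' experiments: a 1280 x 1024 px screen, an 824 px square image, a 10 x 10
#' heatmap grid, a 150 ms fast-guess threshold and +/-3.5 SD
#' winsorization. All values are echoed into run manifests.
#'
#' @param styles style roster.
#' @param screen_px screen size `c(width, height)` in px.
#' @param image_px square image side length in px.
#' @param grid_size heatmap cells per side.
#' @param fast_guess_threshold seconds; trials faster than this are
#'   excluded.
#' @param winsorize_k SD multiplier for winsorization.
#' @param rt_correct_only restrict RT matrices to correct trials.
#' @param cor_to_distance correlation-to-distance rule (see
#'   [correlation_distance()]).
#' @param linkage `"unweighted"` (UPGMA) or `"weighted"` (WPGMA).
#' @param asymmetry_threshold minimum asymmetry magnitude for an edge.
#' @param seed master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(styles = style_set(),
                       screen_px = c(1280, 1024),
                       image_px = 824,
                       grid_size = 10,
                       fast_guess_threshold = 0.150,
                       winsorize_k = 3.5,
                       rt_correct_only = FALSE,
                       cor_to_distance = "one_minus_r",
                       linkage = "unweighted",
                       asymmetry_threshold = 0,
                       seed = 1L) {
  structure(list(
    styles = as_style_set(styles),
    screen_px = as.numeric(screen_px),
    image_px = check_pos(image_px, "image_px"),
    grid_size = check_count(grid_size, "grid_size", min = 2),
    fast_guess_threshold = check_pos(fast_guess_threshold,
                                     "fast_guess_threshold"),
    winsorize_k = check_pos(winsorize_k, "winsorize_k"),
    rt_correct_only = isTRUE(rt_correct_only),
    cor_to_distance = match.arg(cor_to_distance,
                                c("one_minus_r", "sqrt_one_minus_r")),
    linkage = match.arg(linkage, c("unweighted", "weighted")),
    asymmetry_threshold = check_pos(asymmetry_threshold + 1e-300,
                                    "asymmetry_threshold") - 1e-300,
    seed = check_count(seed, "seed", min = 0)),
    class = "run_config")
}

TRIAL_COLUMNS <- c("subject", "block", "target_style", "distractor_style",
                   "target_location", "response_location", "rt_s")
FIXATION_COLUMNS <- c("subject", "motif", "style", "x_px", "y_px")

#' Read singleton-search trial logs
#'
#' Comma-delimited text with header columns `subject, block, target_style,
#' distractor_style, target_location, response_location, rt_s` (an
#' optional `motif` column is kept). Malformed rows (non-numeric or
#' nonpositive RT, missing fields) are rejected with their line numbers.
#'
#' @param path file path.
#' @return a data.frame of trial records (`rt` in seconds).
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("trial log ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L          # +1 for the header line
  rt <- suppressWarnings(as.numeric(raw$rt_s))
  bad <- is.na(rt) | rt <= 0
  blank <- Reduce(`|`, lapply(raw[TRIAL_COLUMNS],
                              function(v) is.na(v) | v == ""))
  if (any(bad | blank)) {
    stop("malformed trial row(s) at line(s): ",
         paste(utils::head(line[bad | blank], 10), collapse = ", "),
         " (non-numeric/nonpositive rt_s or empty field)", call. = FALSE)
  }
  block <- suppressWarnings(as.integer(raw$block))
  if (any(is.na(block))) {
    stop("non-integer block at line(s): ",
         paste(utils::head(line[is.na(block)], 10), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    subject = raw$subject, block = block,
    target_style = raw$target_style,
    distractor_style = raw$distractor_style,
    target_location = raw$target_location,
    response_location = raw$response_location,
    rt = rt, stringsAsFactors = FALSE)
  if ("motif" %in% names(raw)) out$motif <- raw$motif
  out
}

#' Write singleton-search trial logs
#'
#' @param trials data.frame of trial records (internal `rt` column in
#'   seconds; written as `rt_s`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(
    subject = trials$subject, block = trials$block,
    target_style = trials$target_style,
    distractor_style = trials$distractor_style,
    target_location = trials$target_location,
    response_location = trials$response_location,
    rt_s = trials$rt, stringsAsFactors = FALSE)
  if ("motif" %in% names(trials)) out$motif <- trials$motif
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fixation logs
#'
#' Comma-delimited text with header columns `subject, motif, style, x_px,
#' y_px` and optional `duration_ms`. Malformed rows are rejected with
#' their line numbers. Coordinates are screen pixels, origin top-left.
#'
#' @param path file path.
#' @param screen_px optional screen size; when given, fixations outside
#'   `[0, width) x [0, height)` are rejected with line numbers.
#' @return a data.frame of fixation records (`x`, `y` in px).
#' @export
read_fixations <- function(path, screen_px = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  missing <- setdiff(FIXATION_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("fixation log ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L
  x <- suppressWarnings(as.numeric(raw$x_px))
  y <- suppressWarnings(as.numeric(raw$y_px))
  blank <- Reduce(`|`, lapply(raw[FIXATION_COLUMNS],
                              function(v) is.na(v) | v == ""))
  bad <- is.na(x) | is.na(y) | blank
  if (!is.null(screen_px)) {
    bad <- bad | x < 0 | x >= screen_px[1] | y < 0 | y >= screen_px[2]
  }
  if (any(bad)) {
    stop("malformed fixation row(s) at line(s): ",
         paste(utils::head(line[bad], 10), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(subject = raw$subject, motif = raw$motif,
                    style = raw$style, x = x, y = y,
                    stringsAsFactors = FALSE)
  if ("duration_ms" %in% names(raw)) {
    out$duration_ms <- suppressWarnings(as.numeric(raw$duration_ms))
  }
  out
}

#' Write fixation logs
#'
#' @param fixations data.frame of fixation records (`x`, `y` in px).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  out <- data.frame(subject = fixations$subject, motif = fixations$motif,
                    style = fixations$style, x_px = fixations$x,
                    y_px = fixations$y, stringsAsFactors = FALSE)
  if ("duration_ms" %in% names(fixations)) {
    out$duration_ms <- fixations$duration_ms
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pair matrix as delimited text
#'
#' Rows are target styles, columns distractor styles; the first column
#' holds the row labels.
#'
#' @param pm a `pair_matrix` (or plain labelled matrix).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(pm, path) {
  m <- as.data.frame(unclass(pm))
  utils::write.csv(cbind(style = rownames(pm), m), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pair matrix written by [write_pair_matrix()]
#'
#' @param path file path.
#' @param statistic statistic tag for the reconstructed matrix.
#' @return a `pair_matrix`.
#' @export
read_pair_matrix <- function(path, statistic = "distance") {
  raw <- utils::read.csv(path, check.names = FALSE)
  labs <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- labs
  if (!identical(colnames(m), labs)) {
    stop("pair matrix row and column labels disagree in ", path,
         call. = FALSE)
  }
  pair_matrix(m, labs, statistic)
}

#' Write a heatmap grid with a metadata header
#'
#' The grid is written as comma-delimited rows preceded by `#`-prefixed
#' metadata lines (motif, style, state, n_fixations, cell_px).
#'
#' @param h a `heatmap_grid`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# motif: %s", attr(h, "motif")), con)
  writeLines(sprintf("# style: %s", attr(h, "style")), con)
  writeLines(sprintf("# state: %s", attr(h, "state")), con)
  writeLines(sprintf("# n_fixations: %d", attr(h, "n_fixations")), con)
  writeLines(sprintf("# cell_px: %g", attr(h, "cell_px")), con)
  utils::write.table(unclass(h), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
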