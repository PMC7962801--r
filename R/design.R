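#' Singleton-search trial schedule
#'
#' Builds a subject-agnostic schedule of singleton-search trials: within
#' each block every ordered style pair (target, distractor), target !=
#' distractor, appears exactly once, in seed-randomized order; each trial
#' is assigned a distinct motif from a motif pool so that no motif repeats
#' within a subject's session. With the default eight-style roster a block
#' has 56 trials and four blocks give 224 trials.
#'
#' @param styles style roster.
#' @param blocks number of blocks (default 4).
#' @param motif_pool number of available motifs; must be at least
#'   `blocks * n_styles * (n_styles - 1)`. Defaults to exactly that count.
#' @param seed integer seed for pair order and motif assignment.
#' @return a data.frame with columns `block`, `trial` (within block),
#'   `target_style`, `distractor_style`, `motif`.
#' @examples
#' d <- make_search_design(style_set(), blocks = 1, seed = 1)
#' nrow(d)  # 56
#' @export
make_search_design <- function(styles = style_set(), blocks = 4,
                               motif_pool = NULL, seed = 1L) {
  styles <- as_style_set(styles)
  blocks <- check_count(blocks, "blocks")
  n <- length(styles)
  pairs <- expand.grid(target_style = as.character(styles),
                       distractor_style = as.character(styles),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$target_style != pairs$distractor_style, ]
  n_pairs <- nrow(pairs)                       # n * (n - 1)
  needed <- blocks * n_pairs
  if (is.null(motif_pool)) motif_pool <- needed
  motif_pool <- check_count(motif_pool, "motif_pool")
  if (motif_pool < needed) {
    stop(sprintf(
      "motif pool too small: %d motifs available but %d blocks x %d ordered pairs = %d required",
      motif_pool, blocks, n_pairs, needed), call. = FALSE)
  }
  with_stream_seed(seed, "search_design", {
    motifs <- sample.int(motif_pool, needed)
    out <- do.call(rbind, lapply(seq_len(blocks), function(b) {
      ord <- sample.int(n_pairs)
      data.frame(block = b, trial = seq_len(n_pairs),
                 target_style = pairs$target_style[ord],
                 distractor_style = pairs$distractor_style[ord],
                 stringsAsFactors = FALSE)
    }))
    out$motif <- sprintf("m%05d", motifs)
    rownames(out) <- NULL
    out
  })
}

#' Free-viewing stimulus schedule
#'
#' Builds per-subject viewing schedules for the gaze experiment: there are
#' `n_styles * motifs_per_style` motifs; each subject sees every motif
#' exactly once, in exactly one style, with `motifs_per_style` motifs per
#' style; each consecutive block of `n_styles` trials contains one stimulus
#' of each style. Style-to-motif assignment rotates across subjects (a
#' balanced Latin-square-like rotation) so that with a multiple of
#' `n_styles` subjects every (motif, style) combination is viewed by an
#' equal-sized subgroup, and no subject sees a motif in two styles.
#'
#' @param styles style roster.
#' @param motifs_per_style motifs per style per subject (default 30; with 8
#'   styles this gives the 240-stimulus session).
#' @param n_subjects number of subjects to schedule.
#' @param seed integer seed; drives the motif relabeling and all orderings.
#' @return a data.frame with columns `subject`, `block`, `trial` (overall
#'   position in the session), `motif`, `style`.
#' @export
make_gaze_design <- function(styles = style_set(), motifs_per_style = 30,
                             n_subjects = 1, seed = 1L) {
  styles <- as_style_set(styles)
  motifs_per_style <- check_count(motifs_per_style, "motifs_per_style")
  n_subjects <- check_count(n_subjects, "n_subjects")
  s <- length(styles)
  n_motifs <- s * motifs_per_style
  with_stream_seed(seed, "gaze_design", {
    # global random motif order shared by all subjects keeps the rotation
    # balanced while decoupling motif identity from the rotation index
    motif_ids <- sprintf("m%04d", sample.int(n_motifs))
    out <- vector("list", n_subjects)
    for (subj in seq_len(n_subjects)) {
      # rotation: motif at position j gets style (j + subj) mod s
      style_idx <- ((seq_len(n_motifs) - 1L + subj) %% s) + 1L
      # per-style motif lists in subject-specific random order
      per_style <- lapply(seq_len(s), function(k) {
        sample(motif_ids[style_idx == k])
      })
      rows <- vector("list", motifs_per_style)
      for (b in seq_len(motifs_per_style)) {
        ord <- sample.int(s)               # style order within the block
        rows[[b]] <- data.frame(
          subject = sprintf("s%03d", subj), block = b,
          motif = vapply(ord, function(k) per_style[[k]][b], character(1)),
          style = as.character(styles)[ord], stringsAsFactors = FALSE)
      }
      out[[subj]] <- do.call(rbind, rows)
    }
    out <- do.call(rbind, out)
    out$trial <- stats::ave(seq_len(nrow(out)), out$subject,
                            FUN = seq_along)
    rownames(out) <- NULL
    out[, c("subject", "block", "trial", "motif", "style")]
  })
}
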