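# Shared fixtures, built in code.

# small labelled symmetric distance matrix
dist_matrix <- function(values, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- values
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# random symmetric zero-diagonal distance matrix
random_dist <- function(n, seed) {
  set.seed(seed)
  labels <- LETTERS[seq_len(n)]
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- round(stats::runif(n * (n - 1) / 2, 0.1, 2), 3)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# brute-force UPGMA oracle: recomputes every pairwise cluster average from
# the ORIGINAL leaf distances at each step (independent of the package's
# incremental update), same lexicographic tie-break
upgma_oracle <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        better <- avg < best_d - 1e-12 ||
          (abs(avg - best_d) <= 1e-12 &&
             (key[1] < best_key[1] ||
                (key[1] == best_key[1] && key[2] < best_key[2])))
        if (better) {
          best <- c(a, b); best_d <- avg; best_key <- key
        }
      }
    }
    merges[[length(merges) + 1]] <- list(
      members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
      height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# merge list of a linkage_tree in the oracle's format
tree_merges <- function(tree) {
  labels <- tree$labels
  members <- vector("list", length(labels) - 1)
  lapply(seq_along(tree$height), function(k) {
    grab <- function(node) {
      if (node < 0) labels[-node] else members[[node]]
    }
    members[[k]] <<- c(grab(tree$merge[k, 1]), grab(tree$merge[k, 2]))
    list(members = sort(members[[k]]), height = tree$height[k])
  })
}

# hand-built trial records
make_trials <- function(rt, target = "A", distractor = "B",
                        correct = TRUE) {
  n <- if (length(rt) == 0) 0L else
    max(length(rt), length(target), length(distractor), length(correct))
  data.frame(
    subject = rep_len("s1", n), block = rep_len(1L, n),
    target_style = rep_len(target, n),
    distractor_style = rep_len(distractor, n),
    target_location = rep_len("TL", n),
    response_location = ifelse(rep_len(correct, n), "TL", "TR"),
    rt = rep_len(rt, n), stringsAsFactors = FALSE)
}

# heatmap grid straight from a count matrix (bypasses binning)
counts_heatmap <- function(counts, motif = "m1", style = "A") {
  styletree:::new_heatmap(counts, "raw_counts", motif, style,
                          n_fixations = sum(counts), n_discarded = 0L,
                          cell_px = 82.4)
}

small_taxonomy <- function() {
  planted_taxonomy(reference_taxonomy())
}

# per-pair t statistics of per-image correlations around `center`
pair_t_stats <- function(per_image, center = 0) {
  labs <- rownames(per_image[[1]]$r)
  n <- length(labs)
  stats <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      vals <- vapply(per_image, function(sc) sc$r[i, j], numeric(1))
      vals <- vals[!is.na(vals)]
      se <- stats::sd(vals) / sqrt(length(vals))
      stats <- c(stats, (mean(vals) - center) / se)
    }
  }
  stats
}
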