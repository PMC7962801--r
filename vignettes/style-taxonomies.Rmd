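---
title: "Deriving perceptual style taxonomies from search and gaze behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving perceptual style taxonomies from search and gaze behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(styletree)
```

## The problem

Art-historical accounts order painting styles into family trees: the early
and late phases of Impressionism belong together, Expressionism forms its
own branch, and the post-impressionist individualists — Cézanne, Gauguin,
van Gogh — sit between them. `styletree` asks whether such a taxonomy can
be recovered from *behavior alone*, without expert judgment, using two
classic paradigms of visual psychophysics:

1. **Singleton search.** An observer sees four images of the same motif,
   three rendered in one style (distractors) and one in another (the
   target), and indicates the target's location. Accuracy and reaction
   time (RT) per ordered style pair index how discriminable — and hence
   how dissimilar — the two styles are.
2. **Free viewing with eye tracking.** Observers look at the same motifs
   rendered in different styles while fixations are recorded. If a style
   systematically redirects gaze, the spatial fixation distributions of
   two similar styles should correlate more than those of dissimilar
   ones.

Both pipelines end in an average-linkage dendrogram over the style roster
that can be compared, clade by clade, against a reference taxonomy.

## Experiment-1 pipeline: effective reaction time

Trial records carry the ordered pair (target style, distractor style),
the target and chosen locations, and the RT in seconds. Processing order:

1. **Fast-guess exclusion** (`exclude_fast_guesses()`): trials with
   RT < 150 ms are dropped. Such responses precede discrimination
   (typically accidental double-presses). Exclusion runs *first*, before
   any moment estimation, so that artifacts do not contaminate the
   winsorization moments — the ordering is the package's choice, made
   because both cleanups are described jointly upstream of the analysis.
2. **Winsorization** (`winsorize_rts()`): RTs deviating more than
   k = 3.5 SDs from the mean are projected onto mean ± 3.5 SD. Mean and
   SD are computed once, globally over all retained trials of the
   dataset (not per subject or per cell — the simplest reading, reported
   transparently in the run manifest). Re-projection with the original
   moments is a fixed point, and no output deviates from the original
   mean by more than 3.5 original SDs.
3. **Accuracy matrix** (`accuracy_matrix()`): cell (t, d) is the fraction
   of correct responses, a proportion in [0, 1]; it is rendered as
   percent only in display. With four response locations chance is 1/4.
4. **RT matrix** (`rt_matrix()`): mean RT in seconds per ordered pair,
   over all retained trials by default (correct and incorrect both carry
   information; a `correct_only` flag restricts it).
5. **Effective RT** (`effective_rt()`): the cell-wise quotient RT /
   accuracy. It penalizes slow *and* inaccurate discriminations while
   leaving accuracy-1 cells unchanged. An accuracy-0 cell maps to `Inf`:
   a pair never discriminated is maximally similar, and the continuous
   limit of the quotient keeps it defined.
6. **Distances** (`distance_from_effective_rt()`): cell-wise inverse
   (1/`Inf` = 0), then symmetrized as the arithmetic mean of the two
   ordered cells, zero diagonal. The symmetrization rule is the
   package's choice of reduction (some reduction is required, since
   clustering needs one distance per unordered pair).
7. **Asymmetries** (`asymmetry_matrix()`): the antisymmetric matrix
   eff(i→j) − eff(j→i); an edge is drawn from the style with the larger
   target-role effective RT toward the smaller when the magnitude
   exceeds a configurable threshold (default 0, sign only).
8. **Clustering** (`average_linkage()`), described below.

`search_pipeline()` chains all steps and returns every intermediate plus
a report of excluded and clamped counts. Ordered pairs with no trials
abort clustering with an error naming the pair, rather than imputing.

## Experiment-2 pipeline: fixation heatmap correlation

Fixation records carry subject, motif, style and screen coordinates
(origin top-left, x rightward, y downward — the usual eye-tracker
convention). The stimulus is an 824 px square image centered on a
1280 × 1024 screen; both are configuration, not constants.

1. **Binning** (`bin_fixations()`): fixations of one (motif, style) map
   into a 10 × 10 grid over the image (82.4 px cells at the default
   geometry). Cells are half-open with the last row/column closed, so
   boundary fixations at the far image edge are kept. Fixations outside
   the image rectangle are *discarded and counted*, not clipped — real
   free-viewing data contain off-stimulus fixations, and clipping would
   inflate edge cells.
2. **Normalization** (`normalize_heatmap()`): counts divide by their
   total so every map has unit mass regardless of how many observers saw
   that stimulus. Zero-fixation maps are undefined and are excluded from
   correlation with bookkeeping (never imputed as r = 0).
3. **Grand bias** (`grand_bias()`, `subtract_bias()`): the unweighted
   mean of all normalized maps — dominated by the central fixation
   bias — is subtracted from each map, leaving signed fields that sum to
   0. Unweighted means treat every map equally regardless of its
   fixation count.
4. **Per-image correlation** (`correlate_styles_for_image()`): the
   bias-subtracted maps of one motif are flattened row-major into
   100-vectors; pairwise Pearson r and two-sided p-values are computed.
   p-values are reported per image but never meta-combined; the
   dataset-level matrix averages r only.
5. **Averaging** (`average_correlations()`): cell-wise mean of r over
   the images where the cell is defined, with per-cell counts.
6. **Distance and clustering**: d = 1 − r (the standard monotone
   conversion; `sqrt((1-r)/2)` available), then average linkage.
   `accumulate_style_heatmaps()` additionally averages each style's
   normalized maps and subtracts the bias, exposing style-level spatial
   signatures that survive even when per-image correlations average out.

A state machine on `heatmap_grid` objects (`raw_counts` → `normalized` →
`bias_subtracted`) enforces this order: normalizing twice, or correlating
maps that still contain the center bias, is an error, not a silent
mistake.

One subtlety deserves emphasis. Because every style shows the *same
motifs*, the motif's content field is common to all styles of an image;
grand-bias subtraction removes only the dataset-average map, so the
motif-specific content residual correlates **every** style pair
positively even when styles have no effect on gaze at all. The correct
null expectation under "no style signal" is therefore not r ≈ 0 but a
*uniform* correlation matrix — indistinguishable pair means and collapsed
dendrogram heights. The test suite asserts exactly that, and r ≈ 0 only
in the fully content-free (center bias + sampling noise) condition.

## Average linkage, tree comparison, newick

`average_linkage()` implements unweighted average linkage (UPGMA): at
each step the two clusters with the smallest mean inter-cluster leaf
distance merge at that mean, which guarantees nondecreasing heights and
an ultrametric tree. Ties are broken by the lexicographically smallest
pair of cluster representative labels (a cluster is represented by its
alphabetically first leaf) — determinism that generic library
implementations do not specify, and that the test suite verifies against
a brute-force oracle recomputing every cluster average from the original
leaf distances at each step. A weighted (WPGMA) variant sits behind the
`linkage` configuration flag.

`cophenetic_matrix()` reads pairwise merge heights off the tree;
`compare_trees()` reports (i) the **rooted clade symmetric difference**
(the number of internal-node leaf sets present in exactly one tree,
excluding the root) and (ii) the Pearson correlation between cophenetic
upper triangles. Clades rather than unrooted bipartitions are compared
because dendrograms are rooted objects: on four leaves, the caterpillar
(((A,B),C),D) and the balanced ((A,B),(C,D)) collapse to the same single
unrooted split yet are distinct clusterings; the clade distance
separates them. Only the topology distance is invariant to monotone
height rescaling.

Trees are exchanged as newick with branch lengths equal to merge-height
differences, so the leaf-to-root path equals the root height;
`from_newick()` inverts the encoding through cophenetic distances and
requires ultrametric input. The shipped reference taxonomy
(`reference_taxonomy()`) transcribes the qualitative art-historical
relations — (EI,LI) and (EE,LE) clades, a ((C,G),VG) post-impressionist
group, Photography as outgroup — with *synthetic* merge heights (the
source relations are qualitative), so only topology comparisons against
it are meaningful; its file is named `reference_taxonomy_synthetic.nwk`
to make that explicit.

## The synthetic data generator

No behavioral dataset ships with the package; instead, a generator
plants a known taxonomy and simulates both experiments so that each
pipeline's ability to recover it is testable end to end.

**Designs.** `make_search_design()` schedules every ordered style pair
exactly once per block (56 trials per block, 224 over four blocks for
eight styles), with seed-randomized pair order and motif assignment
without repetition within a subject. `make_gaze_design()` schedules
30 motifs per style per subject (240 stimuli), each motif in exactly one
style per subject, one stimulus of each style per consecutive block, and
rotates the style↔motif assignment across subjects so that with a
multiple of eight subjects every (motif, style) combination is viewed by
an equal subgroup — with 64 subjects, 8 viewers per stimulus and ~128
fixations per image at 16 per viewer.

**Search behavior** (`search_behavior_model()`): accuracy follows
p(D) = c + (1−c)(1−e^(−λD)) with chance c = 0.25 and planted distance
D ∈ [0,1] — the simplest monotone psychometric family with a closed
form — and RT is lognormal with location μ₀ − βD, so harder (more
similar) pairs are slower, coupling accuracy and RT the way the human
data do. Defaults (λ = 2, μ₀ = log 2, β = 0.8, σ = 0.5, 2% fast
guesses, 1% Pareto-inflated lapses) put mean correct RT near 2.2 s and
overall accuracy near 75%, the scale of the human sessions. Fast
guesses draw RT uniformly on [0.05, 0.15) s — exactly the excluded
band, so the exclusion rule's effect is observable — and respond
uniformly over the four locations. Inter-subject RT heterogeneity is
deliberately not modeled: it would only inflate the global SD without
changing any pairwise contrast the pipeline measures.

**Gaze behavior** (`gaze_behavior_model()`): the fixation density of a
stimulus is a convex mixture of a motif content field, a style field and
a central Gaussian bias (defaults 0.5 / 0.15 / 0.35 — content and
center dominate, matching the observation that content outweighs style
in free viewing). Style fields are smooth Gaussian fields accumulated
along the planted tree's branches, each branch contribution scaled by
√(branch length / scale), so the expected correlation between two
styles' fields is exactly 1 − D. A `style_field_stability` parameter
(default 0.3) splits the style field into a component shared across all
motifs and a component redrawn per motif: the shared part makes
accumulated per-style heatmaps distinct, while the per-motif part lets
the 240-image average correlation converge to its expectation (a single
global field per style would leave an irreducible ±0.12 realization
error at the 10 × 10 grid's ~100 degrees of freedom, scrambling rank
recovery no matter how many images are averaged). Fixation counts are
Poisson(16) per subject and image; positions are i.i.d. from the mixed
density (cell by mass, uniform within the cell), always inside the
image rectangle.

All randomness flows from one master seed through labeled streams
(design / trials / fields / fixations), so stages can be re-run
independently and identical seeds give bit-identical outputs.

**What the generator does not emulate.** Saccade dynamics, fixation
durations, oculomotor main-sequence constraints, salience driven by
actual image content, inter-subject strategy differences, and learning
across blocks. Passing recovery tests therefore show that the pipelines
are *correct and sensitive under the assumed statistical structure* —
monotone psychometrics, tree-structured gaze similarity — not that real
observers satisfy those assumptions.

## Numerical choices and degenerate inputs

- Winsorization with fewer than two trials or zero SD passes data
  through with a flagged warning instead of failing.
- Accuracy-0 cells → `Inf` effective RT → distance contribution 0.
- Missing matrix cells propagate as `NA` and block clustering with an
  error naming the offending pair.
- Normalized maps sum to 1 and bias-subtracted maps to 0 within 1e−9
  (asserted dataset-wide in the tests).
- Zero-variance heatmap vectors make the Pearson r undefined (`NA` +
  warning), never silently 0.
- Linkage tolerates asymmetry only to 1e−8 and treats height ties within
  1e−12 as exact for tie-breaking.

## Problem sizes used by the test and acceptance runs

Recovery checks run 20 replicates of 5 subjects × 100 blocks (500 trials
per ordered pair) for the search pipeline, and one 64-subject ×
240-image session for the gaze pipeline (strong style weight 0.8 for
the recovery condition); the linkage oracle comparison covers 100 random
matrices of 3–7 leaves; chance calibration uses 8 ordered-pair cells at
10⁵ trials each. These sizes make every Monte-Carlo bound (3 binomial
SEs, rank thresholds) comfortably decidable while the whole suite runs
in well under a minute.

## Known limitations

- The reference taxonomy's heights are synthetic; cophenetic correlation
  against it is reported but has no quantitative meaning beyond rank.
- The effective-RT statistic has no error model; no confidence intervals
  accompany the distance matrix (the replicate spread in the acceptance
  run is the honest summary of its variability).
- Per-image maps pool fixations across the subjects who saw that
  stimulus before normalization; a per-subject-average variant is a
  documented extension point rather than a flag, since the pooled
  variant is the only one the downstream statistics need.
- The CLI reads plain delimited text; converters from proprietary
  eye-tracker exports are out of scope (an extension point, not a
  dependency).
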