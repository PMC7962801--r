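test_that("search design covers every ordered pair once per block", {
  for (n in 2:8) {
    styles <- style_set(LETTERS[seq_len(n)])
    d <- make_search_design(styles, blocks = 2, seed = n)
    expect_equal(nrow(d), 2 * n * (n - 1))
    for (b in 1:2) {
      blk <- d[d$block == b, ]
      key <- paste(blk$target_style, blk$distractor_style)
      expect_equal(sort(key),
                   sort(paste(rep(styles, each = n - 1),
                              unlist(lapply(seq_len(n), function(i)
                                styles[-i])))))
    }
    expect_false(anyDuplicated(d$motif) > 0)   # no motif repeats
    expect_true(all(d$target_style != d$distractor_style))
  }
})

test_that("eight-style design arithmetic matches the session layout", {
  d1 <- make_search_design(style_set(), blocks = 1, seed = 1)
  expect_equal(nrow(d1), 56)
  d4 <- make_search_design(style_set(), blocks = 4, seed = 1)
  expect_equal(nrow(d4), 224)
})

test_that("too small a motif pool fails with the required count", {
  expect_error(
    make_search_design(style_set(), blocks = 4, motif_pool = 200),
    "200 motifs available.*224 required")
})

test_that("gaze design: one motif per style slot, block structure, rotation", {
  styles <- style_set()
  d <- make_gaze_design(styles, motifs_per_style = 30, n_subjects = 2,
                        seed = 4)
  for (s in unique(d$subject)) {
    ds <- d[d$subject == s, ]
    expect_equal(nrow(ds), 240)
    expect_false(anyDuplicated(ds$motif) > 0)
    expect_equal(unname(table(ds$style)), rep(30, 8), ignore_attr = TRUE)
    # every consecutive block of 8 trials holds one stimulus of each style
    for (b in unique(ds$block)) {
      expect_setequal(ds$style[ds$block == b], as.character(styles))
    }
  }
  # no subject sees a motif twice, but style assignment rotates across
  # subjects: the same motif appears in different styles
  wide <- merge(d[d$subject == "s001", c("motif", "style")],
                d[d$subject == "s002", c("motif", "style")], by = "motif")
  expect_true(all(wide$style.x != wide$style.y))

  tiny <- make_gaze_design(style_set(), motifs_per_style = 1, seed = 9)
  expect_equal(nrow(tiny), 8)
  expect_setequal(tiny$style, as.character(style_set()))
})

test_that("designs are bit-identical under the same seed, differ across seeds", {
  expect_identical(make_search_design(seed = 5), make_search_design(seed = 5))
  expect_false(identical(make_search_design(seed = 5),
                         make_search_design(seed = 6)))
  expect_identical(make_gaze_design(n_subjects = 2, seed = 5),
                   make_gaze_design(n_subjects = 2, seed = 5))
  expect_false(identical(make_gaze_design(seed = 5),
                         make_gaze_design(seed = 6)))
})

test_that("p_correct matches its closed form in simulation", {
  # lambda = 2, D = 0.8, chance 0.25 -> p = 0.25 + 0.75 * (1 - e^-1.6)
  styles <- style_set(c("A", "B"))
  d <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
              dimnames = list(styles, styles))
  tax <- planted_taxonomy(average_linkage(d), distance_scale = 1)
  model <- search_behavior_model(discrimination_gain = 2,
                                 fast_guess_rate = 0, outlier_rate = 0,
                                 seed = 11)
  design <- make_search_design(styles, blocks = 50000, seed = 11)
  trials <- simulate_search_trials(design, tax, model)
  p_true <- 0.25 + 0.75 * (1 - exp(-1.6))
  expect_equal(p_correct(model, 0.8), p_true)
  p_hat <- mean(trials$response_location == trials$target_location)
  se <- sqrt(p_true * (1 - p_true) / nrow(trials))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("simulated mean RTs track the closed-form lognormal mean", {
  styles <- style_set(c("A", "B"))
  d <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(styles, styles))
  tax <- planted_taxonomy(average_linkage(d), distance_scale = 1)
  model <- search_behavior_model(fast_guess_rate = 0, outlier_rate = 0,
                                 seed = 21)
  trials <- simulate_search_trials(
    make_search_design(styles, blocks = 20000, seed = 21), tax, model)
  mu <- model$rt_location - model$rt_similarity_slope * 0.5
  m_true <- exp(mu + model$rt_sigma^2 / 2)
  sd_true <- sqrt((exp(model$rt_sigma^2) - 1)) * m_true
  m_hat <- mean(trials$rt)
  expect_lt(abs(m_hat - m_true), 3 * sd_true / sqrt(nrow(trials)))
})

test_that("without fast guesses no RT sits in the fast-guess band", {
  tax <- planted_star()
  model <- search_behavior_model(fast_guess_rate = 0, seed = 3)
  trials <- simulate_search_trials(
    make_search_design(blocks = 2, seed = 3), tax, model)
  expect_true(all(trials$rt > 0))
  # lognormal with mu ~ log(2): mass below 0.15 s is ~pnorm(-5), absent
  # at this n
  expect_gte(min(trials$rt), 0.15)

  eps <- search_behavior_model(fast_guess_rate = 1, seed = 3)
  fast <- simulate_search_trials(make_search_design(blocks = 2, seed = 3),
                                 tax, eps)
  expect_true(all(fast$rt >= 0.05 & fast$rt < 0.15))
})

test_that("accuracy rises and RT falls with planted distance", {
  tax <- planted_taxonomy(reference_taxonomy())
  model <- search_behavior_model(fast_guess_rate = 0, outlier_rate = 0,
                                 seed = 13)
  trials <- simulate_search_trials(
    make_search_design(blocks = 200, seed = 13), tax, model)
  key <- paste(trials$target_style, trials$distractor_style)
  acc <- tapply(trials$response_location == trials$target_location, key,
                mean)
  rt <- tapply(trials$rt, key, mean)
  dvals <- tapply(planted_distance(tax, trials$target_style,
                                   trials$distractor_style), key, mean)
  ord <- order(dvals)
  expect_gt(cor(dvals, acc, method = "spearman"), 0.9)
  expect_lt(cor(dvals, rt, method = "spearman"), -0.9)
})

test_that("trial simulation is reproducible and seed-sensitive", {
  tax <- planted_star()
  d <- make_search_design(blocks = 1, seed = 2)
  m1 <- search_behavior_model(seed = 8)
  expect_identical(simulate_search_trials(d, tax, m1),
                   simulate_search_trials(d, tax, m1))
  m2 <- search_behavior_model(seed = 9)
  expect_false(identical(simulate_search_trials(d, tax, m1),
                         simulate_search_trials(d, tax, m2)))
})

test_that("style fields at planted distance zero coincide; correlations follow the tree rule", {
  labs <- c("A", "B", "C")
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(labs, labs))
  tax <- planted_taxonomy(average_linkage(d), distance_scale = 1)
  model <- gaze_behavior_model(seed = 1)
  r_ab <- r_ac <- numeric(200)
  for (i in 1:200) {
    f <- style_fields(tax, model, seed = i)
    r_ab[i] <- cor(as.vector(f$A), as.vector(f$B))
    r_ac[i] <- cor(as.vector(f$A), as.vector(f$C))
  }
  # distance 0: fields identical, correlation maximal (= 1)
  expect_true(all(r_ab > 1 - 1e-9))
  # distance 1: no shared branch; mean correlation ~ 0
  expect_lt(abs(mean(r_ac)), 3 * sd(r_ac) / sqrt(200) + 0.01)
})

test_that("fixations respect geometry, Poisson counts and the center-bias limit", {
  tax <- small_taxonomy()
  model <- gaze_behavior_model(seed = 5)
  design <- make_gaze_design(motifs_per_style = 3, n_subjects = 8,
                             seed = 5)
  fix <- simulate_fixations(design, tax, model)
  expect_true(all(fix$x >= 0 & fix$x < model$screen_px[1]))
  expect_true(all(fix$y >= 0 & fix$y < model$screen_px[2]))
  rect <- image_rect(model$screen_px, model$image_px)
  expect_true(all(fix$x >= rect$x0 & fix$x <= rect$x0 + rect$w))
  expect_true(all(fix$y >= rect$y0 & fix$y <= rect$y0 + rect$h))
  # Poisson(16) per subject-image; the rotation gives each (motif, style)
  # one viewer per 8 subjects, so here ~16 fixations per image
  per_image <- table(paste(fix$motif, fix$style))
  expect_equal(length(per_image), 8 * 3 * 8)
  expect_lt(abs(mean(per_image) - 16),
            4 * sqrt(16 / length(per_image)))

  # pure center bias: the accumulated peak sits in a central cell
  cmodel <- gaze_behavior_model(weight_content = 0, weight_style = 0,
                                weight_center = 1, seed = 5)
  cfix <- simulate_fixations(design, tax, cmodel)
  h <- bin_fixations(cfix, rect, 10)
  peak <- which(unclass(h) == max(h), arr.ind = TRUE)[1, ]
  expect_true(all(peak >= 5 & peak <= 6))
})

test_that("fixation simulation is reproducible and validates styles", {
  tax <- small_taxonomy()
  model <- gaze_behavior_model(seed = 2)
  design <- make_gaze_design(motifs_per_style = 1, n_subjects = 2,
                             seed = 2)
  expect_identical(simulate_fixations(design, tax, model),
                   simulate_fixations(design, tax, model))
  bad <- design
  bad$style[1] <- "nope"
  expect_error(simulate_fixations(bad, tax, model), "unknown style")
})
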