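test_that("similarity maps are Fisher-z Pearson correlations over frequency", {
  f1 <- matrix(c(1, 2, 3, 4,
                 2, 4, 6, 8,
                 1, 0, 1, 0), nrow = 4)
  # self-correlation on the diagonal hits the clip
  m_self <- similarity_map(f1, f1)
  expect_equal(diag(m_self), rep(atanh(1 - 1e-6), 3))
  # perfectly linear vectors give r = 1 (clipped z)
  v1 <- matrix(c(1, 2, 3, 4), 4, 1)
  v2 <- matrix(c(2, 4, 6, 8), 4, 1)
  expect_equal(similarity_map(v1, v2)[1, 1], atanh(1 - 1e-6))
  # hand-computed zero covariance -> z = 0
  a <- matrix(c(1, 0, 1, 0), 4, 1)
  b <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(similarity_map(a, b)[1, 1], 0)
  # zero variance propagates as missing
  const <- matrix(1, 4, 1)
  expect_true(is.na(similarity_map(const, v1)[1, 1]))
  expect_error(similarity_map(v1, matrix(1, 3, 1)), "equal rows")
})

test_that("self-maps are symmetric but cross-event maps need not be", {
  set.seed(22)
  f <- matrix(rnorm(4 * 12), 4, 12)
  g <- matrix(rnorm(4 * 12), 4, 12)
  self <- similarity_map(f, f)
  expect_lt(max(abs(self - t(self))), 1e-12)
  cross <- similarity_map(f, g)
  expect_gt(max(abs(cross - t(cross))), 1e-6)
})

test_that("similarity is invariant to positive affine rescaling", {
  set.seed(21)
  f1 <- matrix(rnorm(4 * 10), 4, 10)
  f2 <- matrix(rnorm(4 * 10), 4, 10)
  base <- similarity_map(f1, f2)
  for (a in c(0.5, 2, 10)) {
    scaled <- similarity_map(a * f1 + 3, f2)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("the RDM set has 8 conditions built within story only", {
  d <- scaled_design(n_stories = 2, reps = 3)
  eff <- latent_effects(alpha = alpha_cell(0.9), gamma = zero_gamma())
  ft <- simulate_features(d, eff, 1, seed = 8, montage = scaled_montage())
  maps <- build_rdm_set(ft)
  expect_equal(dim(maps$z)[2], 8L)
  expect_equal(nrow(maps$conditions), 8L)
  expect_setequal(
    thetalink:::condition_key(maps$conditions),
    c("linked_pre_imagination", "linked_pre_observation",
      "linked_post_imagination", "linked_post_observation",
      "nonlinked_pre_imagination", "nonlinked_pre_observation",
      "nonlinked_post_imagination", "nonlinked_post_observation"))
  expect_equal(dim(maps$z)[4:5], c(41L, 41L))

  # restricting to one phase and one mode leaves 2 conditions
  keep <- ft$trials$phase == "pre" & ft$trials$mode == "imagination"
  ft_small <- ft
  ft_small$values <- ft$values[keep, , , , drop = FALSE]
  ft_small$trials <- ft$trials[keep, ]
  maps_small <- build_rdm_set(ft_small)
  expect_equal(nrow(maps_small$conditions), 2L)

  # a story missing one event errors with its name
  drop <- !(ft$trials$story == 1 & ft$trials$event == "B")
  ft_bad <- ft
  ft_bad$values <- ft$values[drop, , , , drop = FALSE]
  ft_bad$trials <- ft$trials[drop, ]
  expect_error(build_rdm_set(ft_bad), "missing event")
})

test_that("identical A and B features give clipped-diagonal linked maps", {
  d <- scaled_design(n_stories = 2, reps = 3)
  ft <- simulate_features(d, latent_effects(gamma = zero_gamma()), 1,
                          seed = 9, montage = scaled_montage())
  tab <- ft$trials
  for (st in 1:2) for (ph in c("pre", "post")) for (s in unique(tab$subject)) {
    ia <- which(tab$subject == s & tab$story == st & tab$phase == ph &
                  tab$event == "A")
    ib <- which(tab$subject == s & tab$story == st & tab$phase == ph &
                  tab$event == "B")
    ft$values[ib, , , ] <- ft$values[ia, , , ]
  }
  maps <- build_rdm_set(ft)
  li <- match("linked_pre_imagination",
              thetalink:::condition_key(maps$conditions))
  diag_vals <- vapply(1:41, function(t) maps$z[1, li, 1, t, t],
                      numeric(1))
  expect_equal(diag_vals, rep(atanh(1 - 1e-6), 41))
})

test_that("contrast composition is the stated weighted sum", {
  d <- scaled_design(n_stories = 2, reps = 3)
  ft <- simulate_features(d, latent_effects(gamma = zero_gamma()), 1,
                          seed = 10, montage = scaled_montage())
  maps <- build_rdm_set(ft)
  keys <- thetalink:::condition_key(maps$conditions)

  w0 <- stats::setNames(rep(0, 8), keys)
  expect_true(all(compose_contrast(maps, w0)$value == 0))

  # plant known constants and check the difference-of-differences
  maps_c <- maps
  consts <- c(linked_post_imagination = 3, linked_pre_imagination = 1,
              linked_post_observation = 2, linked_pre_observation = 2)
  for (nm in names(consts))
    maps_c$z[, match(nm, keys), , , ] <- consts[[nm]]
  cm <- compose_contrast(maps_c, rsa_contrast_weights("linked_interaction"))
  expect_true(all(abs(cm$value - 2) < 1e-12))

  # post = pre collapses the post-pre contrast to zero
  maps_e <- maps
  for (pair in c("linked", "nonlinked")) for (mode in c("imagination",
                                                        "observation")) {
    pre_i <- match(paste(pair, "pre", mode, sep = "_"), keys)
    post_i <- match(paste(pair, "post", mode, sep = "_"), keys)
    maps_e$z[, post_i, , , ] <- maps_e$z[, pre_i, , , ]
  }
  cm_e <- compose_contrast(maps_e, rsa_contrast_weights("linked_interaction"))
  expect_true(all(abs(cm_e$value) < 1e-12))

  expect_error(compose_contrast(maps, c(linked_pre_imagination = 1)),
               "sum to 0")
  expect_error(compose_contrast(maps, c(bogus_condition = 0)),
               "unknown")
})

test_that("planted integration raises linked post-phase similarity with alpha", {
  d <- scaled_design(n_stories = 2, reps = 3)
  mont <- scaled_montage()
  mean_linked_change <- function(a, seed) {
    eff <- latent_effects(alpha = alpha_cell(a), gamma = zero_gamma(),
                          pattern_snr = 2,
                          pattern_channels = c("FT7", "T7", "TP7"))
    ft <- simulate_features(d, eff, 2, seed = seed, montage = mont)
    maps <- build_rdm_set(ft)
    keys <- thetalink:::condition_key(maps$conditions)
    sham <- which(maps$groups == "sham")
    chan <- match(c("FT7", "T7", "TP7"), mont$label)
    post <- maps$z[sham, match("linked_post_imagination", keys), chan, , ]
    pre <- maps$z[sham, match("linked_pre_imagination", keys), chan, , ]
    mean(post - pre, na.rm = TRUE)
  }
  for (seed in 1:3) {
    deltas <- vapply(c(0, 0.6), mean_linked_change, numeric(1),
                     seed = seed)
    expect_gt(deltas[2], deltas[1])
    # no-integration change is small relative to the planted one
    expect_lt(abs(deltas[1]), deltas[2] / 2)
  }
})
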