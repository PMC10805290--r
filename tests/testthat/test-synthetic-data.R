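test_that("generators are bit-identical under a fixed seed", {
  expect_identical(gen_power_law_features(20, 5, 1, seed = 3),
                   gen_power_law_features(20, 5, 1, seed = 3))
  f <- gen_power_law_features(20, 5, 1, seed = 3)
  expect_identical(gen_neural_responses(f, 4, 3, snr = 1, n_repeats = 2, seed = 5),
                   gen_neural_responses(f, 4, 3, snr = 1, n_repeats = 2, seed = 5))
  expect_identical(gen_category_clouds(3, 4, 2, 6, 1, 1, seed = 7),
                   gen_category_clouds(3, 4, 2, 6, 1, 1, seed = 7))
  expect_identical(gen_feature_maps(2, 3, 2, 2, seed = 9),
                   gen_feature_maps(2, 3, 2, 2, seed = 9))
})

test_that("power-law features realize the target spectrum and ED", {
  # isotropic: ED approaches the channel count
  iso <- gen_power_law_features(3000, 10, alpha = 0, seed = 11)
  expect_equal(effective_dimensionality(compute_eigenspectrum(iso)), 10,
               tolerance = 0.05)

  # steep decay: ED collapses toward 1
  steep <- gen_power_law_features(3000, 10, alpha = 8, seed = 12)
  expect_equal(effective_dimensionality(compute_eigenspectrum(steep)), 1,
               tolerance = 0.05)

  # alpha = 1: estimated ED matches the truncated-sum participation ratio
  f <- gen_power_law_features(5000, 100, alpha = 1, seed = 13)
  target <- sum(1 / (1:100))^2 / sum(1 / (1:100)^2)
  est <- effective_dimensionality(compute_eigenspectrum(f))
  expect_lt(abs(est - target) / target, 0.1)

  expect_error(gen_power_law_features(0, 5, 1), "positive")
  expect_error(gen_power_law_features(10, 5, -1), "nonnegative")
})

test_that("empirical eigenspectrum converges to the generator's target", {
  p <- 20
  f <- gen_power_law_features(50 * p, p, alpha = 1.5, seed = 21)
  spec <- compute_eigenspectrum(f)
  target <- (1:p)^(-1.5)
  rel_err <- abs(spec[1:10] - target[1:10]) / target[1:10]
  expect_lt(max(rel_err), 0.1)
})

test_that("neural responses obey the snr reliability law", {
  f <- gen_power_law_features(300, 12, 0.5, seed = 31)

  # noiseless: repeats identical, reliability exactly 1
  clean <- gen_neural_responses(f, 6, 8, snr = Inf, n_repeats = 3, seed = 32)
  expect_equal(clean$values[, , 1], clean$values[, , 3])
  rel <- split_half_reliability(clean, n_splits = 4, corrected = FALSE, seed = 33)
  expect_equal(unname(rel$per_unit_ceiling), rep(1, 6), tolerance = 1e-12)

  # single repeat: reliability must refuse
  single <- gen_neural_responses(f, 3, 4, snr = 1, n_repeats = 1, seed = 34)
  expect_error(split_half_reliability(single), "at least 2")

  # snr = 1, 2 repeats: mean split-half reliability ~ snr/(snr+1) = 0.5
  big <- gen_power_law_features(2000, 20, 0.5, seed = 35)
  noisy <- gen_neural_responses(big, 40, 10, snr = 1, n_repeats = 2, seed = 36)
  rel2 <- split_half_reliability(noisy, n_splits = 1, corrected = FALSE, seed = 37)
  expect_equal(mean(rel2$per_unit_ceiling), 0.5, tolerance = 0.05)

  expect_error(gen_neural_responses(f, 3, 99, snr = 1), "exceeds")
  expect_error(gen_neural_responses(f, 3, 4, snr = 0), "positive")
})

test_that("full-rank regression on generated responses recovers snr/(snr+1)", {
  f <- gen_power_law_features(2000, 15, 0, seed = 41)
  for (snr in c(0.5, 2)) {
    rec <- gen_neural_responses(f, 20, 15, snr = snr, n_repeats = 1, seed = 42)
    enc <- fit_cv_encoder(f, rec, variant = "ols_fmri", n_folds = 5, seed = 43)
    r2 <- median(enc$per_unit_r)^2
    expect_equal(r2, snr / (snr + 1), tolerance = 0.05)
  }
})

test_that("category clouds realize the requested geometry", {
  # radius 0: every sample sits on its centroid; perfect transfer
  pt <- gen_category_clouds(4, 6, 2, 8, radius = 0, separation = 2, seed = 51)
  spread <- tapply(seq_along(pt$labels), pt$labels, function(idx) {
    max(dist(pt$features[idx, , drop = FALSE]))
  })
  expect_equal(as.numeric(spread), rep(0, 4), tolerance = 1e-12)
  res <- monte_carlo_transfer(pt, n_train = 3, n_test = 3, n_iterations = 2, seed = 52)
  expect_identical(res$accuracy, 1)
  expect_identical(res$mrr, 1)

  # separation 0: classes indistinguishable, accuracy ~ 1/M
  M <- 5
  null <- gen_category_clouds(M, 40, 3, 10, radius = 1, separation = 0, seed = 53)
  res0 <- monte_carlo_transfer(null, n_train = 20, n_test = 20,
                               n_iterations = 5, seed = 54)
  # binomial tolerance on 5 x 100 test decisions
  expect_lt(abs(res0$accuracy - 1 / M), 3 * sqrt(0.2 * 0.8 / 500))

  # expected centroid separation is honored
  cl <- gen_category_clouds(30, 2, 4, 50, radius = 0, separation = 3, seed = 55)
  cents <- do.call(rbind, lapply(levels(cl$labels), function(l) {
    colMeans(cl$features[cl$labels == l, , drop = FALSE])
  }))
  expect_equal(mean(dist(cents)), 3, tolerance = 0.2)

  expect_error(gen_category_clouds(1, 5, 2, 4, 1, 1), "2 classes")
  expect_error(gen_category_clouds(3, 5, 9, 4, 1, 1), "latent_dim")
})

test_that("normalized projection distance decreases over the latent grid", {
  tab <- run_projection_vs_dimensionality(
    seed = 61, latent_dims = c(2, 8, 32, 128), M = 10, n_per_class = 20
  )
  expect_true(all(diff(tab$mean_projection) < 0))
})

test_that("feature matrices and recordings round-trip through CSV", {
  f <- gen_power_law_features(10, 4, 0.7, seed = 71)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(f, fp)
  expect_equal(read_feature_csv(fp), f, tolerance = 1e-12)

  rec <- gen_neural_responses(f, 3, 2, snr = 1, n_repeats = 2, seed = 72)
  rp <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, rp)
  back <- read_recording_csv(rp)
  expect_equal(back$values, rec$values, tolerance = 1e-12)
  expect_identical(back$stimulus_ids, rec$stimulus_ids)
  expect_identical(back$unit_ids, rec$unit_ids)
})
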