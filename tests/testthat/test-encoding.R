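test_that("pca_reduce projects onto reference components", {
  x <- tiny_features(n = 25, p = 8, seed = 3)

  # full-rank self-reference: orthogonal projection preserves distances
  red <- pca_reduce(x, x, n_components = 8)
  expect_equal(attr(red, "n_components"), 8)
  expect_equal(as.matrix(dist(unclass(red))), as.matrix(dist(unclass(x))),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_equal(ncol(pca_reduce(x, x, n_components = 1)), 1L)
  expect_error(pca_reduce(x, tiny_features(25, 5, seed = 4)), "share channels")
})

test_that("encoding score is unchanged by full-rank PCA reduction", {
  f <- gen_power_law_features(120, 6, 0.5, seed = 13)
  rec <- gen_neural_responses(f, 5, 4, snr = 2, n_repeats = 1, seed = 14)
  direct <- fit_cv_encoder(f, rec, "pls_monkey", n_components = 6,
                           n_folds = 5, seed = 15)
  reduced <- fit_cv_encoder(pca_reduce(f, f, 6), rec, "pls_monkey",
                            n_components = 6, n_folds = 5, seed = 15)
  expect_equal(direct$per_unit_r, reduced$per_unit_r, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("cross-validated encoders recover exact linear structure", {
  x <- gen_power_law_features(150, 8, 0, seed = 23)
  w <- with_fixture_seed(24, matrix(rnorm(8 * 6), 8, 6))
  y <- unclass(x) %*% w

  for (variant in c("pls_monkey", "ols_fmri")) {
    enc <- fit_cv_encoder(x, y, variant, n_components = 8, n_folds = 5, seed = 25)
    expect_equal(unname(enc$per_unit_r), rep(1, 6), tolerance = 1e-6)
  }

  # pure-noise null: median |r| below the 3/sqrt(n) bound
  noise <- with_fixture_seed(26, matrix(rnorm(150 * 6), 150, 6))
  null <- fit_cv_encoder(x, noise, "pls_monkey", n_components = 8,
                         n_folds = 5, seed = 27)
  expect_lt(abs(median(null$per_unit_r)), 3 / sqrt(150))
})

test_that("PLS matches OLS in the full-rank component limit", {
  x <- gen_power_law_features(80, 5, 0.3, seed = 33)
  y <- with_fixture_seed(34, unclass(x) %*% matrix(rnorm(15), 5, 3) +
                           0.1 * matrix(rnorm(240), 80, 3))
  pls <- fit_cv_encoder(x, y, "pls_monkey", n_components = 5, n_folds = 4, seed = 35)
  ols <- fit_cv_encoder(x, y, "ols_fmri", n_folds = 4, seed = 35)
  expect_equal(pls$per_unit_r, ols$per_unit_r, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("encoding pipeline is invariant to unit order and feature rotation", {
  x <- gen_power_law_features(100, 6, 0.4, seed = 43)
  rec <- gen_neural_responses(x, 8, 4, snr = 1.5, n_repeats = 1, seed = 44)
  y <- average_repeats(rec)
  base <- fit_cv_encoder(x, y, "ols_fmri", n_folds = 5, seed = 45)

  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  permuted <- fit_cv_encoder(x, y[, perm], "ols_fmri", n_folds = 5, seed = 45)
  expect_equal(unname(permuted$per_unit_r), unname(base$per_unit_r[perm]),
               tolerance = 1e-10)

  rot <- random_rotation(6, seed = 46)
  rotated <- fit_cv_encoder(feature_matrix(unclass(x) %*% rot), y,
                            "ols_fmri", n_folds = 5, seed = 45)
  expect_equal(rotated$per_unit_r, base$per_unit_r, tolerance = 1e-8)
})

test_that("split-half reliability behaves at the signal and noise extremes", {
  f <- gen_power_law_features(150, 6, 0.5, seed = 53)

  clean <- gen_neural_responses(f, 4, 3, snr = Inf, n_repeats = 4, seed = 54)
  for (corrected in c(TRUE, FALSE)) {
    rel <- split_half_reliability(clean, n_splits = 3, corrected = corrected, seed = 55)
    expect_equal(unname(rel$per_unit_ceiling), rep(1, 4), tolerance = 1e-10)
  }

  # no signal: ceiling near zero
  pure_noise <- with_fixture_seed(
    59, neural_recording_set(array(rnorm(400 * 4 * 6), c(400, 4, 6)))
  )
  rel0 <- split_half_reliability(pure_noise, n_splits = 10, seed = 56)
  expect_lt(max(abs(rel0$per_unit_ceiling)), 0.2)

  # Spearman-Brown correction is the 2r/(1+r) map of the uncorrected value
  noisy <- gen_neural_responses(f, 6, 3, snr = 1, n_repeats = 2, seed = 57)
  un <- split_half_reliability(noisy, n_splits = 5, corrected = FALSE, seed = 58)
  co <- split_half_reliability(noisy, n_splits = 5, corrected = TRUE, seed = 58)
  expect_equal(co$per_unit_ceiling,
               2 * un$per_unit_ceiling / (1 + un$per_unit_ceiling))
})

test_that("normalized encoding score squares the ceiling-relative median", {
  mk_result <- function(r) structure(list(median_r = r), class = "encoding_result")
  mk_rel <- function(c_) structure(list(per_unit_ceiling = c_), class = "reliability_set")

  expect_equal(normalized_encoding_score(mk_result(0.6), mk_rel(c(0.6, 0.6))), 1)
  expect_equal(normalized_encoding_score(mk_result(0), mk_rel(c(0.5, 0.7))), 0)
  expect_equal(normalized_encoding_score(mk_result(0.3), mk_rel(0.6)), 0.25)
  expect_error(normalized_encoding_score(mk_result(0.3), mk_rel(c(-0.1, 0))),
               "undefined")

  # monotone in median r for a fixed ceiling
  scores <- sapply(seq(0, 0.5, by = 0.1), function(r) {
    normalized_encoding_score(mk_result(r), mk_rel(0.5))
  })
  expect_true(all(diff(scores) > 0))
})

test_that("RSA scores match identity and permutation expectations", {
  x <- tiny_features(n = 12, p = 6, seed = 63)
  expect_equal(rsa_score(x, unclass(x)), 1)
  expect_equal(rsa_score(x, unclass(x)[, c(4, 1, 6, 2, 3, 5)]), 1)
  expect_error(rsa_score(x[1:2, ], unclass(x)[1:2, ]), "3 stimuli")
  bad <- unclass(x); bad[3, ] <- 2
  expect_error(rsa_score(bad, bad), "constant")
})

test_that("RSA equals brute-force pairwise computation on 5 stimuli", {
  x <- tiny_features(n = 5, p = 7, seed = 73)
  y <- tiny_features(n = 5, p = 4, seed = 74)
  rx <- brute_rdm(unclass(x))
  ry <- brute_rdm(unclass(y))
  pairs_x <- rx[upper.tri(rx)]
  pairs_y <- ry[upper.tri(ry)]
  expect_equal(rsa_score(x, unclass(y)),
               cor(pairs_x, pairs_y, method = "spearman"))
})
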