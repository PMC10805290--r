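test_that("natural observations realize the configured covariance", {
  # isotropic full-rank option: sample covariance near identity
  cfg <- subspace_sim_config(ambient_dim = 10L, natural_dim = 10L,
                             eco_dim = 5L, model_dim = 5L, natural_alpha = 0,
                             n_train = 4000L, n_test = 10L, seed = 3L)
  nat <- sample_natural_observations(cfg)
  expect_equal(cov(nat$observations), diag(10), tolerance = 0.12)

  # rank bounded by natural_dim
  cfg2 <- subspace_sim_config(ambient_dim = 40L, natural_dim = 12L,
                              eco_dim = 6L, model_dim = 6L,
                              n_train = 100L, n_test = 10L, seed = 4L)
  nat2 <- sample_natural_observations(cfg2)
  sv <- svd(scale(nat2$observations, scale = FALSE))$d
  expect_lte(sum(sv > 1e-8), 12)

  # population spectrum ED matches its analytic participation ratio
  expect_equal(effective_dimensionality(nat2$spectrum),
               power_law_ed(cfg2$natural_alpha, 12))
})

test_that("aligned subspaces interpolate overlap between random and identical", {
  set.seed(11)
  ref <- random_orthonormal(50, 8)

  full <- make_aligned_subspace(ref, 1, AP = 1, seed = 12)
  expect_equal(subspace_overlap(full$basis, ref), 1, tolerance = 1e-10)
  expect_equal(crossprod(full$basis), diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)

  # AP = 0 matches the Monte-Carlo overlap of two independent random frames
  null_overlaps <- replicate(200, {
    subspace_overlap(random_orthonormal(50, 8), random_orthonormal(50, 8))
  })
  ap0 <- replicate(50, {
    subspace_overlap(make_aligned_subspace(ref, 1, AP = 0)$basis, ref)
  })
  expect_lt(abs(mean(ap0) - mean(null_overlaps)),
            4 * sd(null_overlaps) / sqrt(50))

  # overlap grows monotonically in AP (averaged over seeds)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_overlap <- sapply(grid, function(ap) {
    mean(sapply(1:25, function(s) {
      subspace_overlap(make_aligned_subspace(ref, 1, AP = ap, seed = s)$basis, ref)
    }))
  })
  expect_true(all(diff(mean_overlap) > 0))
  expect_error(make_aligned_subspace(ref, 1, AP = 1.5), "AP")
})

test_that("encoding experiments hit the identity and orthogonal extremes", {
  # identical subspaces, no noise: perfect prediction
  ident <- subspace_sim_config(alignment_pressure = 1, eco_dim = 16L,
                               model_dim = 16L, eco_alpha = 0.5,
                               model_alpha = 0.5, noise_sigma = 0,
                               n_train = 150L, n_test = 60L, seed = 21L)
  expect_gt(simulate_encoding_experiment(ident)$score, 0.98)

  # unaligned, heavy noise: nothing predictable
  null <- subspace_sim_config(ambient_dim = 400L, natural_dim = 64L,
                              alignment_pressure = 0, noise_sigma = 4,
                              eco_dim = 8L, model_dim = 8L,
                              n_train = 150L, n_test = 60L, seed = 22L)
  expect_lt(simulate_encoding_experiment(null)$score, 0.05)

  # determinism
  cfg <- subspace_sim_config(seed = 23L, n_train = 100L, n_test = 50L,
                             eco_dim = 8L, model_dim = 8L)
  expect_identical(simulate_encoding_experiment(cfg),
                   simulate_encoding_experiment(cfg))
})

test_that("scores are capped at 1 and degrade monotonically with noise", {
  sigmas <- c(0, 0.5, 2)
  means <- sapply(sigmas, function(sg) {
    mean(sapply(1:8, function(s) {
      cfg <- subspace_sim_config(alignment_pressure = 1, eco_dim = 12L,
                                 model_dim = 12L, noise_sigma = sg,
                                 n_train = 150L, n_test = 60L, seed = 100L + s)
      res <- simulate_encoding_experiment(cfg)
      expect_lte(res$score, 1)
      res$score
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("the encoder is invariant to orthogonal rotation of model features", {
  set.seed(31)
  x <- matrix(rnorm(120 * 10), 120, 10)
  y <- x[, 1:4] + 0.3 * matrix(rnorm(120 * 4), 120, 4)
  base <- neurodim:::encode_r2(x, y, n_train = 90)
  rot <- neurodim:::encode_r2(x %*% random_rotation(10, seed = 32), y, n_train = 90)
  expect_equal(base$raw_score, rot$raw_score, tolerance = 1e-8)
})

test_that("regime sweeps tabulate one row per grid point and replicate", {
  grid <- regime_preset("alignment", n_points = 3, ed_fixed = 5,
                        base = subspace_sim_config(eco_dim = 8L, model_dim = 8L,
                                                   n_train = 80L, n_test = 40L))
  sw <- run_regime_sweep(grid, n_replicates = 2, seed = 41)
  expect_equal(nrow(sw), 6)
  expect_true(all(sw$encoding_score >= 0 & sw$encoding_score <= 1))
  expect_true(all(sw$encoding_score >= sw$raw_score - 1e-12))
  summ <- summarize_sweep(sw)
  expect_equal(nrow(summ), 3)
  expect_error(run_regime_sweep(list()), "nonempty")

  # analytic model ED is recorded per grid point
  expected_ed <- sapply(grid, function(c_) power_law_ed(c_$model_alpha, c_$model_dim))
  expect_equal(sw$model_ed, expected_ed[sw$grid_point])
})

test_that("replicate scatter shrinks with larger samples", {
  spread <- sapply(c(60L, 400L), function(n) {
    scores <- sapply(1:10, function(s) {
      cfg <- subspace_sim_config(eco_dim = 8L, model_dim = 8L,
                                 alignment_pressure = 0.7,
                                 n_train = n, n_test = n %/% 2L,
                                 seed = 200L + s)
      simulate_encoding_experiment(cfg)$raw_score
    })
    sd(scores)
  })
  expect_lt(spread[2], spread[1])
})
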