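# Seeded generators for every input class the analyses consume: feature
# clouds with controlled power-law eigenspectra, multi-trial neural responses
# as noisy linear readouts of a latent signal subspace, labeled category
# clouds with controlled latent dimensionality, and spatial feature maps.

#' Generate Gaussian features with a power-law eigenspectrum
#'
#' Samples `n_stimuli` observations from a zero-mean Gaussian whose population
#' covariance has eigenvalues `lambda_i` proportional to `i^(-alpha)` over a
#' random orthonormal eigenbasis. `alpha = 0` gives an isotropic cloud
#' (ED = n_channels); large `alpha` collapses the variance onto the first
#' component (ED -> 1). The analytic population ED is [power_law_ed()].
#'
#' @param n_stimuli,n_channels Positive dimensions; `n_stimuli > n_channels`
#'   recommended when the empirical spectrum will be estimated.
#' @param alpha Nonnegative decay exponent of the target spectrum.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `feature_matrix`.
#' @export
gen_power_law_features <- function(n_stimuli, n_channels, alpha, seed = 1L) {
  if (n_stimuli < 2L || n_channels < 1L) stop("dimensions must be positive (>= 2 stimuli)")
  if (alpha < 0) stop("alpha must be nonnegative")
  with_seed(seed, {
    lambdas <- seq_len(n_channels)^(-alpha)
    basis <- random_orthonormal(n_channels)
    z <- matrix(stats::rnorm(n_stimuli * n_channels), n_stimuli, n_channels)
    x <- z %*% (t(basis) * sqrt(lambdas))
    feature_matrix(x)
  })
}

#' Generate multi-trial neural responses as noisy readouts of feature space
#'
#' Responses are a fixed random linear readout of the top `n_signal_dims`
#' principal directions of `features`, plus independent Gaussian noise per
#' repeat, scaled so that each unit's signal variance over single-repeat noise
#' variance equals `snr`. Under this model the expected split-half
#' reliability of a unit (two repeats) is `snr / (snr + 1)`.
#'
#' @param features A `feature_matrix` providing the signal subspace.
#' @param n_units Number of simulated recording sites.
#' @param n_signal_dims Number of leading principal directions carrying
#'   signal; at most `ncol(features)`.
#' @param snr Per-unit signal-to-noise variance ratio, > 0 (use `Inf` for
#'   noiseless responses).
#' @param n_repeats Trial repeats (>= 1).
#' @param seed Integer seed.
#' @return A `neural_recording_set` aligned with `features`' stimulus ids.
#' @export
gen_neural_responses <- function(features, n_units, n_signal_dims, snr,
                                 n_repeats = 2L, seed = 1L) {
  x <- as_feature_values(features)
  if (n_signal_dims > ncol(x)) stop("n_signal_dims exceeds the channel count")
  if (!(snr > 0)) stop("snr must be positive")
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  with_seed(seed, {
    xc <- sweep(x, 2L, colMeans(x), "-")
    sv <- svd(xc, nu = 0, nv = n_signal_dims)
    scores <- xc %*% sv$v                       # stimuli x n_signal_dims
    readout <- matrix(stats::rnorm(n_signal_dims * n_units), n_signal_dims, n_units)
    signal <- scores %*% readout                # stimuli x units
    sig_var <- apply(signal, 2L, stats::var)
    noise_sd <- sqrt(sig_var / snr)             # 0 when snr = Inf
    vals <- array(0, dim = c(nrow(x), n_units, n_repeats))
    for (r in seq_len(n_repeats)) {
      noise <- matrix(stats::rnorm(nrow(x) * n_units), nrow(x), n_units)
      vals[, , r] <- signal + sweep(noise, 2L, noise_sd, "*")
    }
    neural_recording_set(vals, stimulus_ids = rownames(x))
  })
}

#' Generate labeled category clouds with controlled latent dimensionality
#'
#' All classes live in a single `latent_dim`-dimensional subspace of the
#' ambient feature space (a random orthonormal embedding drawn from the
#' seed), so the latent dimensionality of the generated representation is
#' controlled directly: its effective dimensionality is of order
#' `latent_dim`. Class centroids are drawn from a scaled Gaussian in the
#' latent space so that the expected pairwise centroid distance equals
#' `separation`; within-class samples are uniform in a `latent_dim`-ball of
#' the given `radius` around their centroid. Because between-class readout
#' directions lie in the same latent subspace as the class clouds, higher
#' `latent_dim` at fixed radius concentrates each class's projections onto
#' readout directions more tightly around its centroid (of order
#' `radius / sqrt(latent_dim)`).
#'
#' @param M Number of classes (>= 2).
#' @param n_per_class Samples per class (>= 2).
#' @param latent_dim Intrinsic dimensionality of each class cloud,
#'   `<= ambient_dim`.
#' @param ambient_dim Number of feature channels.
#' @param radius Class-cloud radius (>= 0; 0 collapses each class onto its
#'   centroid).
#' @param separation Expected pairwise centroid distance (>= 0).
#' @param seed Integer seed.
#' @return A `category_samples` object.
#' @export
gen_category_clouds <- function(M, n_per_class, latent_dim, ambient_dim,
                                radius, separation, seed = 1L) {
  if (M < 2L) stop("need at least 2 classes")
  if (latent_dim > ambient_dim) stop("latent_dim must not exceed ambient_dim")
  if (n_per_class < 2L) stop("need at least 2 samples per class")
  with_seed(seed, {
    # For centroids iid N(0, s^2 I_d), E||c_i - c_j|| = s * sqrt(2) * E||z||,
    # z ~ N(0, I_d), E||z|| = sqrt(2) * gamma((d+1)/2) / gamma(d/2).
    d <- latent_dim
    e_norm <- sqrt(2) * exp(lgamma((d + 1) / 2) - lgamma(d / 2))
    s <- if (separation > 0) separation / (sqrt(2) * e_norm) else 0
    centroids <- matrix(stats::rnorm(M * d, sd = 1), M, d) * s
    emb <- random_orthonormal(ambient_dim, latent_dim)  # shared embedding
    latent <- matrix(0, M * n_per_class, d)
    labels <- rep(seq_len(M), each = n_per_class)
    for (m in seq_len(M)) {
      ball <- runif_ball(n_per_class, latent_dim, radius)
      rows <- which(labels == m)
      latent[rows, ] <- sweep(ball, 2L, centroids[m, ], "+")
    }
    feats <- latent %*% t(emb)
    category_samples(
      feature_matrix(feats),
      labels = factor(pad_ids(M, prefix = "class")[labels])
    )
  })
}

#' Generate Gaussian feature maps for pooling tests
#'
#' @param n_stimuli,n_channels,height,width Array dimensions, all >= 1.
#' @param seed Integer seed.
#' @return A `feature_map_set`.
#' @export
gen_feature_maps <- function(n_stimuli, n_channels, height, width, seed = 1L) {
  if (min(n_stimuli, n_channels, height, width) < 1L) stop("all dimensions must be >= 1")
  with_seed(seed, {
    vals <- array(
      stats::rnorm(n_stimuli * n_channels * height * width),
      dim = c(n_stimuli, n_channels, height, width)
    )
    dimnames(vals) <- list(pad_ids(n_stimuli), NULL, NULL, NULL)
    feature_map_set(vals)
  })
}
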