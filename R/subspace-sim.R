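# Subspace-alignment simulation framework: observations are sampled from a
# high-dimensional "natural image" subspace and projected onto two smaller
# subspaces — an ecological (brain) subspace and a model subspace — each
# weighted by a power-law eigenspectrum and observed under Gaussian noise.
# Cross-validated linear regression from model features to ecological
# dimensions yields an encoding score, and sweeping the model's effective
# dimensionality (ED, via its spectral decay) against alignment pressure
# (AP, the tendency of the two subspaces' leading dimensions to overlap)
# reproduces the Alignment / Joint / Dimensionality regimes.

#' Configuration for a subspace-alignment simulation
#'
#' @param ambient_dim Ambient dimensionality of the natural space.
#' @param natural_dim Number of nonzero variance directions of the natural
#'   image subspace (`<= ambient_dim`).
#' @param eco_dim,model_dim Dimensionalities of the ecological and model
#'   subspaces.
#' @param natural_alpha Decay exponent of the natural spectrum (small =
#'   slowly decaying).
#' @param eco_alpha,model_alpha Power-law exponents of the ecological and
#'   model subspace spectra; the model's analytic ED is
#'   `power_law_ed(model_alpha, model_dim)`.
#' @param alignment_pressure AP in `[0, 1]`: 0 = independently sampled model
#'   subspace, 1 = model subspace identical to the ecological one.
#' @param noise_sigma Observation noise scale added to both projections.
#' @param n_train,n_test Sample counts (`>= 2` each).
#' @param regression `"ols"` or `"pls"` encoder.
#' @param noise_on `"observations"` (default: noise added after projection)
#'   or `"latent"` (added to the ambient observations before projection).
#' @param seed Integer seed.
#' @return A list of class `subspace_sim_config`.
#' @export
subspace_sim_config <- function(ambient_dim = 128L, natural_dim = 64L,
                                eco_dim = 32L, model_dim = 64L,
                                natural_alpha = 0.1, eco_alpha = 0.5,
                                model_alpha = 0.5, alignment_pressure = 0.5,
                                noise_sigma = 0.25, n_train = 500L,
                                n_test = 200L, regression = c("ols", "pls"),
                                noise_on = c("observations", "latent"),
                                seed = 1L) {
  regression <- match.arg(regression)
  noise_on <- match.arg(noise_on)
  if (natural_dim > ambient_dim) stop("natural_dim must not exceed ambient_dim")
  if (eco_dim > natural_dim || model_dim > natural_dim) {
    stop("subspace dimensions must not exceed natural_dim")
  }
  if (alignment_pressure < 0 || alignment_pressure > 1) stop("AP must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (n_train < 2L || n_test < 2L) stop("sample counts must be >= 2")
  structure(
    list(
      ambient_dim = as.integer(ambient_dim), natural_dim = as.integer(natural_dim),
      eco_dim = as.integer(eco_dim), model_dim = as.integer(model_dim),
      natural_alpha = natural_alpha, eco_alpha = eco_alpha,
      model_alpha = model_alpha, alignment_pressure = alignment_pressure,
      noise_sigma = noise_sigma, n_train = as.integer(n_train),
      n_test = as.integer(n_test), regression = regression,
      noise_on = noise_on, seed = as.integer(seed)
    ),
    class = "subspace_sim_config"
  )
}

#' Sample observations from the natural image subspace
#'
#' Zero-mean Gaussian samples in the ambient space whose covariance has
#' `natural_dim` nonzero eigenvalues decaying slowly as
#' `i^(-natural_alpha)` over a random orthonormal eigenbasis.
#'
#' @param config A `subspace_sim_config`.
#' @return A list with `observations` ((n_train + n_test) x ambient_dim
#'   matrix), `basis` (ambient_dim x natural_dim), `spectrum`.
#' @export
sample_natural_observations <- function(config) {
  with_seed(config$seed, {
    lam <- seq_len(config$natural_dim)^(-config$natural_alpha)
    basis <- random_orthonormal(config$ambient_dim, config$natural_dim)
    n <- config$n_train + config$n_test
    z <- matrix(stats::rnorm(n * config$natural_dim), n, config$natural_dim)
    x <- (z * rep(sqrt(lam), each = n)) %*% t(basis)
    list(observations = x, basis = basis, spectrum = lam)
  })
}

#' Construct a subspace aligned to a reference basis
#'
#' Realizes alignment pressure as an interpolation between an independently
#' drawn random orthonormal basis (AP = 0) and the reference basis (AP = 1),
#' re-orthonormalized column by column so that leading directions retain the
#' strongest alignment. Columns beyond the reference's width are purely
#' random. Returns the basis together with a power-law spectrum.
#'
#' @param reference_basis Matrix (ambient x r) with orthonormal columns.
#' @param target_alpha Spectrum decay exponent for the new subspace.
#' @param AP Alignment pressure in `[0, 1]`.
#' @param seed Integer seed (`NULL` to use the current RNG stream).
#' @param k Number of columns of the new basis (default: same as reference).
#' @return A list with `basis` (ambient x k, orthonormal) and `spectrum`
#'   (length k).
#' @export
make_aligned_subspace <- function(reference_basis, target_alpha, AP,
                                  seed = NULL, k = ncol(reference_basis)) {
  if (AP < 0 || AP > 1) stop("AP must lie in [0, 1]")
  d <- nrow(reference_basis)
  r <- ncol(reference_basis)
  with_seed(seed, {
    rnd <- random_orthonormal(d, k)
    mix <- rnd * (1 - AP)
    shared <- seq_len(min(r, k))
    mix[, shared] <- mix[, shared] + AP * reference_basis[, shared, drop = FALSE]
    qr_ <- qr(mix)
    q <- qr.Q(qr_)
    s <- diag(qr.R(qr_))
    basis <- q * rep(sign(s + (s == 0)), each = d)
    list(basis = basis, spectrum = seq_len(k)^(-target_alpha))
  })
}

#' Mean squared top-k subspace overlap
#'
#' Mean squared canonical correlation between the leading `k` directions of
#' two orthonormal bases; 1 for identical spans, small for random pairs in a
#' large ambient space.
#'
#' @param basis_a,basis_b Orthonormal-column matrices in the same ambient
#'   space.
#' @param k Number of leading columns to compare.
#' @export
subspace_overlap <- function(basis_a, basis_b, k = min(ncol(basis_a), ncol(basis_b))) {
  a <- basis_a[, seq_len(k), drop = FALSE]
  b <- basis_b[, seq_len(k), drop = FALSE]
  mean(svd(crossprod(a, b), nu = 0, nv = 0)$d^2)
}

# Cross-validated encoder from model features to ecological dimensions:
# mean held-out R^2 across ecological dimensions.
encode_r2 <- function(x_model, y_eco, n_train, regression = "ols",
                      n_pls_components = 25L, summary_fun = mean) {
  n <- nrow(x_model)
  train <- seq_len(n_train)
  test <- (n_train + 1L):n
  fallback <- FALSE
  if (regression == "ols" && n_train <= ncol(x_model) + 1L) {
    regression <- "pls"
    fallback <- TRUE
  }
  if (regression == "ols") {
    b <- ols_fit(x_model[train, , drop = FALSE], y_eco[train, , drop = FALSE])
    pred <- ols_predict(b, x_model[test, , drop = FALSE])
  } else {
    ncomp <- min(n_pls_components, ncol(x_model), n_train - 1L)
    fit <- pls_fit(x_model[train, , drop = FALSE], y_eco[train, , drop = FALSE], ncomp)
    pred <- pls_predict(fit, x_model[test, , drop = FALSE])
  }
  yt <- y_eco[test, , drop = FALSE]
  ss_res <- colSums((yt - pred)^2)
  ss_tot <- colSums(sweep(yt, 2L, colMeans(yt), "-")^2)
  r2 <- 1 - ss_res / ss_tot
  list(raw_score = summary_fun(r2), per_dim_r2 = r2, fallback = fallback)
}

#' Run one subspace-alignment encoding experiment
#'
#' Samples natural observations, projects them onto the ecological and model
#' subspaces (each dimension scaled by the square root of its spectral
#' weight), adds observation noise, fits a cross-validated linear encoder
#' from model features to each ecological dimension, and returns the mean
#' held-out R^2 across ecological dimensions (clipped at 0 for reporting;
#' the raw value is retained).
#'
#' @param config A `subspace_sim_config`.
#' @param summary_fun Aggregation across ecological dimensions (default
#'   `mean`; `median` mirrors the neural pipeline).
#' @return A list with `score` (clipped at 0), `raw_score`, `per_dim_r2`,
#'   `model_ed` (analytic participation ratio of the model spectrum),
#'   `fallback` (whether OLS switched to PLS).
#' @export
simulate_encoding_experiment <- function(config, summary_fun = mean) {
  nat <- sample_natural_observations(config)
  with_seed(derive_seed(config$seed, "subspaces"), {
    eco_ref <- nat$basis %*% random_orthonormal(config$natural_dim, config$eco_dim)
    eco_spec <- seq_len(config$eco_dim)^(-config$eco_alpha)
    model <- make_aligned_subspace(
      eco_ref, config$model_alpha, config$alignment_pressure,
      seed = NULL, k = config$model_dim
    )
    x <- nat$observations
    n <- nrow(x)
    if (config$noise_on == "latent" && config$noise_sigma > 0) {
      x <- x + config$noise_sigma *
        matrix(stats::rnorm(n * config$ambient_dim), n, config$ambient_dim)
    }
    y_eco <- (x %*% eco_ref) * rep(sqrt(eco_spec), each = n)
    x_model <- (x %*% model$basis) * rep(sqrt(model$spectrum), each = n)
    if (config$noise_on == "observations" && config$noise_sigma > 0) {
      y_eco <- y_eco + config$noise_sigma *
        matrix(stats::rnorm(n * config$eco_dim), n, config$eco_dim)
      x_model <- x_model + config$noise_sigma *
        matrix(stats::rnorm(n * config$model_dim), n, config$model_dim)
    }
    enc <- encode_r2(x_model, y_eco, config$n_train, config$regression,
                     summary_fun = summary_fun)
    list(
      score = max(0, enc$raw_score),
      raw_score = enc$raw_score,
      per_dim_r2 = enc$per_dim_r2,
      model_ed = power_law_ed(config$model_alpha, config$model_dim),
      fallback = enc$fallback
    )
  })
}

#' Invert the participation ratio of a truncated power law
#'
#' Finds the decay exponent `alpha` at which a length-`n` power-law spectrum
#' has the requested effective dimensionality.
#'
#' @param ed Target ED in `(1, n]`.
#' @param n Spectrum length.
#' @export
alpha_for_ed <- function(ed, n) {
  if (ed > n || ed <= 1) stop("target ED must lie in (1, n]")
  if (abs(ed - n) < 1e-9) return(0)
  stats::uniroot(
    function(a) power_law_ed(a, n) - ed,
    interval = c(0, 50), tol = 1e-10
  )$root
}

#' Build the config grid for one simulation regime
#'
#' Presets for the three predicted regimes relating model ED to encoding
#' performance:
#' * `"dimensionality"` — AP fixed at a moderate value, model spectral decay
#'   swept so that model ED covers a log-spaced grid; ED drives performance.
#' * `"alignment"` — model ED fixed, AP swept over `[0, 1]`; alignment drives
#'   performance.
#' * `"joint"` — the ED grid of the dimensionality preset, with AP linked to
#'   ED by a log-Gaussian bump peaking at `ed_opt`, so performance peaks at
#'   an interior optimal dimensionality.
#'
#' @param regime One of `"dimensionality"`, `"alignment"`, `"joint"`.
#' @param n_points Grid resolution.
#' @param ed_range ED sweep range (log-spaced) for the dimensionality and
#'   joint presets; defaults to 2–50 (dimensionality) or 2–28 (joint, whose
#'   model subspace is half the natural space so that alignment stays
#'   binding).
#' @param ap_fixed AP used by the dimensionality preset.
#' @param ed_fixed Model ED used by the alignment preset.
#' @param ed_opt,ap_max,ap_width Joint-regime link: `AP(ED) = ap_max *
#'   exp(-(log ED - log ed_opt)^2 / (2 ap_width^2))`.
#' @param base Base `subspace_sim_config` providing all other parameters.
#'   Defaults per regime: the dimensionality preset uses a model subspace as
#'   wide as the natural space (`model_dim = 64`), so that high-ED models can
#'   span the dimensions the ecological subspace happens to occupy; the
#'   alignment and joint presets use `model_dim = 32`, leaving alignment with
#'   room to matter.
#' @return A list of `subspace_sim_config` objects (one per grid point).
#' @export
regime_preset <- function(regime = c("dimensionality", "alignment", "joint"),
                          n_points = 8L, ed_range = NULL, ap_fixed = 0.3,
                          ed_fixed = 10, ed_opt = 8, ap_max = 0.9,
                          ap_width = 0.6, base = NULL) {
  regime <- match.arg(regime)
  if (is.null(base)) {
    base <- if (regime == "dimensionality") subspace_sim_config()
            else subspace_sim_config(model_dim = 32L)
  }
  if (is.null(ed_range)) {
    ed_range <- if (regime == "joint") c(2, 28) else c(2, 50)
  }
  mk <- function(model_alpha, ap) {
    cfg <- base
    cfg$model_alpha <- model_alpha
    cfg$alignment_pressure <- ap
    cfg
  }
  if (regime == "alignment") {
    alpha <- alpha_for_ed(ed_fixed, base$model_dim)
    ap_grid <- seq(0, 1, length.out = n_points)
    return(lapply(ap_grid, function(ap) mk(alpha, ap)))
  }
  ed_grid <- exp(seq(log(ed_range[1L]), log(ed_range[2L]), length.out = n_points))
  ed_grid <- pmin(ed_grid, base$model_dim)
  alphas <- vapply(ed_grid, alpha_for_ed, numeric(1), n = base$model_dim)
  if (regime == "dimensionality") {
    return(lapply(alphas, function(a) mk(a, ap_fixed)))
  }
  aps <- ap_max * exp(-(log(ed_grid) - log(ed_opt))^2 / (2 * ap_width^2))
  Map(function(a, ap) mk(a, ap), alphas, aps)
}

#' Sweep encoding performance over a grid of simulation configs
#'
#' Runs [simulate_encoding_experiment()] for every config and replicate
#' (seeds derived deterministically from `seed`) and collects one row per
#' (grid point, replicate).
#'
#' @param config_grid List of `subspace_sim_config` objects (e.g. from
#'   [regime_preset()]).
#' @param n_replicates Replicates per grid point.
#' @param seed Integer master seed.
#' @return A data frame of class `regime_sweep_result` with columns
#'   `grid_point`, `replicate`, `model_ed`, `ap`, `encoding_score` (clipped),
#'   `raw_score`.
#' @export
run_regime_sweep <- function(config_grid, n_replicates = 20L, seed = 1L) {
  if (length(config_grid) == 0L) stop("config grid must be nonempty")
  rows <- list()
  for (g in seq_along(config_grid)) {
    for (rep_ in seq_len(n_replicates)) {
      cfg <- config_grid[[g]]
      cfg$seed <- derive_seed(seed, paste0("sweep-", g, "-", rep_))
      res <- simulate_encoding_experiment(cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        grid_point = g, replicate = rep_,
        model_ed = res$model_ed, ap = cfg$alignment_pressure,
        encoding_score = res$score, raw_score = res$raw_score
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("regime_sweep_result", class(out))
  out
}

#' Per-grid-point summary of a regime sweep
#'
#' @param sweep A `regime_sweep_result`.
#' @return Data frame with one row per grid point: `model_ed`, `ap`,
#'   `mean_score`, `se_score`.
#' @export
summarize_sweep <- function(sweep) {
  sp <- split(as.data.frame(sweep), sweep$grid_point)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      grid_point = d$grid_point[1L], model_ed = d$model_ed[1L], ap = d$ap[1L],
      mean_score = mean(d$encoding_score),
      se_score = stats::sd(d$encoding_score) / sqrt(nrow(d))
    )
  }))
  rownames(out) <- NULL
  out
}
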