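# End-to-end synthetic reproduction workflows. Each workflow derives
# per-stage seeds deterministically from a single master seed, runs the
# package's generators and analyses, and returns tidy tables; run_all()
# bundles them into a single report with pass/fail flags on the qualitative
# properties the analyses are expected to show.

#' Synthetic dimensionality-vs-encoding-performance experiment
#'
#' The synthetic analogue of the relationship between model ED and neural
#' encoding performance: a fixed high-dimensional synthetic "brain" (noisy
#' linear readout of an isotropic latent feature space, measured over two
#' trial repeats) is predicted from a family of model feature sets that share
#' the brain's latent source but reweight it by power-law spectra of
#' increasing ED, under a fixed feature-noise floor that renders low-variance
#' model dimensions uninformative. Higher-ED models carry more usable
#' dimensions of the latent source and should achieve higher
#' ceiling-normalized encoding scores.
#'
#' @param seed Master integer seed.
#' @param ed_grid Target (population) EDs of the model feature spectra;
#'   log-spaced by default.
#' @param n_seeds Independent repetitions of the whole experiment.
#' @param n_stimuli,n_channels Latent feature cloud size.
#' @param n_units Simulated recording sites.
#' @param snr Per-unit signal-to-noise ratio of the brain responses.
#' @param n_repeats Trial repeats (>= 2, for the noise ceiling).
#' @param feature_noise_sd Isotropic noise added to model features; sets the
#'   variance floor below which model dimensions are unusable.
#' @param n_components,n_folds Encoder settings.
#' @return A list with `table` (one row per grid point x seed: `ed_target`,
#'   `alpha`, `ed_measured`, `median_r`, `normalized_score`), `by_grid`
#'   (per-grid-point means), and `spearman` (rank correlation between ED and
#'   mean normalized score across grid points; `NA` for a single point).
#' @export
run_fig3_synthetic <- function(seed = 1L,
                               ed_grid = exp(seq(log(2), log(60), length.out = 8)),
                               n_seeds = 5L, n_stimuli = 600L, n_channels = 100L,
                               n_units = 50L, snr = 1, n_repeats = 2L,
                               feature_noise_sd = 0.3, n_components = 25L,
                               n_folds = 10L) {
  alphas <- vapply(ed_grid, alpha_for_ed, numeric(1), n = n_channels)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    base_seed <- derive_seed(seed, paste0("fig3-rep", s))
    latent <- gen_power_law_features(n_stimuli, n_channels, alpha = 0,
                                     seed = derive_seed(base_seed, "latent"))
    brain <- gen_neural_responses(latent, n_units = n_units,
                                  n_signal_dims = n_channels, snr = snr,
                                  n_repeats = n_repeats,
                                  seed = derive_seed(base_seed, "brain"))
    ceiling <- split_half_reliability(brain, n_splits = 10L, corrected = TRUE,
                                      seed = derive_seed(base_seed, "ceiling"))
    z <- as_feature_values(latent)
    for (g in seq_along(alphas)) {
      model_feats <- with_seed(derive_seed(base_seed, paste0("model-", g)), {
        q <- random_orthonormal(n_channels)
        lam <- seq_len(n_channels)^(-alphas[g])
        x <- (z %*% q) * rep(sqrt(lam), each = n_stimuli)
        x <- x + feature_noise_sd *
          matrix(stats::rnorm(n_stimuli * n_channels), n_stimuli, n_channels)
        feature_matrix(x)
      })
      ed_meas <- effective_dimensionality(compute_eigenspectrum(model_feats))
      enc <- fit_cv_encoder(model_feats, brain, variant = "pls_monkey",
                            n_components = n_components, n_folds = n_folds,
                            seed = derive_seed(base_seed, paste0("cv-", g)))
      rows[[length(rows) + 1L]] <- data.frame(
        seed_rep = s, grid_point = g, ed_target = ed_grid[g], alpha = alphas[g],
        ed_measured = ed_meas, median_r = enc$median_r,
        normalized_score = normalized_encoding_score(enc, ceiling)
      )
    }
  }
  table <- do.call(rbind, rows)
  by_grid <- do.call(rbind, lapply(split(table, table$grid_point), function(d) {
    data.frame(
      grid_point = d$grid_point[1L], ed_target = d$ed_target[1L],
      ed_measured = mean(d$ed_measured),
      normalized_score = mean(d$normalized_score)
    )
  }))
  rownames(by_grid) <- NULL
  spearman <- if (nrow(by_grid) >= 2L) {
    stats::cor(by_grid$ed_measured, by_grid$normalized_score, method = "spearman")
  } else NA_real_
  list(table = table, by_grid = by_grid, spearman = spearman)
}

#' Transfer performance across latent dimensionalities
#'
#' Generates category clouds of increasing latent dimensionality at fixed
#' radius and separation and evaluates Monte Carlo prototype transfer on
#' each. Higher-dimensional clouds concentrate their projections and should
#' classify novel samples more accurately.
#'
#' @param seed Master integer seed.
#' @param latent_dims Latent dimensionality grid.
#' @param M Classes; `n_train`/`n_test` per-class split sizes (the per-class
#'   sample count is their sum).
#' @param ambient_dim Feature channels.
#' @param radius,separation Class-cloud geometry.
#' @param n_train,n_test,n_iterations Transfer protocol.
#' @return Data frame with one row per latent dimensionality: `latent_dim`,
#'   `accuracy`, `mrr`.
#' @export
run_transfer_vs_dimensionality <- function(seed = 1L,
                                           latent_dims = c(2L, 8L, 32L, 128L),
                                           M = 50L, ambient_dim = 128L,
                                           radius = 2, separation = 1,
                                           n_train = 50L, n_test = 50L,
                                           n_iterations = 10L) {
  rows <- lapply(latent_dims, function(d) {
    clouds <- gen_category_clouds(
      M = M, n_per_class = n_train + n_test, latent_dim = d,
      ambient_dim = ambient_dim, radius = radius, separation = separation,
      seed = derive_seed(seed, paste0("clouds-", d))
    )
    res <- monte_carlo_transfer(clouds, n_train = n_train, n_test = n_test,
                                n_iterations = n_iterations,
                                seed = derive_seed(seed, paste0("mc-", d)))
    data.frame(latent_dim = d, accuracy = res$accuracy, mrr = res$mrr)
  })
  do.call(rbind, rows)
}

#' Projection-distance concentration across latent dimensionalities
#'
#' Generates category clouds of increasing latent dimensionality and records
#' the mean off-diagonal normalized projection distance of each; the mean
#' should decrease as dimensionality grows.
#'
#' @inheritParams run_transfer_vs_dimensionality
#' @param n_per_class Samples per class.
#' @return Data frame with `latent_dim` and `mean_projection`.
#' @export
run_projection_vs_dimensionality <- function(seed = 1L,
                                             latent_dims = c(2L, 8L, 32L, 128L),
                                             M = 20L, n_per_class = 30L,
                                             ambient_dim = 128L, radius = 2,
                                             separation = 1) {
  rows <- lapply(latent_dims, function(d) {
    clouds <- gen_category_clouds(
      M = M, n_per_class = n_per_class, latent_dim = d,
      ambient_dim = ambient_dim, radius = radius, separation = separation,
      seed = derive_seed(seed, paste0("pclouds-", d))
    )
    data.frame(
      latent_dim = d,
      mean_projection = mean_projection_distance(projection_matrix(clouds))
    )
  })
  do.call(rbind, rows)
}

#' Run every synthetic reproduction workflow and report pass/fail properties
#'
#' Executes the three regime-sweep presets, the synthetic ED-vs-encoding
#' experiment, the transfer-vs-dimensionality grid, the projection
#' concentration grid, and the uniform-ball projection demonstration; writes
#' per-stage CSV tables and a JSON summary when `out_dir` is given (JSON
#' requires the jsonlite package). Stage failures are recorded and do not
#' abort the run.
#'
#' @param seed Master integer seed.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param n_replicates Replicates per regime-sweep grid point.
#' @param fig3_args,transfer_args,projection_args Optional named-argument
#'   lists overriding the defaults of the corresponding workflow (e.g. to
#'   scale problem sizes).
#' @return A report list with one element per stage (`result`, `checks`,
#'   `error`) plus `passed`, the conjunction of all checks.
#' @export
run_all <- function(seed = 1L, out_dir = NULL, n_replicates = 20L,
                    fig3_args = list(), transfer_args = list(),
                    projection_args = list()) {
  report <- list()
  stage <- function(name, fun, checks_fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      list(result = NULL, checks = NULL, error = conditionMessage(res))
    } else {
      list(result = res, checks = checks_fun(res), error = NULL)
    }
  }

  report$regime_dimensionality <- stage(
    "regime_dimensionality",
    function() {
      sw <- run_regime_sweep(regime_preset("dimensionality"),
                             n_replicates = n_replicates,
                             seed = derive_seed(seed, "regime-dim"))
      summarize_sweep(sw)
    },
    function(s) list(
      spearman_ed_score = stats::cor(s$model_ed, s$mean_score, method = "spearman"),
      positive_trend = stats::cor(s$model_ed, s$mean_score, method = "spearman") > 0.8
    )
  )

  report$regime_alignment <- stage(
    "regime_alignment",
    function() {
      sw <- run_regime_sweep(regime_preset("alignment", n_points = 5L),
                             n_replicates = n_replicates,
                             seed = derive_seed(seed, "regime-ap"))
      summarize_sweep(sw)
    },
    function(s) list(
      nondecreasing_in_ap = !is.unsorted(s$mean_score[order(s$ap)])
    )
  )

  report$regime_joint <- stage(
    "regime_joint",
    function() {
      sw <- run_regime_sweep(regime_preset("joint"),
                             n_replicates = n_replicates,
                             seed = derive_seed(seed, "regime-joint"))
      summarize_sweep(sw)
    },
    function(s) {
      peak <- which.max(s$mean_score[order(s$model_ed)])
      list(interior_maximum = peak > 1L && peak < nrow(s))
    }
  )

  report$fig3_synthetic <- stage(
    "fig3_synthetic",
    function() do.call(run_fig3_synthetic,
                       c(list(seed = derive_seed(seed, "fig3")), fig3_args)),
    function(r) list(spearman = r$spearman, strong_positive = r$spearman > 0.8)
  )

  report$transfer <- stage(
    "transfer",
    function() do.call(run_transfer_vs_dimensionality,
                       c(list(seed = derive_seed(seed, "transfer")), transfer_args)),
    function(t) list(
      accuracy_nondecreasing = !is.unsorted(t$accuracy),
      mrr_nondecreasing = !is.unsorted(t$mrr)
    )
  )

  report$projection <- stage(
    "projection",
    function() do.call(run_projection_vs_dimensionality,
                       c(list(seed = derive_seed(seed, "projection")), projection_args)),
    function(p) list(decreasing_in_dim = all(diff(p$mean_projection) < 0))
  )

  report$sphere_demo <- stage(
    "sphere_demo",
    function() sphere_projection_demo(c(1L, 4L, 16L, 64L),
                                      seed = derive_seed(seed, "sphere")),
    function(s) list(
      d1_matches_half = abs(s$mean[s$d == 1] - 0.5) <= 3 * s$se[s$d == 1],
      strictly_decreasing = all(diff(s$mean) < 0)
    )
  )

  checks <- unlist(lapply(report, function(st) {
    Filter(is.logical, st$checks)
  }))
  report$passed <- length(checks) > 0 && all(checks) &&
    !any(vapply(report[names(report) != "passed"],
                function(st) !is.null(st$error), logical(1)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(report), "passed")) {
      res <- report[[nm]]$result
      if (is.data.frame(res)) {
        utils::write.csv(res, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
      } else if (is.list(res) && is.data.frame(res$table)) {
        utils::write.csv(res$table, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
      }
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      summary <- lapply(report[setdiff(names(report), "passed")], function(st) {
        list(checks = st$checks, error = st$error)
      })
      summary$passed <- report$passed
      jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  report
}
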