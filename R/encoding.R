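# Neural encoding pipeline: PCA feature reduction, cross-validated PLS/OLS
# regression from model features to per-unit responses, split-half noise
# ceilings, ceiling-normalized scores, and an RSA alternative that involves
# no parameter fitting.

#' Project features onto the principal components of a reference set
#'
#' Dimensionality reduction used to keep the number of regressors constant
#' across models: principal components are estimated on a reference feature
#' set and the analysis features are centered by the reference mean and
#' projected along the top components.
#'
#' @param features `feature_matrix` to reduce.
#' @param reference `feature_matrix` with the same channels, used to estimate
#'   the components.
#' @param n_components Requested component count (default 1000); capped at
#'   the reference's rank, with the effective count recorded in the
#'   `"n_components"` attribute.
#' @return A `feature_matrix` with `n_components` (effective) channels.
#' @export
pca_reduce <- function(features, reference, n_components = 1000L) {
  x <- as_feature_values(features)
  ref <- as_feature_values(reference)
  if (ncol(x) != ncol(ref)) stop("features and reference must share channels")
  mu <- colMeans(ref)
  refc <- sweep(ref, 2L, mu, "-")
  sv <- svd(refc, nu = 0)
  tol <- max(dim(refc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(n_components, rank)
  out <- sweep(x, 2L, mu, "-") %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(out) <- pad_ids(k, prefix = "pc")
  res <- feature_matrix(out, stimulus_ids = rownames(x))
  attr(res, "n_components") <- k
  res
}

# NIPALS partial least squares with deflation (PLS2). Returns centered-model
# coefficients so predictions are x %*% B recentered by the training means.
pls_fit <- function(x, y, ncomp, tol = 1e-10, max_iter = 200L) {
  x <- as.matrix(x); y <- as.matrix(y)
  xm <- colMeans(x); ym <- colMeans(y)
  X <- sweep(x, 2L, xm, "-")
  Y <- sweep(y, 2L, ym, "-")
  p <- ncol(X); q <- ncol(Y)
  ncomp <- max(1L, min(ncomp, p, nrow(X) - 1L))
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  a <- 0L
  for (comp in seq_len(ncomp)) {
    if (sum(X^2) < 1e-12 || sum(Y^2) < 1e-12) break
    u <- Y[, which.max(colSums(Y^2))]
    w_old <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break
      w <- w / wn
      tt <- X %*% w
      tss <- sum(tt^2)
      if (tss < 1e-14) break
      qv <- crossprod(Y, tt) / tss
      qn2 <- sum(qv^2)
      if (qn2 < 1e-14) break
      u <- Y %*% qv / qn2
      if (sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break
    tt <- X %*% w
    tss <- sum(tt^2)
    if (tss < 1e-14) break
    pv <- crossprod(X, tt) / tss
    qv <- crossprod(Y, tt) / tss
    X <- X - tt %*% t(pv)
    Y <- Y - tt %*% t(qv)
    a <- a + 1L
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv
  }
  if (a == 0L) {
    coefs <- matrix(0, p, q)
  } else {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[, seq_len(a), drop = FALSE]
    coefs <- W %*% solve(crossprod(P, W), t(Q))
  }
  list(coefficients = coefs, x_mean = xm, y_mean = ym, n_components = a)
}

pls_predict <- function(fit, xnew) {
  pred <- sweep(as.matrix(xnew), 2L, fit$x_mean, "-") %*% fit$coefficients
  sweep(pred, 2L, fit$y_mean, "+")
}

# Multivariate OLS with intercept; rank-deficient columns get zero weight.
ols_fit <- function(x, y) {
  X1 <- cbind(1, as.matrix(x))
  b <- qr.coef(qr(X1), as.matrix(y))
  b[is.na(b)] <- 0
  b
}

ols_predict <- function(b, xnew) cbind(1, as.matrix(xnew)) %*% b

#' Fit a cross-validated linear encoding model
#'
#' Maps model features to per-unit neural responses (averaged over trial
#' repeats) with seeded k-fold cross-validation. The monkey-electrophysiology
#' variant (`"pls_monkey"`) uses partial least squares with 25 latent
#' components and 10 folds; the fMRI variant (`"ols_fmri"`) uses ordinary
#' least squares with 9 folds. Per unit, performance is the Pearson
#' correlation between predicted and held-out responses, either averaged
#' across folds (default, `aggregate = "per_fold_mean"`) or computed once on
#' the concatenated held-out predictions (`"concatenated"`).
#'
#' @param features `feature_matrix` of regressors, stimulus-aligned with
#'   `recordings`.
#' @param recordings `neural_recording_set` (repeats are averaged before
#'   fitting) or a stimuli x units matrix.
#' @param variant `"pls_monkey"` or `"ols_fmri"`.
#' @param n_components PLS latent components (ignored for OLS).
#' @param n_folds Cross-validation folds; defaults to 10 (PLS) or 9 (OLS).
#' @param aggregate Per-unit aggregation across folds.
#' @param seed Seed for the fold shuffle.
#' @return An `encoding_result`: list with `per_unit_r`, `median_r`,
#'   `n_folds`, `n_pls_components`, `variant`, `aggregate`, and
#'   `n_undefined_folds` (fold/unit cells dropped for zero test variance).
#' @export
fit_cv_encoder <- function(features, recordings,
                           variant = c("pls_monkey", "ols_fmri"),
                           n_components = 25L, n_folds = NULL,
                           aggregate = c("per_fold_mean", "concatenated"),
                           seed = 1L) {
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  x <- as_feature_values(features)
  y <- if (inherits(recordings, "neural_recording_set")) {
    if (!is.null(rownames(x)) &&
        !identical(recordings$stimulus_ids, rownames(x))) {
      stop("features and recordings have mismatched stimulus ids")
    }
    average_repeats(recordings)
  } else {
    as.matrix(recordings)
  }
  if (nrow(x) != nrow(y)) stop("features and recordings must have the same stimuli")
  if (is.null(n_folds)) n_folds <- if (variant == "pls_monkey") 10L else 9L
  n <- nrow(x)
  if (n_folds < 2L || n_folds > n) stop("n_folds must be in [2, n_stimuli]")

  folds <- with_seed(seed, split(sample.int(n), cut(seq_len(n), n_folds, labels = FALSE)))
  n_units <- ncol(y)
  fold_r <- matrix(NA_real_, n_folds, n_units)
  concat_pred <- matrix(NA_real_, n, n_units)
  n_undefined <- 0L

  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (variant == "pls_monkey") {
      fit <- pls_fit(x[train, , drop = FALSE], y[train, , drop = FALSE], n_components)
      pred <- pls_predict(fit, x[test, , drop = FALSE])
    } else {
      b <- ols_fit(x[train, , drop = FALSE], y[train, , drop = FALSE])
      pred <- ols_predict(b, x[test, , drop = FALSE])
    }
    concat_pred[test, ] <- pred
    for (u in seq_len(n_units)) {
      yt <- y[test, u]
      if (stats::sd(yt) == 0 || stats::sd(pred[, u]) == 0) {
        n_undefined <- n_undefined + 1L
      } else {
        fold_r[f, u] <- stats::cor(pred[, u], yt)
      }
    }
  }
  if (n_undefined > 0L) {
    warning(sprintf("%d fold/unit correlations undefined (zero variance); excluded", n_undefined))
  }
  per_unit_r <- if (aggregate == "per_fold_mean") {
    colMeans(fold_r, na.rm = TRUE)
  } else {
    vapply(seq_len(n_units), function(u) {
      if (stats::sd(concat_pred[, u]) == 0 || stats::sd(y[, u]) == 0) NA_real_
      else stats::cor(concat_pred[, u], y[, u])
    }, numeric(1))
  }
  names(per_unit_r) <- colnames(y)
  structure(
    list(
      per_unit_r = per_unit_r,
      median_r = stats::median(per_unit_r, na.rm = TRUE),
      n_folds = n_folds,
      n_pls_components = if (variant == "pls_monkey") n_components else NA_integer_,
      variant = variant,
      aggregate = aggregate,
      n_undefined_folds = n_undefined
    ),
    class = "encoding_result"
  )
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf(
    "<encoding_result: %s, %d folds, median r = %.4f over %d units>\n",
    x$variant, x$n_folds, x$median_r, length(x$per_unit_r)
  ))
  invisible(x)
}

#' Split-half reliability (noise ceiling) of multi-trial recordings
#'
#' Per unit, the Pearson correlation between stimulus-wise mean responses of
#' two random halves of the trial repeats, averaged over `n_splits` random
#' splits. With the Spearman-Brown correction (`2r / (1 + r)`, default on)
#' the value estimates the reliability of the full repeat-averaged response;
#' uncorrected, it estimates the reliability of half the repeats — for
#' responses with per-repeat signal-to-noise ratio `snr` and two repeats the
#' uncorrected expectation is `snr / (snr + 1)`.
#'
#' @param recordings `neural_recording_set` with `n_repeats >= 2`.
#' @param n_splits Number of random repeat splits to average over.
#' @param corrected Apply Spearman-Brown correction?
#' @param seed Seed for the split assignment.
#' @return A `reliability_set`: list with `per_unit_ceiling`, `n_splits`,
#'   `corrected`.
#' @export
split_half_reliability <- function(recordings, n_splits = 20L,
                                   corrected = TRUE, seed = 1L) {
  if (!inherits(recordings, "neural_recording_set")) stop("expected a neural_recording_set")
  R <- n_repeats(recordings)
  if (R < 2L) stop("reliability unavailable: need at least 2 trial repeats")
  vals <- recordings$values
  n_units <- dim(vals)[2L]
  with_seed(seed, {
    acc <- matrix(0, n_splits, n_units)
    for (s in seq_len(n_splits)) {
      perm <- sample.int(R)
      h1 <- perm[seq_len(R %/% 2L)]
      h2 <- perm[(R %/% 2L + 1L):R]
      m1 <- apply(vals[, , h1, drop = FALSE], c(1L, 2L), mean)
      m2 <- apply(vals[, , h2, drop = FALSE], c(1L, 2L), mean)
      acc[s, ] <- vapply(seq_len(n_units), function(u) {
        if (stats::sd(m1[, u]) == 0 && stats::sd(m2[, u]) == 0) 1
        else if (stats::sd(m1[, u]) == 0 || stats::sd(m2[, u]) == 0) NA_real_
        else stats::cor(m1[, u], m2[, u])
      }, numeric(1))
    }
    r <- colMeans(acc, na.rm = TRUE)
    if (corrected) r <- 2 * r / (1 + r)
    names(r) <- recordings$unit_ids
    structure(
      list(per_unit_ceiling = r, n_splits = n_splits, corrected = corrected),
      class = "reliability_set"
    )
  })
}

#' Ceiling-normalized encoding score
#'
#' Aggregates per-unit encoding correlations by their median, normalizes by
#' the median noise ceiling across units, and squares the quotient:
#' `(median r / median r_ceil)^2`, a coefficient of explained variance
#' relative to the noise ceiling.
#'
#' @param result An `encoding_result`.
#' @param reliability A `reliability_set` for the same units.
#' @return A single number.
#' @export
normalized_encoding_score <- function(result, reliability) {
  r_med <- result$median_r
  c_med <- stats::median(reliability$per_unit_ceiling, na.rm = TRUE)
  if (!(c_med > 0)) stop("normalized score undefined: median ceiling <= 0")
  (r_med / c_med)^2
}

#' Representational similarity analysis score
#'
#' Compares representational dissimilarity matrices (1 - Pearson correlation
#' between stimulus activation profiles) of two representations by Spearman
#' rank correlation of their upper triangles. Involves no parameter fitting.
#'
#' @param features `feature_matrix` (or matrix), stimuli x channels.
#' @param recordings `neural_recording_set` (repeat-averaged) or a stimuli x
#'   units matrix.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
rsa_score <- function(features, recordings) {
  x <- as_feature_values(features)
  y <- if (inherits(recordings, "neural_recording_set")) average_repeats(recordings)
       else as.matrix(recordings)
  if (nrow(x) != nrow(y)) stop("stimuli must align")
  if (nrow(x) < 3L) stop("RSA needs at least 3 stimuli")
  rdm_x <- rdm(x)
  rdm_y <- rdm(y)
  ut <- upper.tri(rdm_x)
  stats::cor(rdm_x[ut], rdm_y[ut], method = "spearman")
}

rdm <- function(x) {
  if (any(apply(x, 1L, stats::sd) == 0)) {
    stop("undefined dissimilarity: constant stimulus rows")
  }
  1 - stats::cor(t(x))
}
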