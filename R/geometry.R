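#' Eigenspectrum of a feature matrix
#'
#' Principal-component variances of the column-centered sample covariance of a
#' stimuli x channels feature matrix, computed via singular value decomposition
#' of the centered data (numerically stabler than forming the covariance for
#' wide matrices). Eigenvalues use the n-1 sample-variance denominator and are
#' returned sorted in decreasing order, zero-padded to `n_channels` so that the
#' spectrum length always equals the ambient channel count.
#'
#' @param features A `feature_matrix` or a plain numeric matrix
#'   (stimuli x channels) with at least 2 rows.
#' @return Numeric vector of length `ncol(features)`: eigenvalues
#'   `lambda_1 >= lambda_2 >= ... >= 0`.
#' @examples
#' x <- matrix(c(0, 0, 2, 0), nrow = 2, byrow = TRUE)
#' compute_eigenspectrum(x) # c(2, 0)
#' @export
compute_eigenspectrum <- function(features) {
  x <- as_feature_values(features)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) stop("eigenspectrum requires at least 2 stimuli")
  xc <- sweep(x, 2L, colMeans(x), "-")
  if (sum(xc^2) == 0) {
    stop("degenerate spectrum: features are constant (zero total variance)")
  }
  d <- svd(xc, nu = 0, nv = 0)$d
  lambdas <- d^2 / (n - 1)
  # rank of centered data is at most min(n - 1, p); pad with exact zeros
  k <- min(n - 1L, p)
  lambdas <- lambdas[seq_len(min(k, length(lambdas)))]
  out <- numeric(p)
  out[seq_along(lambdas)] <- lambdas
  sort(out, decreasing = TRUE)
}

#' Effective dimensionality (participation ratio)
#'
#' ED = (sum_i lambda_i)^2 / sum_i lambda_i^2, a continuous estimate of how
#' many principal components carry the variance of a representation. Equal
#' variance along all n directions gives ED = n; variance concentrated on one
#' direction gives ED = 1. Scale- and permutation-invariant.
#'
#' @param spectrum Numeric vector of nonnegative eigenvalues (order
#'   irrelevant), or a `feature_matrix`, in which case its eigenspectrum is
#'   computed first.
#' @return A single number in `[1, n_nonzero]`.
#' @examples
#' effective_dimensionality(c(1, 1, 1)) # 3
#' effective_dimensionality(c(4, 2, 1)) # 49/21
#' @export
effective_dimensionality <- function(spectrum) {
  if (is.matrix(spectrum) || inherits(spectrum, "feature_matrix")) {
    spectrum <- compute_eigenspectrum(spectrum)
  }
  lam <- as.numeric(spectrum)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("spectrum must be finite and nonnegative")
  }
  s <- sum(lam)
  if (s <= 0) stop("effective dimensionality undefined for an all-zero spectrum")
  s^2 / sum(lam^2)
}

#' Analytic participation ratio of a truncated power-law spectrum
#'
#' For lambda_i = i^(-alpha), i = 1..n, returns
#' (sum i^-alpha)^2 / (sum i^-2alpha): the population ED a power-law
#' generator targets.
#'
#' @param alpha Nonnegative decay exponent.
#' @param n Number of components.
#' @export
power_law_ed <- function(alpha, n) {
  i <- seq_len(n)
  sum(i^(-alpha))^2 / sum(i^(-2 * alpha))
}

#' Global average pooling of convolutional feature maps
#'
#' Collapses a stimuli x channels x height x width activation array to a
#' stimuli x channels matrix by averaging over the two spatial dimensions, so
#' that downstream dimensionality estimates reflect channel covariance (the
#' diversity of encoded image features) rather than spatial covariance.
#'
#' @param maps A 4-way numeric array `[n_stimuli, n_channels, height, width]`
#'   or a `feature_map_set`.
#' @return A `feature_matrix` of shape n_stimuli x n_channels.
#' @export
global_average_pool <- function(maps) {
  a <- if (inherits(maps, "feature_map_set")) maps$values else maps
  if (!(is.array(a) && length(dim(a)) == 4L)) {
    stop("global_average_pool expects a 4-way array (stimuli x channels x height x width)")
  }
  pooled <- apply(a, c(1L, 2L), mean)
  ids <- dimnames(a)[[1L]]
  if (is.null(ids)) ids <- pad_ids(nrow(pooled))
  feature_matrix(pooled, stimulus_ids = ids)
}

#' Fit a power law to an eigenspectrum
#'
#' Least-squares slope of log(lambda_i) against log(i) over a contiguous index
#' range. The exponent is reported with a positive sign for decaying spectra:
#' lambda_i proportional to 1/i yields exponent 1, the reference decay rate at
#' which representations are maximally expressive while remaining smooth.
#'
#' @param spectrum Numeric eigenvalue vector, sorted decreasing.
#' @param fit_range Integer vector `c(start, end)` of component indices
#'   (inclusive); must contain at least 3 indices, all with positive
#'   eigenvalues.
#' @return A list of class `power_law_fit` with elements `exponent`,
#'   `fit_range`, and `goodness` (R-squared of the log-log regression).
#' @examples
#' fit_power_law(1 / (1:50), c(1, 50))$exponent # 1
#' @export
fit_power_law <- function(spectrum, fit_range = c(1L, length(spectrum))) {
  lam <- as.numeric(spectrum)
  start <- as.integer(fit_range[1L])
  end <- as.integer(fit_range[2L])
  if (start < 1L || end > length(lam) || end - start + 1L < 3L) {
    stop("fit_range must lie within the spectrum and span at least 3 components")
  }
  idx <- start:end
  if (any(lam[idx] <= 0)) {
    stop("invalid range: zero or negative eigenvalue inside fit_range")
  }
  fit <- stats::lm.fit(cbind(1, log(idx)), log(lam[idx]))
  slope <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  y <- log(lam[idx])
  ss_tot <- sum((y - mean(y))^2)
  goodness <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(exponent = -slope, fit_range = c(start, end), goodness = goodness),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: lambda_i ~ i^(-%.4f) over components %d..%d (R^2 = %.3f)\n",
    x$exponent, x$fit_range[1L], x$fit_range[2L], x$goodness
  ))
  invisible(x)
}
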