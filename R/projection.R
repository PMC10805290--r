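# Projection-distance concentration analysis: how tightly class samples
# project around their centroid along between-class readout directions, and
# why this tightens as latent dimensionality grows (concentration of
# measure).

#' Between-class readout vector
#'
#' The unit-length difference of class centroids,
#' `w = (mu_i - mu_j) / ||mu_i - mu_j||` — the direction along which a
#' prototype classifier separates classes i and j.
#'
#' @param xi,xj Sample matrices (rows = samples) for classes i and j.
#' @return Unit-norm numeric vector.
#' @export
readout_vector <- function(xi, xj) {
  mu_i <- colMeans(as.matrix(xi))
  mu_j <- colMeans(as.matrix(xj))
  diff <- mu_i - mu_j
  nrm <- sqrt(sum(diff^2))
  if (nrm == 0) stop("identical centroids: readout vector undefined")
  diff / nrm
}

#' Projection distances of class samples along a readout direction
#'
#' Per sample k of class i: `p_k = |(x_k - mu_i) . w|`, the absolute
#' centered projection onto the readout vector.
#'
#' @param xi Sample matrix for class i.
#' @param w Readout vector (same dimension as the feature space).
#' @return Nonnegative numeric vector, one entry per sample.
#' @export
projection_distances <- function(xi, w) {
  x <- as.matrix(xi)
  if (ncol(x) != length(w)) stop("dimension mismatch between samples and readout vector")
  mu <- colMeans(x)
  abs(as.vector(sweep(x, 2L, mu, "-") %*% w))
}

#' Category subspace radius
#'
#' Square root of the mean per-dimension variance of a class's samples — a
#' scale factor quantifying the class cloud's size, used to normalize
#' projection distances across representations with different feature scales.
#'
#' @param xi Sample matrix with at least 2 rows.
#' @return A nonnegative number.
#' @export
subspace_radius <- function(xi) {
  x <- as.matrix(xi)
  if (nrow(x) < 2L) stop("radius undefined for a single sample")
  sqrt(mean(apply(x, 2L, stats::var)))
}

#' Pairwise matrix of mean normalized projection distances
#'
#' Entry (i, j), i != j: the mean of class i's projection distances along the
#' i-vs-j readout vector, divided by class i's subspace radius. The matrix is
#' not symmetric (row class supplies both the samples and the radius); the
#' diagonal is undefined and stored as `NA`.
#'
#' @param data A `category_samples` with at least 2 classes, each with at
#'   least 2 samples.
#' @return A `projection_matrix`: M x M numeric matrix with `NA` diagonal and
#'   class ids as dimnames.
#' @export
projection_matrix <- function(data) {
  labels <- as.factor(data$labels)
  x <- as_feature_values(data$features)
  classes <- levels(labels)
  M <- length(classes)
  if (M < 2L) stop("need at least 2 classes")
  by_class <- lapply(classes, function(cl) x[labels == cl, , drop = FALSE])
  radii <- vapply(by_class, subspace_radius, numeric(1))
  if (any(radii == 0)) stop("degenerate class with zero radius: normalized distances undefined")
  out <- matrix(NA_real_, M, M, dimnames = list(classes, classes))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (i == j) next
      w <- readout_vector(by_class[[i]], by_class[[j]])
      out[i, j] <- mean(projection_distances(by_class[[i]], w)) / radii[i]
    }
  }
  class(out) <- c("projection_matrix", class(out))
  out
}

#' Mean off-diagonal normalized projection distance
#'
#' Summary statistic of a [projection_matrix()]: the mean over all ordered
#' off-diagonal pairs. Decreases as the latent dimensionality of the class
#' clouds grows.
#'
#' @param pmat A `projection_matrix`.
#' @export
mean_projection_distance <- function(pmat) {
  mean(pmat[row(pmat) != col(pmat)])
}

#' Concentration of projections of a uniform ball
#'
#' Demonstrates the concentration-of-measure phenomenon: points sampled
#' uniformly in the volume of a unit-radius sphere of dimensionality d,
#' projected along a random unit vector, concentrate around 0 as d grows.
#' For d = 1 the mean absolute projection is 1/2; for d = 2 it is
#' 4 / (3 * pi).
#'
#' @param d_list Integer vector of ball dimensionalities.
#' @param n_samples Points per dimensionality.
#' @param seed Integer seed.
#' @param probs Quantiles to report.
#' @return Data frame with one row per d: `d`, `mean`, `se` (Monte Carlo
#'   standard error of the mean), and the requested quantiles.
#' @export
sphere_projection_demo <- function(d_list, n_samples = 10000L, seed = 1L,
                                   probs = c(0.25, 0.5, 0.75, 0.95)) {
  stopifnot(all(d_list >= 1))
  with_seed(seed, {
    rows <- lapply(d_list, function(d) {
      pts <- runif_ball(n_samples, d)
      w <- stats::rnorm(d)
      w <- w / sqrt(sum(w^2))
      p <- abs(as.vector(pts %*% w))
      qs <- stats::quantile(p, probs = probs, names = FALSE)
      out <- data.frame(d = d, mean = mean(p), se = stats::sd(p) / sqrt(n_samples))
      out[paste0("q", probs * 100)] <- as.list(qs)
      out
    })
    do.call(rbind, rows)
  })
}
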