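# Prototype-learning transfer: classify held-out stimuli from novel
# categories by the nearest class centroid (Euclidean), reporting accuracy
# and mean reciprocal rank.

#' Fit class prototypes
#'
#' Prototype learning rule: one centroid per class, the mean feature vector
#' of its training samples.
#'
#' @param train A `category_samples` object (or list with `features` and
#'   `labels`); every class needs at least one sample.
#' @return A `prototype_model`: list with `centroids` (M x channels) and
#'   `class_ids`.
#' @export
fit_prototypes <- function(train) {
  x <- as_feature_values(train$features)
  labels <- as.factor(train$labels)
  if (any(table(labels) < 1L)) stop("every class needs at least one training sample")
  classes <- levels(labels)
  centroids <- t(vapply(
    classes,
    function(cl) colMeans(x[labels == cl, , drop = FALSE]),
    numeric(ncol(x))
  ))
  if (any(!is.finite(centroids))) stop("non-finite centroid")
  structure(
    list(centroids = centroids, class_ids = classes),
    class = "prototype_model"
  )
}

#' Evaluate prototypes on labeled test samples
#'
#' Each test sample ranks the classes by ascending Euclidean distance to
#' their centroids. Accuracy is the fraction with the true class at rank 1;
#' mean reciprocal rank (MRR) averages 1/rank of the true class. Distance
#' ties are broken deterministically by class-id order and flagged.
#'
#' @param model A `prototype_model`.
#' @param test A `category_samples` with matching channels; its label levels
#'   must be a subset of the model's class ids.
#' @return A `transfer_result`: list with `accuracy`, `mrr`, `ranks`,
#'   `n_ties`.
#' @export
evaluate_prototypes <- function(model, test) {
  x <- as_feature_values(test$features)
  if (ncol(x) != ncol(model$centroids)) stop("test channels must match centroids")
  true_idx <- match(as.character(test$labels), model$class_ids)
  if (anyNA(true_idx)) stop("test labels not all present among model classes")
  # squared distances sample x class
  d2 <- outer(rowSums(x^2), rep(1, nrow(model$centroids))) -
    2 * x %*% t(model$centroids) +
    outer(rep(1, nrow(x)), rowSums(model$centroids^2))
  n_ties <- 0L
  ranks <- vapply(seq_len(nrow(x)), function(k) {
    d <- d2[k, ]
    if (anyDuplicated(signif(d, 12))) n_ties <<- n_ties + 1L
    ord <- order(d, seq_along(d))   # stable: ties broken by class-id order
    match(true_idx[k], ord)
  }, integer(1))
  structure(
    list(
      accuracy = mean(ranks == 1L),
      mrr = mean(1 / ranks),
      ranks = ranks,
      n_ties = n_ties
    ),
    class = "transfer_result"
  )
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result: accuracy %.3f, MRR %.3f>\n", x$accuracy, x$mrr))
  invisible(x)
}

#' Monte Carlo cross-validated prototype transfer
#'
#' Repeatedly splits each class into disjoint train/test subsets, fits
#' prototypes on the training samples, evaluates on the held-out samples, and
#' averages accuracy and MRR across iterations. Defaults mirror the standard
#' novel-category protocol: 50 training and 50 test samples per class over 10
#' Monte Carlo iterations.
#'
#' @param data `category_samples`; each class needs `n_train + n_test`
#'   samples.
#' @param n_train,n_test Per-class split sizes.
#' @param n_iterations Monte Carlo iterations.
#' @param seed Integer seed.
#' @return A `transfer_result` with aggregate `accuracy` and `mrr` plus
#'   `per_iteration` data frame and `n_iterations`.
#' @export
monte_carlo_transfer <- function(data, n_train = 50L, n_test = 50L,
                                 n_iterations = 10L, seed = 1L) {
  labels <- as.factor(data$labels)
  counts <- table(labels)
  if (any(counts < n_train + n_test)) {
    stop("every class needs at least n_train + n_test samples")
  }
  x <- as_feature_values(data$features)
  classes <- levels(labels)
  with_seed(seed, {
    per_iter <- data.frame(
      iteration = seq_len(n_iterations),
      accuracy = NA_real_, mrr = NA_real_
    )
    for (it in seq_len(n_iterations)) {
      train_rows <- integer(0); test_rows <- integer(0)
      for (cl in classes) {
        rows <- which(labels == cl)
        picked <- sample(rows, n_train + n_test)
        train_rows <- c(train_rows, picked[seq_len(n_train)])
        test_rows <- c(test_rows, picked[(n_train + 1L):(n_train + n_test)])
      }
      model <- fit_prototypes(list(features = x[train_rows, , drop = FALSE],
                                   labels = labels[train_rows]))
      res <- evaluate_prototypes(model, list(features = x[test_rows, , drop = FALSE],
                                             labels = labels[test_rows]))
      per_iter$accuracy[it] <- res$accuracy
      per_iter$mrr[it] <- res$mrr
    }
    structure(
      list(
        accuracy = mean(per_iter$accuracy),
        mrr = mean(per_iter$mrr),
        per_iteration = per_iter,
        n_iterations = n_iterations
      ),
      class = "transfer_result"
    )
  })
}
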