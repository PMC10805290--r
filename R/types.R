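#' Feature matrix container
#'
#' A stimuli x channels activation matrix with ordered stimulus identifiers —
#' the universal model-side representation consumed by every analysis in the
#' package.
#'
#' @param values Numeric matrix, n_stimuli x n_channels, no missing values.
#' @param stimulus_ids Character vector of row identifiers; defaults to
#'   zero-padded integer strings.
#' @return An object of class `feature_matrix`: the matrix with stimulus ids
#'   as rownames.
#' @export
feature_matrix <- function(values, stimulus_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) stop("feature values must be finite, no NAs")
  if (nrow(values) < 2L) stop("a feature matrix needs at least 2 stimuli")
  if (ncol(values) < 1L) stop("a feature matrix needs at least 1 channel")
  if (is.null(stimulus_ids)) stimulus_ids <- pad_ids(nrow(values))
  if (length(stimulus_ids) != nrow(values)) stop("stimulus_ids length must match rows")
  rownames(values) <- as.character(stimulus_ids)
  if (is.null(colnames(values))) colnames(values) <- pad_ids(ncol(values), prefix = "ch")
  class(values) <- c("feature_matrix", class(values))
  values
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d stimuli x %d channels>\n", nrow(x), ncol(x)))
  invisible(x)
}

# Accept either a feature_matrix or a bare matrix everywhere.
as_feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) return(unclass(x))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Feature map container
#'
#' A 4-way stimuli x channels x height x width array of convolutional
#' activations, the input to [global_average_pool()].
#'
#' @param values Numeric 4-way array with all dimensions >= 1, finite values.
#' @export
feature_map_set <- function(values) {
  if (!(is.array(values) && length(dim(values)) == 4L)) {
    stop("feature maps must be a 4-way array")
  }
  if (any(!is.finite(values))) stop("feature map values must be finite")
  structure(list(values = values), class = "feature_map_set")
}

#' Neural recording container
#'
#' Stimuli x units x repeats response array. With `n_repeats >= 2`, repeats
#' support split-half reliability estimation; `n_repeats = 1` is allowed for
#' trial-averaged data.
#'
#' @param values Numeric 3-way array `[n_stimuli, n_units, n_repeats]` (a
#'   2-way matrix is promoted to a single repeat).
#' @param stimulus_ids,unit_ids Identifier vectors; default zero-padded
#'   integer strings.
#' @export
neural_recording_set <- function(values, stimulus_ids = NULL, unit_ids = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!(is.array(values) && length(dim(values)) == 3L)) {
    stop("recordings must be a stimuli x units x repeats array")
  }
  if (any(!is.finite(values))) stop("recording values must be finite")
  d <- dim(values)
  if (is.null(stimulus_ids)) stimulus_ids <- pad_ids(d[1L])
  if (is.null(unit_ids)) unit_ids <- pad_ids(d[2L], prefix = "u")
  if (length(stimulus_ids) != d[1L] || length(unit_ids) != d[2L]) {
    stop("identifier lengths must match array dimensions")
  }
  structure(
    list(
      values = values,
      stimulus_ids = as.character(stimulus_ids),
      unit_ids = as.character(unit_ids)
    ),
    class = "neural_recording_set"
  )
}

#' @export
print.neural_recording_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<neural_recording_set: %d stimuli x %d units x %d repeats>\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Number of trial repeats in a recording set
#' @param recordings A `neural_recording_set`.
#' @export
n_repeats <- function(recordings) dim(recordings$values)[3L]

#' Average recordings over trial repeats
#' @param recordings A `neural_recording_set`.
#' @return A stimuli x units numeric matrix.
#' @export
average_repeats <- function(recordings) {
  m <- apply(recordings$values, c(1L, 2L), mean)
  dimnames(m) <- list(recordings$stimulus_ids, recordings$unit_ids)
  m
}

#' Labeled category samples
#'
#' A feature matrix with one categorical label per stimulus; every class must
#' have at least 2 samples. Input to the transfer and projection analyses.
#'
#' @param features A `feature_matrix` (or numeric matrix).
#' @param labels Vector coercible to factor, one label per row of `features`.
#' @export
category_samples <- function(features, labels) {
  x <- as_feature_values(features)
  labels <- as.factor(labels)
  if (length(labels) != nrow(x)) stop("one label per stimulus required")
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 samples")
  structure(
    list(features = x, labels = labels),
    class = "category_samples"
  )
}

#' @export
print.category_samples <- function(x, ...) {
  cat(sprintf(
    "<category_samples: %d samples, %d classes, %d channels>\n",
    nrow(x$features), nlevels(x$labels), ncol(x$features)
  ))
  invisible(x)
}

pad_ids <- function(n, prefix = "") {
  width <- max(nchar(as.character(n)), 4L)
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}
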