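# Plain-text I/O for the two array types that cross tool boundaries.
# Feature matrices are 2-D CSV (header row = channel ids, first column =
# stimulus ids). Recordings are a long-format CSV (stimulus, unit, repeat,
# value), which round-trips the 3-way array without a binary container.

#' Write / read a feature matrix as CSV
#'
#' @param features A `feature_matrix`.
#' @param path Output file path.
#' @export
write_feature_csv <- function(features, path) {
  x <- as_feature_values(features)
  df <- data.frame(stimulus_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(stimulus_id = "character"))
  m <- as.matrix(df[, -1L, drop = FALSE])
  feature_matrix(m, stimulus_ids = df$stimulus_id)
}

#' Write / read a neural recording set as long-format CSV
#'
#' Columns: `stimulus_id`, `unit_id`, `repeat_idx`, `value`.
#'
#' @param recordings A `neural_recording_set`.
#' @param path Output file path.
#' @export
write_recording_csv <- function(recordings, path) {
  d <- dim(recordings$values)
  df <- data.frame(
    stimulus_id = rep(recordings$stimulus_ids, times = d[2L] * d[3L]),
    unit_id = rep(rep(recordings$unit_ids, each = d[1L]), times = d[3L]),
    repeat_idx = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    value = as.vector(recordings$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    stimulus_id = "character", unit_id = "character"
  ))
  stim <- unique(df$stimulus_id)
  units <- unique(df$unit_id)
  reps <- sort(unique(df$repeat_idx))
  vals <- array(NA_real_, dim = c(length(stim), length(units), length(reps)))
  idx <- cbind(
    match(df$stimulus_id, stim),
    match(df$unit_id, units),
    match(df$repeat_idx, reps)
  )
  vals[idx] <- df$value
  if (anyNA(vals)) stop("incomplete recording table: missing stimulus/unit/repeat cells")
  neural_recording_set(vals, stimulus_ids = stim, unit_ids = units)
}
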