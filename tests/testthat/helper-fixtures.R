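# Small deterministic fixtures shared across test files.

tiny_features <- function(n = 20, p = 5, seed = 101) {
  with_fixture_seed(seed, feature_matrix(matrix(rnorm(n * p), n, p)))
}

with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Random orthogonal p x p matrix for invariance tests.
random_rotation <- function(p, seed = 7) {
  with_fixture_seed(seed, qr.Q(qr(matrix(rnorm(p * p), p, p))))
}

# Brute-force RDM: pairwise 1 - Pearson r via explicit loops.
brute_rdm <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- 1 - cor(x[i, ], x[j, ])
    }
  }
  out
}
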