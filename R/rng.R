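# Seeding and random-geometry primitives shared by the generators and the
# subspace simulation.

# Evaluate expr under a local RNG state so generators are reproducible without
# clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive an operation-specific seed from a global seed
#'
#' Deterministically maps a global integer seed and an operation name to a
#' sub-seed below 2^31, so that each stochastic stage of a workflow draws from
#' its own reproducible stream.
#'
#' @param seed Global integer seed.
#' @param name Character tag of the operation.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483629L)
}

# Random n x k matrix with orthonormal columns (Haar-ish via QR of a Gaussian;
# signs fixed so the factorization is unique).
random_orthonormal <- function(n, k = n) {
  stopifnot(k <= n)
  qr_ <- qr(matrix(stats::rnorm(n * k), n, k))
  q <- qr.Q(qr_)
  r <- diag(qr.R(qr_))
  q * rep(sign(r + (r == 0)), each = n)
}

# n samples uniform in the d-ball of given radius: random direction times
# radius * U^(1/d). Exact and standard.
runif_ball <- function(n, d, radius = 1) {
  z <- matrix(stats::rnorm(n * d), n, d)
  norms <- sqrt(rowSums(z^2))
  norms[norms == 0] <- 1
  r <- radius * stats::runif(n)^(1 / d)
  z / norms * r
}
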