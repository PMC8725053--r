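# run code under a fixed RNG seed, restoring the caller's RNG state.
# `seed` is forced before the state is saved: a lazily evaluated seed
# expression may itself consume the caller's RNG stream, and that draw
# must not be undone by the restore.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Gauss-Legendre nodes/weights on [a, b] via Golub-Welsch
gauss_legendre <- function(n, a = -1, b = 1) {
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

# Gauss-Hermite quadrature re-expressed for a standard-normal weight:
# sum w_i f(x_i) approximates E[f(Z)], Z ~ N(0,1)
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2  # physicists' weights / sqrt(pi)
  ord <- order(x)
  list(nodes = sqrt(2) * x[ord], weights = w[ord])
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}
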