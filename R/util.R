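# Small numeric helpers shared across the package.

# Run code under a temporary RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) {
  neg <- x < 0
  if (any(neg)) x[neg] <- exp(x[neg]) - 1
  x
}

elu_grad <- function(x) {
  neg <- x < 0
  out <- x
  out[!neg] <- 1
  if (any(neg)) out[neg] <- exp(x[neg])
  out
}

leakyrelu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

leakyrelu_grad <- function(x, slope) {
  out <- rep.int(1, length(x))
  out[x < 0] <- slope
  out
}

# Glorot/fan-balanced uniform init
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

glorot_vec <- function(n) {
  lim <- sqrt(6 / (n + 1))
  stats::runif(n, -lim, lim)
}

# add a bias row-vector to every row of a matrix
addb <- function(m, b) m + matrix(b, nrow(m), ncol(m), byrow = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a
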