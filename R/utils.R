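## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Abort with a message assembled sprintf-style; keeps call noise out of errors.
pk_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

pk_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Coerce to a channels x samples matrix, accepting a bare vector as 1 channel.
as_channel_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

## Odd (antisymmetric) reflection padding about the end values, the standard
## edge treatment for zero-phase IIR filtering of long signals. `pad` is
## capped at n - 1, the longest single reflection the series supports; for
## short epochs relative to the filter's slowest time constant, use
## zero-padding of the demeaned epoch instead (see `zero_pad`).
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad <= 0L) {
    return(list(x = x, pad = 0L))
  }
  head_ref <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad)]
  list(x = c(head_ref, x, tail_ref), pad = pad)
}

## Demean-and-zero-pad edge treatment for short epochs: assumes the signal
## is zero outside the observed window (standard spectral practice), which
## injects no fabricated low-frequency content. The removed mean is not
## restored: the band-pass rejects DC anyway.
zero_pad <- function(x, pad) {
  pad <- as.integer(pad)
  if (pad <= 0L) return(list(x = x, pad = 0L))
  z <- rep(0, pad)
  list(x = c(z, x - mean(x), z), pad = pad)
}

## Symmetrize and floor the eigenvalues of a covariance estimate at `floor`.
make_psd <- function(S, floor = 0) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  (S2 + t(S2)) / 2
}

## Draw sub-seeds for independent random streams from one master seed.
derive_seeds <- function(seed, n) {
  stopifnot(is_count(n))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards so package randomness never leaks out.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
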