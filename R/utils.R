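# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the global RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Central-difference gradient of a scalar (or vector-valued) function.
fd_grad <- function(fn, x, h = 1e-4) {
  p <- length(x)
  f0 <- fn(x)
  out <- matrix(NA_real_, nrow = length(f0), ncol = p)
  for (k in seq_len(p)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    out[, k] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  if (nrow(out) == 1L) drop(out) else out
}

# Central-difference Hessian of a scalar function.
fd_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      xi <- x
      if (i == j) {
        xp <- x; xp[i] <- xp[i] + h
        xm <- x; xm[i] <- xm[i] - h
        H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / h^2
      } else {
        xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
        xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
        xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
        xmm <- x; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
        H[i, j] <- H[j, i] <- (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a
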