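# Independent numerical oracles used by the tests.

published_typical_params <- function(crrt = 0) {
  pk_params(3.79 * 0.44^crrt, 2.4, 8.56, 21.3)
}

# High-accuracy ODE integration of the two-compartment mass-balance
# system with zero-order infusions, integrated piecewise between infusion
# switch events so the forcing is exact.
ode_concentration <- function(p, doses, times, rtol = 1e-10) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  k <- micro_constants(p)
  rate_at <- function(t) {
    sum(doses$amount / doses$duration *
          (t >= doses$start_time & t < doses$start_time + doses$duration))
  }
  deriv <- function(t, y, parms) {
    rin <- rate_at(t)
    list(c(rin - (k["k10"] + k["k12"]) * y[1] + k["k21"] * y[2],
           k["k12"] * y[1] - k["k21"] * y[2]))
  }
  ev <- sort(unique(c(0, doses$start_time, doses$start_time + doses$duration,
                      times)))
  ev <- ev[ev <= max(times) + 1e-12]
  y <- c(A1 = 0, A2 = 0)
  out <- stats::setNames(numeric(length(times)), times)
  if (any(times == 0)) out[times == 0] <- 0
  for (i in seq_len(length(ev) - 1)) {
    seg <- c(ev[i], ev[i + 1])
    # integrate strictly inside the segment; forcing is constant there
    mid_ok <- seg[2] > seg[1] + 1e-12
    if (!mid_ok) next
    sol <- deSolve::lsoda(y, seg, deriv, parms = NULL,
                          rtol = rtol, atol = 1e-12)
    y <- sol[nrow(sol), c("A1", "A2")]
    hit <- which(abs(times - seg[2]) < 1e-12)
    if (length(hit)) out[hit] <- y[1] / p$V1
  }
  unname(out)
}

# Adaptive Gauss-Hermite quadrature (pracma nodes) for the per-subject
# marginal likelihood; independent of the package's Laplace machinery.
# Works for d = 1 or 2 active random effects.
agq_neg2ll <- function(spec, params, dataset, n_nodes = 9) {
  stopifnot(requireNamespace("pracma", quietly = TRUE))
  gh <- pracma::gaussHermite(n_nodes)
  d0 <- dataset$data
  obs <- d0[d0$EVID == 0 & d0$BLQ == 0, , drop = FALSE]
  dos <- d0[d0$EVID == 1, , drop = FALSE]
  ids <- sort(unique(obs$ID))
  om <- unname(params[paste0("omega2_", spec$iiv)])
  act <- spec$iiv[om > 1e-10]
  om <- om[om > 1e-10]
  d <- length(act)
  sig2 <- params[["sigma2"]]
  total <- 0
  for (id in ids) {
    oi <- obs[obs$ID == id, , drop = FALSE]
    di <- dos[dos$ID == id, , drop = FALSE]
    doses <- dose_events(di$TIME, di$AMT, di$AMT / di$RATE)
    crrt <- oi$CRRT[1]
    logy <- log(oi$DV)
    predfun <- function(eta) {
      e <- stats::setNames(rep(0, 2), c("cl", "v2"))
      e[act] <- eta
      cl <- params[["tvcl"]] *
        (if (spec$covariate == "crrt") params[["theta_crrt"]]^crrt else 1) *
        exp(e["cl"])
      p <- pk_params(cl, params[["tvv1"]], params[["tvv2"]] * exp(e["v2"]),
                     params[["tvq"]])
      log(pmax(concentration(p, doses, oi$TIME), 1e-12))
    }
    gfun <- function(eta) {
      r <- logy - predfun(eta)
      0.5 * (sum(r^2) / sig2 + length(r) * log(2 * pi * sig2)) +
        0.5 * (sum(eta^2 / om) + sum(log(om)) + d * log(2 * pi))
    }
    # center at the mode found by an independent optimizer
    mode <- if (d == 1) {
      stats::optimize(function(x) gfun(x), c(-5, 5))$minimum
    } else {
      stats::optim(rep(0, d), gfun, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000))$par
    }
    H <- fd_hess(gfun, mode)
    A <- t(chol(solve(H)))
    if (d == 1) {
      z <- matrix(gh$x, ncol = 1)
      w <- gh$w
    } else {
      z <- as.matrix(expand.grid(gh$x, gh$x))
      w <- as.numeric(outer(gh$w, gh$w))
    }
    vals <- vapply(seq_len(nrow(z)), function(j) {
      eta <- as.numeric(mode + sqrt(2) * A %*% z[j, ])
      exp(-gfun(eta) + sum(z[j, ]^2))
    }, numeric(1))
    lik <- 2^(d / 2) * det(as.matrix(H))^(-0.5) * sum(w * vals)
    total <- total - 2 * log(lik)
  }
  total
}

fd_hess <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
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
  as.matrix(H)
}
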