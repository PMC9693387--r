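# Model-qualification diagnostics on synthetic datasets: a
# prediction-corrected visual predictive check (pcVPC) and conditional
# weighted residuals (CWRES) plus the usual PRED/IPRED quantities.

# Population predictions (eta = 0) at every non-BLQ observation row.
.pred_pop <- function(ed, model) {
  spec <- model_spec(2, if (model$fixed$theta_crrt != 1) "crrt" else "none",
                     iiv = c("cl", "v2"))
  th <- c(tvcl = model$fixed$tvcl, tvv1 = model$fixed$tvv1,
          tvv2 = model$fixed$tvv2, tvq = model$fixed$tvq,
          theta_crrt = model$fixed$theta_crrt)
  p <- .subject_params(ed, spec, th, matrix(0, ed$n, 0), character(0))
  exp(.pred_log(ed, spec, p$CL, p$V1, p$V2, p$Q))
}

# Time since the most recent dose for each observation row.
.time_since_dose <- function(dataset) {
  d <- dataset$data
  obs <- d[d$EVID == 0 & d$BLQ == 0, , drop = FALSE]
  tsld <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    starts <- d$TIME[d$EVID == 1 & d$ID == obs$ID[i] & d$TIME <= obs$TIME[i]]
    tsld[i] <- obs$TIME[i] - if (length(starts)) max(starts) else 0
  }
  tsld
}

# Quantile bin edges on time-since-dose, merging bins with < 3 obs.
.vpc_bins <- function(tsld, bins) {
  edges <- unique(stats::quantile(tsld, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 2) edges <- range(tsld) + c(-1e-9, 1e-9)
  edges[1] <- edges[1] - 1e-9
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  bin <- cut(tsld, edges, labels = FALSE)
  repeat {
    tab <- tabulate(bin, length(edges) - 1)
    small <- which(tab > 0 & tab < 3)
    if (!length(small)) break
    j <- small[1]
    drop_edge <- if (j == 1) 2L else j
    warning("VPC bin with < 3 observations merged with its neighbor",
            call. = FALSE)
    edges <- edges[-drop_edge]
    if (length(edges) < 2) break
    bin <- cut(tsld, edges, labels = FALSE)
  }
  list(edges = edges, bin = bin)
}

#' Prediction-corrected visual predictive check
#'
#' Observations are prediction-corrected by scaling with the ratio of the
#' bin-median population prediction to each observation's own population
#' prediction, and the same correction is applied to `n_sim` datasets
#' simulated from the model at the observed design. Per time bin the
#' 5th/50th/95th percentiles of the corrected observations are compared
#' with 95% confidence intervals of the same percentiles across simulated
#' replicates, and the fraction of observations falling outside the
#' pooled simulated 5th-95th band is reported (about 10% is expected when
#' the model generated the data).
#'
#' @param dataset A `study_dataset` sharing its design with `model`.
#' @param model A [population_model()] used for simulation and for the
#'   population predictions.
#' @param n_sim Number of simulated replicate datasets (>= 100).
#' @param bins Number of quantile-based bins on time since last dose.
#' @param seed Optional integer seed.
#' @return An object of class `vpc_result`: `bins` (per-bin summary
#'   `data.frame`), `outside_fraction`, `pc_obs` (corrected
#'   observations), `n_sim`, `seed`.
#' @export
pcvpc <- function(dataset, model, n_sim = 500, bins = 6, seed = NULL) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(model, "population_model"))
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  ed <- .est_data(dataset)
  pred <- .pred_pop(ed, model)
  obs <- exp(ed$logy)
  tsld <- .time_since_dose(dataset)
  bn <- .vpc_bins(tsld, bins)
  bin <- bn$bin
  nb <- length(bn$edges) - 1
  med_pred <- vapply(seq_len(nb), function(b) stats::median(pred[bin == b]),
                     numeric(1))
  pc_obs <- obs * med_pred[bin] / pred

  # simulate replicates at the observed design: new etas per subject,
  # new residuals per observation; PRED (and hence the correction) is
  # unchanged across replicates
  fx <- model$fixed; re <- model$random
  N <- ed$N
  sim_pc <- matrix(NA_real_, N, n_sim)
  with_seed(seed, {
    spec2 <- model_spec(2, "crrt", c("cl", "v2"))
    th <- c(tvcl = fx$tvcl, tvv1 = fx$tvv1, tvv2 = fx$tvv2, tvq = fx$tvq,
            theta_crrt = fx$theta_crrt)
    for (r in seq_len(n_sim)) {
      eta <- cbind(stats::rnorm(ed$n, 0, sqrt(re$omega2_cl)),
                   stats::rnorm(ed$n, 0, sqrt(re$omega2_v2)))
      p <- .subject_params(ed, spec2, th, eta, c("cl", "v2"))
      f <- exp(.pred_log(ed, spec2, p$CL, p$V1, p$V2, p$Q))
      dv <- f * exp(stats::rnorm(N, 0, sqrt(re$sigma2)))
      sim_pc[, r] <- dv * med_pred[bin] / pred
    }
  })

  qs <- c(0.05, 0.5, 0.95)
  out_rows <- vector("list", nb)
  outside <- logical(N)
  for (b in seq_len(nb)) {
    sel <- bin == b
    pooled <- as.numeric(sim_pc[sel, , drop = FALSE])
    band <- stats::quantile(pooled, c(0.05, 0.95))
    outside[sel] <- pc_obs[sel] < band[1] | pc_obs[sel] > band[2]
    obs_q <- stats::quantile(pc_obs[sel], qs)
    rep_q <- apply(sim_pc[sel, , drop = FALSE], 2, stats::quantile, qs)
    ci_lo <- apply(rep_q, 1, stats::quantile, 0.025)
    ci_hi <- apply(rep_q, 1, stats::quantile, 0.975)
    out_rows[[b]] <- data.frame(
      bin = b, t_lo = bn$edges[b], t_hi = bn$edges[b + 1],
      n_obs = sum(sel),
      obs_p5 = obs_q[1], obs_p50 = obs_q[2], obs_p95 = obs_q[3],
      sim_p5_lo = ci_lo[1], sim_p5_hi = ci_hi[1],
      sim_p50_lo = ci_lo[2], sim_p50_hi = ci_hi[2],
      sim_p95_lo = ci_lo[3], sim_p95_hi = ci_hi[3],
      band_lo = band[1], band_hi = band[2])
  }
  bins_df <- do.call(rbind, out_rows)
  rownames(bins_df) <- NULL
  structure(list(bins = bins_df, outside_fraction = mean(outside),
                 pc_obs = pc_obs, tsld = tsld, bin = bin,
                 n_sim = n_sim, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("pcVPC: %d bins, %d simulated replicates; %.1f%% of observations outside the simulated 5th-95th band\n",
              nrow(x$bins), x$n_sim, 100 * x$outside_fraction))
  invisible(x)
}

#' Conditional weighted residuals
#'
#' FOCE-linearized residuals on the log scale: per subject the marginal
#' mean is `logf(eta_hat) - J eta_hat` and the covariance
#' `J Omega J' + sigma2 I` with `J` the Jacobian of the log-predictions
#' at the empirical Bayes mode; residuals are decorrelated through the
#' Cholesky factor. With all variances at zero they reduce to ordinary
#' standardized residuals. Subjects with a singular covariance are
#' flagged with `NA` residuals and a warning.
#'
#' @param fit A converged `pk_fit`.
#' @param dataset The `study_dataset` the fit used.
#' @return Numeric vector of residuals, one per quantifiable observation
#'   (in dataset row order), with attribute `pred` (population
#'   log-predictions).
#' @export
cwres <- function(fit, dataset) {
  stopifnot(inherits(fit, "pk_fit"))
  ed <- .est_data(dataset)
  spec <- fit$spec
  th <- fit$estimates
  om_all <- th[paste0("omega2_", spec$iiv)]
  act <- spec$iiv[om_all > 1e-10]
  om <- unname(om_all[om_all > 1e-10])
  d <- length(act)
  sig2 <- th[["sigma2"]]
  eta <- if (d > 0) fit$eta else matrix(0, ed$n, 0)

  p <- .subject_params(ed, spec, th, eta, act)
  logf <- .pred_log(ed, spec, p$CL, p$V1, p$V2, p$Q)
  J <- matrix(0, ed$N, d)
  h <- 1e-4
  for (k in seq_len(d)) {
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    pp <- .subject_params(ed, spec, th, ep, act)
    pm <- .subject_params(ed, spec, th, em, act)
    J[, k] <- (.pred_log(ed, spec, pp$CL, pp$V1, pp$V2, pp$Q) -
                 .pred_log(ed, spec, pm$CL, pm$V1, pm$V2, pm$Q)) / (2 * h)
  }
  out <- rep(NA_real_, ed$N)
  for (i in seq_len(ed$n)) {
    sel <- ed$sub == i
    Ji <- J[sel, , drop = FALSE]
    mu <- logf[sel] - if (d > 0) as.numeric(Ji %*% eta[i, ]) else 0
    V <- diag(sig2, sum(sel)) +
      if (d > 0) Ji %*% diag(om, d) %*% t(Ji) else 0
    L <- tryCatch(t(chol(V)), error = function(e) NULL)
    if (is.null(L)) {
      warning(sprintf("singular conditional covariance for subject %s; flagged",
                      ed$ids[i]), call. = FALSE)
      next
    }
    out[sel] <- forwardsolve(L, ed$logy[sel] - mu)
  }
  # population predictions on the natural scale for plotting vs PRED
  p0 <- .subject_params(ed, spec, th, matrix(0, ed$n, max(d, 0)), act)
  attr(out, "pred") <- exp(.pred_log(ed, spec, p0$CL, p0$V1, p0$V2, p0$Q))
  out
}
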