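# Nonlinear mixed-effects estimation of the population model from a
# sparse-sampling study: a FOCE-with-interaction flavored marginal
# likelihood (per-subject Laplace approximation at the eta mode with a
# Gauss-Newton curvature), bounded quasi-Newton outer optimization on
# log-parameters, the likelihood-ratio covariate test used during model
# development, empirical-Bayes eta shrinkage, and a nonparametric
# case-resampling bootstrap for parameter uncertainty.
#
# The exponential residual model is handled by log-transforming
# observations and predictions (additive normal error on the log scale,
# constant variance), which makes the FOCE interaction term benign.

#' Estimation model specification
#'
#' @param n_compartments 1 or 2 (the one-compartment form is retained
#'   only as an estimation baseline).
#' @param covariate `"crrt"` for the power-model CRRT effect on CL
#'   (`CL = tvcl * theta_crrt^CRRT`), or `"none"`.
#' @param iiv Which parameters carry interindividual variability
#'   (subset of `c("cl", "v2")`; `"v2"` requires 2 compartments).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_compartments = 2, covariate = c("crrt", "none"),
                       iiv = c("cl", "v2")) {
  covariate <- match.arg(covariate)
  if (!n_compartments %in% c(1, 2)) {
    stop("n_compartments must be 1 or 2", call. = FALSE)
  }
  iiv <- match.arg(iiv, c("cl", "v2"), several.ok = TRUE)
  if (n_compartments == 1 && "v2" %in% iiv) {
    stop("IIV on V2 requires a two-compartment model", call. = FALSE)
  }
  structure(list(n_compartments = n_compartments, covariate = covariate,
                 iiv = iiv), class = "model_spec")
}

#' Parameter names of a model specification
#'
#' @param spec A [model_spec()].
#' @return Character vector of free parameter names in estimation order.
#' @export
spec_param_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  th <- if (spec$n_compartments == 2) {
    c("tvcl", "tvv1", "tvv2", "tvq")
  } else {
    c("tvcl", "tvv1")
  }
  if (spec$covariate == "crrt") th <- c(th, "theta_crrt")
  om <- paste0("omega2_", spec$iiv)
  c(th, om, "sigma2")
}

# ---- dataset preparation ----------------------------------------------

# Flattens a study_dataset into index vectors for fully vectorized
# prediction: every (observation, dose) pair becomes one expanded row with
# precomputed clamped infusion times, so only the parameters change across
# likelihood evaluations. BLQ observations are excluded from estimation.
.est_data <- function(dataset) {
  d <- dataset$data
  obs <- d[d$EVID == 0 & d$BLQ == 0, , drop = FALSE]
  dos <- d[d$EVID == 1, , drop = FALSE]
  if (!nrow(obs)) stop("dataset contains no quantifiable observations", call. = FALSE)
  ids <- sort(unique(obs$ID))
  sub <- match(obs$ID, ids)
  crrt <- vapply(ids, function(i) obs$CRRT[obs$ID == i][1], numeric(1))
  # expand obs x doses within subject
  eobs <- integer(0); et0 <- numeric(0); eamt <- numeric(0); edur <- numeric(0)
  for (j in seq_along(ids)) {
    dj <- dos[dos$ID == ids[j], , drop = FALSE]
    oj <- which(sub == j)
    if (!nrow(dj)) next
    eobs <- c(eobs, rep(oj, each = nrow(dj)))
    et0 <- c(et0, rep(dj$TIME, times = length(oj)))
    eamt <- c(eamt, rep(dj$AMT, times = length(oj)))
    edur <- c(edur, rep(dj$AMT / dj$RATE, times = length(oj)))
  }
  t_obs <- obs$TIME[eobs]
  tt <- pmax(t_obs - et0, 0)
  list(n = length(ids), ids = ids, sub = sub, crrt = crrt,
       t = obs$TIME, logy = log(obs$DV), n_i = tabulate(sub, length(ids)),
       eobs = eobs, esub = sub[eobs],
       tt = tt, u = pmax(tt - edur, 0), R0 = eamt / edur,
       N = nrow(obs))
}

# Log-predictions for all observations given per-subject structural
# parameters (vectors of length n).
.pred_log <- function(ed, spec, CL, V1, V2, Q) {
  i <- ed$esub
  if (spec$n_compartments == 2) {
    k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
    s <- k10 + k12 + k21
    disc <- s^2 - 4 * k10 * k21
    root <- sqrt(pmax(disc, 0))
    alpha <- (s + root) / 2
    beta <- (s - root) / 2
    beta <- ifelse(disc < 1e-12, beta * (1 - 1e-9), beta)
    cA <- (alpha - k21) / (alpha * (alpha - beta))
    cB <- (k21 - beta) / (beta * (alpha - beta))
    contrib <- (ed$R0 / V1[i]) *
      (cA[i] * (exp(-alpha[i] * ed$u) - exp(-alpha[i] * ed$tt)) +
         cB[i] * (exp(-beta[i] * ed$u) - exp(-beta[i] * ed$tt)))
  } else {
    k <- CL / V1
    contrib <- (ed$R0 / CL[i]) * (exp(-k[i] * ed$u) - exp(-k[i] * ed$tt))
  }
  conc <- rowsum(contrib, ed$eobs, reorder = TRUE)
  log(pmax(as.numeric(conc), 1e-12))
}

# Per-subject parameters under the spec, for an eta matrix (n x d).
.subject_params <- function(ed, spec, th, eta, act) {
  n <- ed$n
  e_cl <- if ("cl" %in% act) eta[, match("cl", act)] else 0
  e_v2 <- if ("v2" %in% act) eta[, match("v2", act)] else 0
  cov_mult <- if (spec$covariate == "crrt") th[["theta_crrt"]]^ed$crrt else 1
  CL <- th[["tvcl"]] * cov_mult * exp(e_cl)
  V1 <- rep(th[["tvv1"]], n)
  if (spec$n_compartments == 2) {
    V2 <- th[["tvv2"]] * exp(e_v2)
    Q <- rep(th[["tvq"]], n)
  } else {
    V2 <- Q <- NULL
  }
  list(CL = CL, V1 = V1, V2 = V2, Q = Q)
}

#' FOCE-type objective function value (-2 log likelihood)
#'
#' Marginal -2 log-likelihood of the study data under the model
#' specification, by per-subject Laplace approximation at the mode of the
#' random effects with a Gauss-Newton (FOCE-style) curvature. Random
#' effects whose variance is (numerically) zero are profiled out exactly,
#' in which case the value equals the closed-form log-normal residual
#' -2LL on log-transformed observations. Deterministic for fixed inputs.
#'
#' @param spec A [model_spec()].
#' @param params Named numeric vector over [spec_param_names()].
#' @param dataset A `study_dataset`.
#' @param eta_start Optional warm-start matrix of random-effect modes
#'   (n_subjects x n_active_etas).
#' @return The OFV (numeric scalar) with attributes `eta` (the modes),
#'   `by_subject` (per-subject contributions) and `pred_log`
#'   (log-predictions at the modes).
#' @export
neg2ll <- function(spec, params, dataset, eta_start = NULL) {
  ed <- if (inherits(dataset, "study_dataset")) .est_data(dataset) else dataset
  th <- params
  nm <- spec_param_names(spec)
  if (!all(nm %in% names(th))) {
    stop("params must be named over: ", paste(nm, collapse = ", "), call. = FALSE)
  }
  sig2 <- th[["sigma2"]]
  if (sig2 <= 0) stop("sigma2 must be > 0", call. = FALSE)
  om_all <- th[paste0("omega2_", spec$iiv)]
  act <- spec$iiv[om_all > 1e-10]
  om <- unname(om_all[om_all > 1e-10])
  d <- length(act)
  n <- ed$n

  obj_parts <- function(eta) {
    p <- .subject_params(ed, spec, th, eta, act)
    logf <- .pred_log(ed, spec, p$CL, p$V1, p$V2, p$Q)
    r <- ed$logy - logf
    rss <- as.numeric(rowsum(r^2, ed$sub, reorder = TRUE))
    quad <- if (d > 0) as.numeric((eta^2) %*% (1 / om)) else 0
    g <- 0.5 * (rss / sig2 + ed$n_i * log(2 * pi * sig2)) +
      0.5 * (quad + if (d > 0) sum(log(om)) + d * log(2 * pi) else 0)
    list(g = g, r = r, logf = logf)
  }

  if (d == 0L) {
    parts <- obj_parts(matrix(0, n, 0))
    ofv_i <- 2 * parts$g
    out <- sum(ofv_i)
    attr(out, "eta") <- matrix(0, n, 0)
    attr(out, "by_subject") <- ofv_i
    attr(out, "pred_log") <- parts$logf
    return(out)
  }

  eta <- if (!is.null(eta_start) && all(dim(eta_start) == c(n, d))) {
    eta_start
  } else {
    matrix(0, n, d)
  }
  h <- 1e-4
  parts <- obj_parts(eta)
  a11 <- a22 <- a12 <- NULL
  for (iter in seq_len(60L)) {
    # finite-difference Jacobian of log-predictions wrt each eta
    J <- vector("list", d)
    for (k in seq_len(d)) {
      ep <- eta; ep[, k] <- ep[, k] + h
      em <- eta; em[, k] <- em[, k] - h
      pp <- .subject_params(ed, spec, th, ep, act)
      pm <- .subject_params(ed, spec, th, em, act)
      J[[k]] <- (.pred_log(ed, spec, pp$CL, pp$V1, pp$V2, pp$Q) -
                   .pred_log(ed, spec, pm$CL, pm$V1, pm$V2, pm$Q)) / (2 * h)
    }
    g1 <- -as.numeric(rowsum(J[[1]] * parts$r, ed$sub)) / sig2 + eta[, 1] / om[1]
    a11 <- as.numeric(rowsum(J[[1]]^2, ed$sub)) / sig2 + 1 / om[1]
    if (d == 2L) {
      g2 <- -as.numeric(rowsum(J[[2]] * parts$r, ed$sub)) / sig2 + eta[, 2] / om[2]
      a22 <- as.numeric(rowsum(J[[2]]^2, ed$sub)) / sig2 + 1 / om[2]
      a12 <- as.numeric(rowsum(J[[1]] * J[[2]], ed$sub)) / sig2
      det <- a11 * a22 - a12^2
      s1 <- (a22 * g1 - a12 * g2) / det
      s2 <- (a11 * g2 - a12 * g1) / det
      step <- cbind(s1, s2)
    } else {
      step <- cbind(g1 / a11)
    }
    # damped Newton: per-subject step halving where g does not decrease
    lam <- rep(1, n)
    for (try in seq_len(8L)) {
      eta_new <- eta - lam * step
      parts_new <- obj_parts(eta_new)
      worse <- parts_new$g > parts$g + 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    if (any(worse)) {
      # no decrease for these subjects even at the smallest step: keep
      # their previous modes
      lam[worse] <- 0
      eta_new <- eta - lam * step
      parts_new <- obj_parts(eta_new)
    }
    moved <- max(abs(lam * step))
    gdrop <- max(parts$g - parts_new$g)
    eta <- eta_new
    parts <- parts_new
    if (moved < 1e-9 || gdrop < 1e-12) break
  }
  # log-determinant of the Gauss-Newton Hessian at the mode
  logdetH <- if (d == 2L) log(a11 * a22 - a12^2) else log(a11)
  ofv_i <- 2 * parts$g - d * log(2 * pi) + logdetH
  out <- sum(ofv_i)
  attr(out, "eta") <- eta
  attr(out, "by_subject") <- ofv_i
  attr(out, "pred_log") <- parts$logf
  out
}

# Default initial estimates: covariate-free published base values, a
# neutral covariate multiplier, and moderate variability.
.default_init <- function(spec) {
  init <- c(tvcl = 2.65, tvv1 = 2.53, tvv2 = 9.61, tvq = 20.8,
            theta_crrt = 0.8,
            omega2_cl = cv_to_omega2(69.4), omega2_v2 = cv_to_omega2(61),
            sigma2 = cv_to_omega2(49.7))
  init[spec_param_names(spec)]
}

#' Fit the population model by FOCE-type estimation
#'
#' Bounded quasi-Newton outer optimization of [neg2ll()] on
#' log-transformed parameters (bounds 1e-4 to 1e4 times the initial
#' values). Inner random-effect modes are warm-started across outer
#' iterations. Standard errors come from the observed-information
#' sandwich (per-subject score outer products between inverse Hessian
#' factors), falling back to the plain observed information when the
#' sandwich is singular.
#'
#' @param spec A [model_spec()].
#' @param dataset A `study_dataset` (>= 2 subjects).
#' @param init Optional named vector of initial estimates (natural
#'   scale, positive).
#' @param se Compute RSE%? Skipping it (`se = FALSE`) saves the Hessian
#'   evaluation in bulk refits (bootstrap, likelihood-ratio scans).
#' @param fix Optional character vector of parameter names to hold fixed
#'   at their initial values (as with NONMEM's `FIX`).
#' @param control Passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return An object of class `pk_fit`: estimates, `ofv`, `converged`,
#'   `rse` (%), `eta` (empirical Bayes modes), `shrinkage` (%),
#'   `iterations`, plus the spec and initial values.
#' @export
fit_model <- function(spec, dataset, init = NULL, se = TRUE, fix = NULL,
                      control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  ed <- .est_data(dataset)
  if (ed$n < 2) stop("at least 2 subjects are required", call. = FALSE)
  nm <- spec_param_names(spec)
  init <- if (is.null(init)) .default_init(spec) else init[nm]
  if (!is.null(fix) && !all(fix %in% nm)) {
    stop("fix must name parameters of the spec", call. = FALSE)
  }
  free <- setdiff(nm, fix)
  if (any(!is.finite(init)) || any(init < 0) || any(init[free] <= 0)) {
    stop("initial estimates must be positive (fixed variances may be 0)",
         call. = FALSE)
  }
  env <- new.env()
  env$eta <- NULL
  obj <- function(lp_free) {
    th <- init
    th[free] <- exp(lp_free)
    val <- tryCatch(neg2ll(spec, th, ed, eta_start = env$eta),
                    error = function(e) NA_real_)
    if (is.na(val) || !is.finite(val)) return(1e10)
    env$eta <- attr(val, "eta")
    as.numeric(val)
  }
  est <- init
  if (length(free)) {
    lp0 <- log(init[free])
    # forward-difference steps large enough to dominate the O(1e-10)
    # noise of the inner Laplace solve; factr 1e9 is ~2e-7 absolute OFV
    ctl <- utils::modifyList(list(maxit = 300, factr = 1e9,
                                  ndeps = rep(1e-5, length(lp0))), control)
    opt <- stats::optim(lp0, obj, method = "L-BFGS-B",
                        lower = lp0 - log(1e4), upper = lp0 + log(1e4),
                        control = ctl)
    est[free] <- exp(opt$par)
  } else {
    opt <- list(par = numeric(0), convergence = 0L,
                counts = c("function" = 1L), message = "all parameters fixed")
    se <- FALSE
  }
  final <- neg2ll(spec, est, ed, eta_start = env$eta)
  eta <- attr(final, "eta")
  act <- spec$iiv[est[paste0("omega2_", spec$iiv)] > 1e-10]
  colnames(eta) <- if (length(act)) paste0("eta_", act) else character(0)

  rse <- cov_mat <- NULL
  if (se) {
    hfun <- function(lp) obj(lp)
    H <- fd_hessian(hfun, opt$par, h = 1e-3)
    A <- H / 2  # observed information of logL in log-parameter space
    S <- tryCatch({
      per <- function(lp_free) {
        th <- init
        th[free] <- exp(lp_free)
        attr(neg2ll(spec, th, ed, eta_start = env$eta), "by_subject")
      }
      -0.5 * fd_grad(per, opt$par, h = 1e-3)  # subjects x params scores
    }, error = function(e) NULL)
    cov_mat <- tryCatch({
      Ainv <- solve(A)
      if (!is.null(S)) Ainv %*% crossprod(S) %*% Ainv else Ainv
    }, error = function(e) NULL)
    if (is.null(cov_mat) || any(!is.finite(diag(cov_mat))) ||
        any(diag(cov_mat) < 0)) {
      cov_mat <- tryCatch(solve(A), error = function(e) NULL)
    }
    if (!is.null(cov_mat)) {
      # log-scale SE is the relative SE of the natural-scale parameter
      rse <- stats::setNames(rep(NA_real_, length(nm)), nm)
      rse[free] <- 100 * sqrt(pmax(diag(cov_mat), 0))
    }
  }

  shr <- if (length(act)) {
    om <- est[paste0("omega2_", act)]
    pmin(pmax(100 * (1 - apply(eta, 2, stats::sd) / sqrt(om)), 0), 100)
  } else {
    numeric(0)
  }
  structure(list(spec = spec, estimates = est, ofv = as.numeric(final),
                 converged = opt$convergence == 0, rse = rse,
                 cov = cov_mat, eta = eta, shrinkage = shr,
                 iterations = unname(opt$counts["function"]), init = init,
                 message = opt$message, n_subjects = ed$n, n_obs = ed$N),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE-type fit (%d-compartment, covariate: %s): OFV = %.3f, %s\n",
              x$spec$n_compartments, x$spec$covariate, x$ofv,
              if (x$converged) "converged" else "NOT CONVERGED"))
  tab <- data.frame(estimate = signif(x$estimates, 4))
  if (!is.null(x$rse)) tab$rse_pct <- signif(x$rse, 3)
  print(tab)
  if (length(x$shrinkage)) {
    cat("eta shrinkage (%):",
        paste(sprintf("%s %.1f", names(x$shrinkage), x$shrinkage),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Likelihood-ratio test for the CRRT covariate
#'
#' Fits the nested base and covariate models and computes
#' `delta_ofv = OFV(base) - OFV(covariate)`. The covariate is
#' forward-selected when the drop exceeds 3.84 (chi-square, 1 df,
#' p < 0.05) and survives backward elimination when its removal raises
#' the OFV by more than 6.64 (p < 0.01).
#'
#' @param dataset A `study_dataset`.
#' @param base_spec,cov_spec Nested [model_spec()]s differing only in
#'   the covariate term.
#' @param ... Passed to [fit_model()].
#' @return A list: `delta_ofv`, `selected` (forward), `retained`
#'   (backward), and both fits.
#' @export
lrt_covariate <- function(dataset, base_spec, cov_spec, ...) {
  if (base_spec$n_compartments != cov_spec$n_compartments ||
      !identical(base_spec$iiv, cov_spec$iiv)) {
    stop("specs must be nested: same structural model and IIV terms",
         call. = FALSE)
  }
  fit_base <- fit_model(base_spec, dataset, se = FALSE, ...)
  fit_cov <- if (identical(base_spec, cov_spec)) {
    fit_base
  } else {
    fit_model(cov_spec, dataset, se = FALSE, ...)
  }
  delta <- fit_base$ofv - fit_cov$ofv
  list(delta_ofv = delta, selected = delta > 3.84, retained = delta > 6.64,
       fit_base = fit_base, fit_cov = fit_cov)
}

#' Empirical-Bayes eta shrinkage
#'
#' `100 * (1 - sd(EBE eta) / omega)` per random effect; near 0 with rich
#' individual data, near 100 when individual data carry no information.
#' Undefined (returned as `NA`) when the corresponding variance is zero.
#'
#' @param fit A `pk_fit`.
#' @return Named numeric vector of shrinkage percentages.
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  out <- stats::setNames(rep(NA_real_, length(fit$spec$iiv)),
                         paste0("eta_", fit$spec$iiv))
  for (k in colnames(fit$eta)) {
    om <- fit$estimates[[sub("eta_", "omega2_", k)]]
    if (om > 1e-10) {
      out[k] <- 100 * (1 - stats::sd(fit$eta[, k]) / sqrt(om))
    }
  }
  pmin(pmax(out, 0), 100)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Case resampling by subject with replacement; each resampled dataset is
#' refit and percentile (2.5-97.5%) intervals are formed per parameter.
#' Deterministic under a fixed seed. A warning is raised if more than 20%
#' of the bootstrap fits fail to converge.
#'
#' @param dataset A `study_dataset`.
#' @param spec A [model_spec()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed.
#' @param init Initial estimates passed to each refit.
#' @return A list: `ci` (data.frame with `lower`, `median`, `upper` per
#'   parameter), `estimates` (replicate matrix), `n_fail`, `flagged`.
#' @export
bootstrap_ci <- function(dataset, spec, n_boot = 100, seed = NULL,
                         init = NULL) {
  stopifnot(inherits(dataset, "study_dataset"), n_boot >= 1)
  ids <- unique(dataset$data$ID)
  nm <- spec_param_names(spec)
  with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, length(nm),
                   dimnames = list(NULL, nm))
    conv <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      pick <- sample(ids, length(ids), replace = TRUE)
      parts <- lapply(seq_along(pick), function(j) {
        sub <- dataset$data[dataset$data$ID == pick[j], , drop = FALSE]
        sub$ID <- j
        sub
      })
      bds <- structure(list(data = do.call(rbind, parts), subjects = NULL,
                            design = dataset$design,
                            model_name = dataset$model_name, seed = NULL),
                       class = "study_dataset")
      fit <- tryCatch(fit_model(spec, bds, init = init, se = FALSE),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        reps[b, ] <- fit$estimates
        conv[b] <- fit$converged
      }
    }
    n_fail <- sum(!conv)
    flagged <- n_fail > 0.2 * n_boot
    if (flagged) {
      warning(sprintf("%d of %d bootstrap fits failed to converge; CIs flagged",
                      n_fail, n_boot), call. = FALSE)
    }
    ok <- reps[conv, , drop = FALSE]
    ci <- data.frame(
      parameter = nm,
      lower = apply(ok, 2, stats::quantile, 0.025, na.rm = TRUE),
      median = apply(ok, 2, stats::quantile, 0.5, na.rm = TRUE),
      upper = apply(ok, 2, stats::quantile, 0.975, na.rm = TRUE),
      row.names = NULL)
    list(ci = ci, estimates = reps, n_fail = n_fail, flagged = flagged)
  })
}
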