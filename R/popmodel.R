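# Population parameter model: typical values with a CRRT covariate on
# clearance, lognormal interindividual variability on CL and V2, and an
# exponential residual-error model. The packaged "final" model carries
# the published estimates; the "base" (covariate-free) model is retained
# as the null model for likelihood-ratio testing.

#' Fixed effects of the population model
#'
#' @param tvcl Typical clearance (L/h).
#' @param tvv1 Typical central volume (L).
#' @param tvv2 Typical peripheral volume (L).
#' @param tvq Typical intercompartmental clearance (L/h).
#' @param theta_crrt Dimensionless multiplier on CL for subjects on CRRT
#'   (`CL = tvcl * theta_crrt^CRRT`); values below 1 reduce clearance.
#'   Defaults to 1 (no covariate effect).
#' @return An object of class `fixed_effects`.
#' @export
fixed_effects <- function(tvcl, tvv1, tvv2, tvq, theta_crrt = 1) {
  vals <- c(tvcl, tvv1, tvv2, tvq, theta_crrt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("fixed effects must be finite and strictly positive", call. = FALSE)
  }
  structure(list(tvcl = tvcl, tvv1 = tvv1, tvv2 = tvv2, tvq = tvq,
                 theta_crrt = theta_crrt), class = "fixed_effects")
}

#' Random-effect variances of the population model
#'
#' Variances on the log scale: `omega2_cl` and `omega2_v2` are the
#' interindividual variances of log CL and log V2; `sigma2` is the
#' variance of the exponential (log-scale additive) residual error.
#'
#' @param omega2_cl,omega2_v2,sigma2 Non-negative variances.
#' @return An object of class `random_effects`.
#' @export
random_effects <- function(omega2_cl, omega2_v2, sigma2) {
  vals <- c(omega2_cl, omega2_v2, sigma2)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("variance components must be finite and >= 0", call. = FALSE)
  }
  structure(list(omega2_cl = omega2_cl, omega2_v2 = omega2_v2,
                 sigma2 = sigma2), class = "random_effects")
}

#' Population model (fixed + random effects)
#'
#' @param fixed A [fixed_effects()] object.
#' @param random A [random_effects()] object.
#' @param name Optional model name.
#' @return An object of class `population_model`.
#' @export
population_model <- function(fixed, random, name = "model") {
  stopifnot(inherits(fixed, "fixed_effects"), inherits(random, "random_effects"))
  structure(list(fixed = fixed, random = random, name = name),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  f <- x$fixed; r <- x$random
  cat(sprintf("Population PK model '%s'\n", x$name))
  cat(sprintf("  TVCL = %.3g L/h, theta_CRRT = %.3g, V1 = %.3g L, V2 = %.3g L, Q = %.3g L/h\n",
              f$tvcl, f$theta_crrt, f$tvv1, f$tvv2, f$tvq))
  cat(sprintf("  omega2(CL) = %.4g, omega2(V2) = %.4g, sigma2 = %.4g\n",
              r$omega2_cl, r$omega2_v2, r$sigma2))
  invisible(x)
}

#' Convert a reported %CV to a log-scale variance
#'
#' Inverts the usual pharmacometric reporting convention
#' \eqn{\%CV \approx 100 \sqrt{\omega^2}}, i.e.
#' \eqn{\omega^2 = (CV/100)^2} -- not the exact lognormal
#' \eqn{CV = \sqrt{e^{\omega^2} - 1}}, whose difference is second order
#' at these magnitudes.
#'
#' @param cv_percent Coefficient of variation in percent, >= 0.
#' @return The log-scale variance.
#' @examples
#' cv_to_omega2(47.1) # 0.2218
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0)) {
    stop("cv_percent must be >= 0", call. = FALSE)
  }
  (cv_percent / 100)^2
}

#' Typical (population-predicted) structural parameters
#'
#' Applies the covariate model: `CL = tvcl * theta_crrt^crrt`; V1, V2 and
#' Q are the typical values (no covariates retained on volumes).
#'
#' @param model A [population_model()] (or [fixed_effects()]).
#' @param crrt CRRT status, 0 or 1.
#' @return A [pk_params()] object.
#' @examples
#' typical_params(final_model(), crrt = 1) # CL = 3.79 * 0.44 = 1.67 L/h
#' @export
typical_params <- function(model, crrt = 0) {
  fx <- if (inherits(model, "population_model")) model$fixed else model
  stopifnot(inherits(fx, "fixed_effects"))
  if (length(crrt) != 1L || !crrt %in% c(0, 1)) {
    stop("crrt must be 0 or 1", call. = FALSE)
  }
  pk_params(fx$tvcl * fx$theta_crrt^crrt, fx$tvv1, fx$tvv2, fx$tvq)
}

#' Sample individual parameters from the population model
#'
#' Draws `n` subjects with lognormal interindividual variability on CL
#' and V2 (`CL_i = CL_typical * exp(eta_CL)`, `eta ~ N(0, omega2)`,
#' independent); V1 and Q carry no interindividual variability.
#'
#' @param model A [population_model()].
#' @param n Number of subjects.
#' @param crrt CRRT status (scalar 0/1, or a length-`n` vector).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return A `data.frame` with columns `CL`, `V1`, `V2`, `Q`, `crrt`,
#'   `eta_cl`, `eta_v2`.
#' @export
sample_individuals <- function(model, n, crrt = 0, seed = NULL) {
  stopifnot(inherits(model, "population_model"), n >= 1)
  crrt <- rep_len(crrt, n)
  if (!all(crrt %in% c(0, 1))) stop("crrt must be 0 or 1", call. = FALSE)
  fx <- model$fixed; re <- model$random
  with_seed(seed, {
    eta_cl <- stats::rnorm(n, 0, sqrt(re$omega2_cl))
    eta_v2 <- stats::rnorm(n, 0, sqrt(re$omega2_v2))
    data.frame(CL = fx$tvcl * fx$theta_crrt^crrt * exp(eta_cl),
               V1 = fx$tvv1,
               V2 = fx$tvv2 * exp(eta_v2),
               Q = fx$tvq,
               crrt = crrt,
               eta_cl = eta_cl,
               eta_v2 = eta_v2)
  })
}

#' Apply exponential residual error to concentrations
#'
#' `y = conc * exp(eps)`, `eps ~ N(0, sigma2)`. Concentrations of exactly
#' zero are returned unchanged (a log-scale error is undefined at zero).
#'
#' @param conc Non-negative concentrations (mg/L).
#' @param sigma2 Log-scale residual variance.
#' @param seed Optional integer seed.
#' @return Perturbed concentrations.
#' @export
apply_residual <- function(conc, sigma2, seed = NULL) {
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  with_seed(seed, {
    eps <- stats::rnorm(length(conc), 0, sqrt(sigma2))
    ifelse(conc > 0, conc * exp(eps), 0)
  })
}

# ---- packaged parameter sets ------------------------------------------

.model_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fx <- fixed_effects(tvcl = j$tvcl, tvv1 = j$tvv1, tvv2 = j$tvv2,
                      tvq = j$tvq, theta_crrt = j$theta_crrt %||% 1)
  re <- random_effects(cv_to_omega2(j$cv_cl), cv_to_omega2(j$cv_v2),
                       cv_to_omega2(j$cv_ruv))
  population_model(fx, re, name = j$name %||% basename(path))
}

#' Packaged population models
#'
#' `final_model()` returns the final covariate model
#' (CL = 3.79 x 0.44^CRRT L/h, V1 = 2.4 L, V2 = 8.56 L, Q = 21.3 L/h,
#' IIV CV 47.1% on CL and 44% on V2, exponential residual CV 47.3%).
#' `base_model()` returns the covariate-free base model used as the null
#' in the likelihood-ratio test.
#'
#' @return A [population_model()].
#' @export
final_model <- function() {
  .model_from_json(system.file("extdata", "final_model.json",
                               package = "meropk", mustWork = TRUE))
}

#' @rdname final_model
#' @export
base_model <- function() {
  .model_from_json(system.file("extdata", "base_model.json",
                               package = "meropk", mustWork = TRUE))
}

#' Read / write a population model as JSON
#'
#' The on-disk format stores typical values plus %CV entries
#' (`cv_cl`, `cv_v2`, `cv_ruv`), mirroring how variance components are
#' usually reported.
#'
#' @param path JSON file path.
#' @param model A [population_model()].
#' @return `read_model()` returns a [population_model()];
#'   `write_model()` returns `path` invisibly.
#' @export
read_model <- function(path) .model_from_json(path)

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  fx <- model$fixed; re <- model$random
  jsonlite::write_json(list(name = model$name,
                            tvcl = fx$tvcl, tvv1 = fx$tvv1, tvv2 = fx$tvv2,
                            tvq = fx$tvq, theta_crrt = fx$theta_crrt,
                            cv_cl = 100 * sqrt(re$omega2_cl),
                            cv_v2 = 100 * sqrt(re$omega2_v2),
                            cv_ruv = 100 * sqrt(re$sigma2)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
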