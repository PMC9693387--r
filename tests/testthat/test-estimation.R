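# FOCE-type estimation: closed-form limits, quadrature-oracle agreement,
# parameter recovery, the covariate likelihood-ratio test, shrinkage and
# the bootstrap.

final_params <- function() {
  c(tvcl = 3.79, tvv1 = 2.4, tvv2 = 8.56, tvq = 21.3, theta_crrt = 0.44,
    omega2_cl = cv_to_omega2(47.1), omega2_v2 = cv_to_omega2(44),
    sigma2 = cv_to_omega2(47.3))
}

test_that("with no active etas the OFV is the closed-form lognormal -2LL", {
  m <- final_model()
  ds <- generate_study(study_design(5, 0.4, jitter_sd = 0), m, seed = 8)
  spec <- model_spec(2, "crrt")
  th <- final_params()
  th["omega2_cl"] <- 0
  th["omega2_v2"] <- 0
  got <- neg2ll(spec, th, ds)
  # independent closed form on log-transformed observations
  obs <- ds$data[ds$data$EVID == 0 & ds$data$BLQ == 0, ]
  r2 <- 0
  n <- 0
  for (id in unique(obs$ID)) {
    oi <- obs[obs$ID == id, ]
    di <- ds$data[ds$data$ID == id & ds$data$EVID == 1, ]
    p <- typical_params(population_model(
      fixed_effects(th["tvcl"], th["tvv1"], th["tvv2"], th["tvq"],
                    th["theta_crrt"]),
      m$random), oi$CRRT[1])
    pred <- concentration(p, dose_events(di$TIME, di$AMT, di$AMT / di$RATE),
                          oi$TIME)
    r2 <- r2 + sum((log(oi$DV) - log(pred))^2)
    n <- n + nrow(oi)
  }
  expected <- n * log(2 * pi * th[["sigma2"]]) + r2 / th[["sigma2"]]
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)
})

test_that("the generating parameters beat grossly perturbed ones", {
  m <- final_model()
  ds <- generate_study(rich_design(20), m, seed = 9)
  spec <- model_spec(2, "crrt")
  th <- final_params()
  bad <- th
  bad["tvcl"] <- th["tvcl"] * 2
  expect_lt(as.numeric(neg2ll(spec, th, ds)),
            as.numeric(neg2ll(spec, bad, ds)))
})

test_that("the Laplace OFV agrees with adaptive Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  m <- final_model()
  ds <- generate_study(study_design(5, 0.4, jitter_sd = 0), m, seed = 10)
  spec <- model_spec(2, "crrt")
  th <- final_params()
  expect_lt(abs(as.numeric(neg2ll(spec, th, ds)) -
                  agq_neg2ll(spec, th, ds, n_nodes = 9)), 0.5)
  # also at a second, off-truth parameter point
  th2 <- th
  th2["tvcl"] <- 3.0
  th2["omega2_cl"] <- 0.35
  expect_lt(abs(as.numeric(neg2ll(spec, th2, ds)) -
                  agq_neg2ll(spec, th2, ds, n_nodes = 9)), 0.5)
})

test_that("the noiseless limit reduces to curve fitting", {
  m <- final_model()
  m0 <- population_model(m$fixed, random_effects(0, 0, 1e-8), "tiny-noise")
  ds <- generate_study(rich_design(6, jitter_sd = 0), m0, seed = 12)
  spec <- model_spec(2, "crrt")
  init <- final_params() * c(rep(1.3, 5), 1, 1, 1)
  init["omega2_cl"] <- 1e-8
  init["omega2_v2"] <- 1e-8
  init["sigma2"] <- 1e-8
  fit <- fit_model(spec, ds, init = init, se = FALSE,
                   fix = c("omega2_cl", "omega2_v2", "sigma2"))
  for (k in c("tvcl", "tvv1", "tvv2", "tvq", "theta_crrt")) {
    expect_equal(unname(fit$estimates[k]), unname(final_params()[k]),
                 tolerance = 1e-3)
  }
})

test_that("starting at the truth converges at least as well as a perturbed start", {
  m <- final_model()
  ds <- generate_study(rich_design(12), m, seed = 13)
  spec <- model_spec(2, "crrt")
  fit_true <- fit_model(spec, ds, init = final_params(), se = FALSE)
  fit_pert <- fit_model(spec, ds, init = final_params() * 1.5, se = FALSE)
  expect_lte(fit_true$ofv, fit_pert$ofv + 0.5)
})

test_that("estimates are invariant to subject order", {
  m <- final_model()
  ds <- generate_study(rich_design(10), m, seed = 14)
  spec <- model_spec(2, "crrt")
  fit1 <- fit_model(spec, ds, se = FALSE)
  # relabel subjects in reverse order
  perm <- rev(sort(unique(ds$data$ID)))
  ds2 <- ds
  ds2$data$ID <- perm[match(ds$data$ID, sort(unique(ds$data$ID)))]
  ds2$data <- ds2$data[order(ds2$data$ID, ds2$data$TIME, ds2$data$EVID), ]
  fit2 <- fit_model(spec, ds2, se = FALSE)
  expect_equal(fit1$estimates, fit2$estimates, tolerance = 1e-3)
  expect_equal(fit1$ofv, fit2$ofv, tolerance = 1e-6)
})

test_that("the OFV is invariant to time-unit rescaling", {
  m <- final_model()
  ds <- generate_study(rich_design(8), m, seed = 15)
  spec <- model_spec(2, "crrt")
  th <- final_params()
  v_h <- as.numeric(neg2ll(spec, th, ds))
  # hours -> minutes: times x60, rates /60, clearances /60
  ds_min <- ds
  ds_min$data$TIME <- ds$data$TIME * 60
  ds_min$data$RATE <- ds$data$RATE / 60
  th_min <- th
  th_min[c("tvcl", "tvq")] <- th[c("tvcl", "tvq")] / 60
  v_min <- as.numeric(neg2ll(spec, th_min, ds_min))
  expect_equal(v_h, v_min, tolerance = 1e-8)
})

test_that("the CRRT covariate test has power at the published effect size", {
  m <- final_model()
  base_spec <- model_spec(2, "none")
  cov_spec <- model_spec(2, "crrt")
  des <- rich_design(20)
  sel <- vapply(1:20, function(s) {
    ds <- generate_study(des, m, seed = 1000 + s)
    lrt_covariate(ds, base_spec, cov_spec)$selected
  }, logical(1))
  expect_gte(mean(sel), 0.9)
})

test_that("the covariate test rarely selects a null covariate", {
  m <- final_model()
  m_null <- population_model(
    fixed_effects(3.79, 2.4, 8.56, 21.3, theta_crrt = 1), m$random, "null")
  base_spec <- model_spec(2, "none")
  cov_spec <- model_spec(2, "crrt")
  des <- rich_design(20)
  sel <- vapply(1:20, function(s) {
    ds <- generate_study(des, m_null, seed = 2000 + s)
    lrt_covariate(ds, base_spec, cov_spec)$selected
  }, logical(1))
  expect_lte(mean(sel), 0.15)
})

test_that("identical specs give a zero OFV difference", {
  m <- final_model()
  ds <- generate_study(rich_design(8), m, seed = 16)
  spec <- model_spec(2, "crrt")
  r <- lrt_covariate(ds, spec, spec)
  expect_equal(r$delta_ofv, 0)
  expect_false(r$selected)
  expect_error(lrt_covariate(ds, model_spec(1, "none", "cl"), spec), "nested")
})

test_that("eta shrinkage tracks the individual information content", {
  m <- final_model()
  rich <- generate_study(rich_design(40), m, seed = 17)
  spec <- model_spec(2, "crrt")
  fit_rich <- fit_model(spec, rich, init = final_params(), se = FALSE)
  shr_rich <- eta_shrinkage(fit_rich)
  expect_lt(shr_rich[["eta_cl"]], 40)
  # study-like sparse design still keeps CL shrinkage under 40%
  sparse <- generate_study(study_design(13, 7 / 13), m, seed = 18)
  fit_sparse <- fit_model(spec, sparse, init = final_params(), se = FALSE)
  expect_lt(eta_shrinkage(fit_sparse)[["eta_cl"]], 40)
  # a single observation per subject carries almost no individual signal
  single <- generate_study(study_design(20, 0.5), m, seed = 19)
  d <- single$data
  keep <- d$EVID == 1
  for (id in unique(d$ID)) {
    obs_i <- which(d$ID == id & d$EVID == 0 & d$BLQ == 0)
    keep[obs_i[2]] <- TRUE  # the 0.5 h sample
  }
  single$data <- d[keep, ]
  # empirical Bayes modes at the generating parameters: with one sample
  # per subject the EBEs collapse toward zero relative to omega
  fit_single <- fit_model(spec, single, init = final_params(), se = FALSE,
                          fix = spec_param_names(spec))
  shr_single <- eta_shrinkage(fit_single)
  expect_gt(shr_single[["eta_cl"]], 60)
  expect_gt(shr_single[["eta_v2"]], 50)
  expect_gt(min(shr_single), max(shr_rich))
})

test_that("the bootstrap is deterministic and collapses at n_boot = 1", {
  m <- final_model()
  ds <- generate_study(rich_design(8), m, seed = 20)
  spec <- model_spec(2, "crrt")
  b1 <- bootstrap_ci(ds, spec, n_boot = 1, seed = 5, init = final_params())
  expect_equal(b1$ci$lower, b1$ci$upper)
  expect_equal(b1$ci$lower, b1$ci$median)
  b2 <- bootstrap_ci(ds, spec, n_boot = 3, seed = 6, init = final_params())
  b3 <- bootstrap_ci(ds, spec, n_boot = 3, seed = 6, init = final_params())
  expect_identical(b2$estimates, b3$estimates)
  expect_true(all(b2$ci$lower <= b2$ci$upper))
})

test_that("bootstrap intervals bracket the generating clearance", {
  m <- final_model()
  ds <- generate_study(rich_design(24), m, seed = 21)
  spec <- model_spec(2, "crrt")
  b <- bootstrap_ci(ds, spec, n_boot = 20, seed = 7, init = final_params())
  ci <- b$ci[b$ci$parameter == "tvcl", ]
  expect_lt(ci$lower, 3.79)
  expect_gt(ci$upper, 3.79 * 0.8)
  expect_equal(b$n_fail, 0)
})
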