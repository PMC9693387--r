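# pcVPC calibration and CWRES standardization.

test_that("the prediction correction is the identity when PRED is flat", {
  m <- final_model()
  ds <- generate_study(study_design(30, 0), m, seed = 30)
  v <- pcvpc(ds, m, n_sim = 100, bins = 3, seed = 31)
  obs <- ds$data[ds$data$EVID == 0 & ds$data$BLQ == 0, ]
  # within each bin, pc-observations are obs x (bin-median PRED / PRED);
  # replacing PRED by a constant must give back the raw observations
  ed <- meropk:::.est_data(ds)
  pred <- meropk:::.pred_pop(ed, m)
  med <- as.numeric(tapply(pred, v$bin, stats::median))
  manual <- obs$DV * med[v$bin] / pred
  expect_equal(unname(v$pc_obs), manual, tolerance = 1e-12)
  flat <- as.numeric(v$pc_obs / (med[v$bin] / pred))
  expect_equal(flat, obs$DV, tolerance = 1e-12)
})

test_that("under the generating model about 10% of observations fall outside the band", {
  m <- final_model()
  ds <- generate_study(study_design(200, 0.5), m, seed = 32)
  v <- pcvpc(ds, m, n_sim = 300, bins = 6, seed = 33)
  expect_gt(v$outside_fraction, 0.05)
  expect_lt(v$outside_fraction, 0.16)
  # percentiles ordered per bin
  expect_true(all(v$bins$obs_p5 <= v$bins$obs_p50))
  expect_true(all(v$bins$obs_p50 <= v$bins$obs_p95))
})

test_that("a threefold clearance misspecification inflates the outside fraction", {
  m <- final_model()
  ds <- generate_study(study_design(100, 0.5), m, seed = 34)
  wrong <- population_model(
    fixed_effects(3.79 * 3, 2.4, 8.56, 21.3, 0.44), m$random, "mis")
  v_true <- pcvpc(ds, m, n_sim = 200, bins = 6, seed = 35)
  v_wrong <- pcvpc(ds, wrong, n_sim = 200, bins = 6, seed = 35)
  expect_gt(v_wrong$outside_fraction, 0.10)
  expect_gt(v_wrong$outside_fraction, v_true$outside_fraction)
})

test_that("scale-free VPC summaries are invariant to joint dose/observation scaling", {
  m <- final_model()
  ds <- generate_study(study_design(60, 0.5), m, seed = 36)
  k <- 2.5
  ds2 <- ds
  ds2$data$DV[ds2$data$EVID == 0] <- ds$data$DV[ds$data$EVID == 0] * k
  ds2$data$AMT[ds2$data$EVID == 1] <- ds$data$AMT[ds$data$EVID == 1] * k
  ds2$data$RATE[ds2$data$EVID == 1] <- ds$data$RATE[ds$data$EVID == 1] * k
  v1 <- pcvpc(ds, m, n_sim = 100, bins = 4, seed = 37)
  v2 <- pcvpc(ds2, m, n_sim = 100, bins = 4, seed = 37)
  expect_equal(v2$outside_fraction, v1$outside_fraction)
  expect_equal(v2$pc_obs / v1$pc_obs, rep(k, length(v1$pc_obs)),
               tolerance = 1e-10)
  expect_equal(v2$bins$obs_p50 / v1$bins$obs_p50, rep(k, nrow(v1$bins)),
               tolerance = 1e-10)
})

test_that("small bins are merged with a warning", {
  m <- final_model()
  ds <- generate_study(study_design(4, 0), m, seed = 38)
  expect_warning(pcvpc(ds, m, n_sim = 100, bins = 12, seed = 39), "merged")
})

test_that("CWRES are standardized under the true model and trend-free vs PRED", {
  m <- final_model()
  ds <- generate_study(study_design(100, 0.5), m, seed = 40)
  spec <- model_spec(2, "crrt")
  truth <- c(tvcl = 3.79, tvv1 = 2.4, tvv2 = 8.56, tvq = 21.3,
             theta_crrt = 0.44, omega2_cl = cv_to_omega2(47.1),
             omega2_v2 = cv_to_omega2(44), sigma2 = cv_to_omega2(47.3))
  fit <- fit_model(spec, ds, init = truth, se = FALSE)
  cw <- cwres(fit, ds)
  expect_equal(mean(cw), 0, tolerance = 0.1)
  expect_equal(stats::var(cw), 1, tolerance = 0.1)
  rho <- stats::cor(cw, attr(cw, "pred"), method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("with zero variances CWRES reduce to ordinary standardized residuals", {
  m <- final_model()
  ds <- generate_study(study_design(10, 0.5), m, seed = 41)
  spec <- model_spec(2, "crrt")
  th0 <- c(tvcl = 3.79, tvv1 = 2.4, tvv2 = 8.56, tvq = 21.3,
           theta_crrt = 0.44, omega2_cl = 0, omega2_v2 = 0,
           sigma2 = cv_to_omega2(47.3))
  fit <- fit_model(spec, ds, init = th0, se = FALSE,
                   fix = spec_param_names(spec))
  cw <- cwres(fit, ds)
  ed <- meropk:::.est_data(ds)
  pred <- attr(neg2ll(spec, th0, ds), "pred_log")
  manual <- (ed$logy - pred) / sqrt(th0[["sigma2"]])
  expect_equal(as.numeric(cw), manual, tolerance = 1e-10)
})
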