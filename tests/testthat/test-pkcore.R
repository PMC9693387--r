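# Closed-form two-compartment kinetics: reparameterization identities,
# analytic-vs-ODE agreement, superposition, mass balance.

test_that("micro constants follow the CL/V reparameterization", {
  p <- published_typical_params()
  k <- micro_constants(p)
  expect_equal(unname(k), c(1.5792, 8.8750, 2.4883), tolerance = 1e-4)
  k1 <- micro_constants(pk_params(1, 1, 1, 1))
  expect_equal(unname(k1), c(1, 1, 1))
  expect_error(pk_params(0, 2.4, 8.56, 21.3), "positive")
})

test_that("hybrid rates are the ordered characteristic roots", {
  k <- micro_constants(published_typical_params())
  ab <- hybrid_rates(k["k10"], k["k12"], k["k21"])
  expect_gt(ab["alpha"], ab["beta"])
  expect_gt(ab["beta"], 0)
  # sum/product identities
  expect_equal(unname(ab["alpha"] + ab["beta"]), unname(sum(k)),
               tolerance = 1e-10)
  expect_equal(unname(ab["alpha"] * ab["beta"]),
               unname(k["k10"] * k["k21"]), tolerance = 1e-10)
  expect_equal(unname(ab["alpha"] * ab["beta"]), 3.9295, tolerance = 1e-3)
  # decoupled limit k12 -> 0: roots approach max/min of (k10, k21)
  ab0 <- hybrid_rates(2, 1e-10, 0.5)
  expect_equal(unname(ab0), c(2, 0.5), tolerance = 1e-6)
  expect_error(hybrid_rates(-1, 1, 1), "positive")
})

test_that("concentration is causal, additive and needs sorted doses", {
  p <- published_typical_params()
  t <- c(0, 0.5, 2, 6)
  expect_equal(concentration(p, dose_events(numeric(0), numeric(0), numeric(0)), t),
               rep(0, 4))
  d <- dose_events(1, 1000, 1 / 3)
  expect_equal(concentration(p, d, c(0, 0.5, 0.999))[1:2], c(0, 0))
  expect_gt(concentration(p, d, 1.5), 0)
  unsorted <- dose_events(c(8, 0), 1000, 1 / 3)
  expect_error(concentration(p, unsorted, t), "sorted")
})

test_that("analytic solution matches a stiff ODE oracle at the published typical values", {
  skip_if_not_installed("deSolve")
  p <- published_typical_params(0)
  d <- dose_events(0, 1000, 1 / 3)
  t <- c(1 / 3, 1, 4, 8)
  expect_equal(concentration(p, d, t), ode_concentration(p, d, t),
               tolerance = 1e-6)
})

test_that("analytic solution matches the ODE oracle over random parameters and regimens", {
  skip_if_not_installed("deSolve")
  set.seed(101)
  base <- c(3.79, 2.4, 8.56, 21.3)
  for (i in 1:200) {
    mult <- exp(stats::runif(4, log(0.1), log(100)))
    p <- pk_params(base[1] * mult[1], base[2] * mult[2],
                   base[3] * mult[3], base[4] * mult[4])
    interval <- sample(c(6, 8, 12), 1)
    dur <- stats::runif(1, 0.2, interval)
    amt <- stats::runif(1, 250, 2000)
    nd <- sample(1:3, 1)
    d <- dose_events((seq_len(nd) - 1) * interval, amt, dur)
    t <- sort(stats::runif(4, 0.05, nd * interval))
    a <- concentration(p, d, t)
    o <- ode_concentration(p, d, t)
    expect_equal(a, o, tolerance = 1e-6,
                 label = sprintf("case %d analytic", i))
  }
})

test_that("multi-dose profiles obey superposition exactly", {
  p <- published_typical_params()
  reg <- regimen(1000, 8, "II")
  doses <- regimen_doses(reg)
  t <- seq(0, 24, by = 0.25)
  multi <- concentration(p, doses, t)
  single <- Reduce(`+`, lapply(seq_len(nrow(doses)), function(i) {
    concentration(p, doses[i, , drop = FALSE], t)
  }))
  expect_equal(multi, single, tolerance = 1e-10)
})

test_that("mass balance: CL x AUC(0->inf) recovers the dose", {
  p <- published_typical_params()
  d <- dose_events(0, 1000, 1 / 3)
  t <- sort(unique(c(seq(0, 2, by = 0.002), seq(2, 200, by = 0.02))))
  pr <- conc_profile(t, concentration(p, d, t))
  expect_equal(p$CL * auc(pr), 1000, tolerance = 1e-3)
})

test_that("continuous infusion reaches the Dose/(tau x CL) plateau", {
  p <- pk_params(1.67, 2.4, 8.56, 21.3)
  reg <- regimen(1000, 8, "CI", window = 120)
  pr <- pk_profile(p, reg)
  css <- 1000 / (8 * 1.67)
  expect_equal(tail(pr$conc, 1), css, tolerance = 5e-3)
  expect_equal(css, 74.85, tolerance = 1e-4)
})

test_that("profiles use an event-augmented grid and the right dose counts", {
  p <- published_typical_params()
  expect_equal(nrow(regimen_doses(regimen(1000, 8, "II"))), 3)
  expect_equal(nrow(regimen_doses(regimen(1000, 12, "II"))), 2)
  pr <- pk_profile(p, regimen(1000, 8, "II"))
  expect_true(any(abs(pr$times - 1 / 3) < 1e-12))   # end of 20-min infusion
  expect_true(any(abs(pr$times - (8 + 1 / 3)) < 1e-12))
  expect_equal(pr$conc[pr$times == 0], 0)
})

test_that("concentration increases strictly with dose amount", {
  p <- published_typical_params()
  t <- seq(0.1, 24, by = 0.5)
  lo <- concentration(p, dose_events(c(0, 8, 16), 500, 1 / 3), t)
  hi <- concentration(p, dose_events(c(0, 8, 16), 1000, 1 / 3), t)
  expect_true(all(hi[t > 0] > lo[t > 0]))
})

test_that("auc handles flat and degenerate profiles", {
  flat <- conc_profile(c(0, 24), c(5, 5))
  expect_equal(auc(flat), 120)
  expect_equal(auc(conc_profile(3, 7)), 0)
})

test_that("sim_profiles agrees with the per-subject path", {
  m <- final_model()
  params <- sample_individuals(m, 5, crrt = 0, seed = 7)
  reg <- regimen(1000, 8, "EI3")
  mat <- sim_profiles(params, reg, grid_step = 0.25)
  for (i in 1:5) {
    p <- pk_params(params$CL[i], params$V1[i], params$V2[i], params$Q[i])
    expect_equal(unname(mat$conc[i, ]),
                 concentration(p, regimen_doses(reg), mat$times),
                 tolerance = 1e-12)
  }
})

test_that("dose and profile CSV round-trips keep the stated columns", {
  d <- regimen_doses(regimen(1000, 8, "II"))
  f1 <- tempfile(fileext = ".csv")
  write_doses_csv(d, "s1", f1)
  back <- read.csv(f1)
  expect_named(back, c("subject_id", "time_h", "amount_mg", "duration_h"))
  expect_equal(back$time_h, d$start_time)
  pr <- pk_profile(published_typical_params(), regimen(1000, 8, "II"), grid_step = 1)
  f2 <- tempfile(fileext = ".csv")
  write_profile_csv(pr, "s1", f2)
  expect_named(read.csv(f2), c("subject_id", "time_h", "conc_mg_L"))
})
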