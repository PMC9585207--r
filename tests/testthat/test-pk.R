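# Two-compartment kinetics, transit-absorption simulation, NCA,
# superposition and relative bioavailability.

test_that("closed form matches an independent RK4 ODE integration", {
  d <- tramadol_disposition()
  ka <- 1.7; F <- 0.75; dose <- 50
  tt <- seq(0, 24, by = 0.5)
  cf <- simulate_two_compartment_oral(d, ka, F,
                                      list(dose_mg = dose,
                                           dose_times_h = 0), tt)
  # independent oracle: RK4 on the 3-state gut/central/peripheral system
  V <- d$Vc * d$body_weight_kg
  h <- 1e-3
  state <- c(F * dose, 0, 0)
  rhs <- function(x) c(-ka * x[1],
                       ka * x[1] - (d$k10 + d$k12) * x[2] + d$k21 * x[3],
                       d$k12 * x[2] - d$k21 * x[3])
  oracle <- numeric(length(tt)); oracle[1] <- 0
  t_now <- 0; i_out <- 2L
  while (i_out <= length(tt)) {
    k1 <- rhs(state); k2 <- rhs(state + h / 2 * k1)
    k3 <- rhs(state + h / 2 * k2); k4 <- rhs(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t_now <- t_now + h
    if (abs(t_now - tt[i_out]) < h / 2) {
      oracle[i_out] <- 1000 * state[2] / V
      i_out <- i_out + 1L
    }
  }
  rel <- abs(cf$conc_ng_ml[-1] - oracle[-1]) / oracle[-1]
  expect_lt(max(rel), 1e-6)
})

test_that("degenerate limits of the oral closed form", {
  # k12, k21 -> 0: one-compartment AUC = 1000 * F * Dose / (CL * weight)
  d1 <- disposition_params(Vc = 1.4776, k12 = 1e-9, k21 = 0.02,
                           CL = 0.06, body_weight_kg = 70)
  tt <- c(seq(0, 10, by = 0.02), seq(10.5, 2000, by = 0.5))
  pr <- simulate_two_compartment_oral(d1, 1.5, 0.8,
                                      list(dose_mg = 100,
                                           dose_times_h = 0), tt)
  auc <- sum(diff(tt) * (head(pr$conc_ng_ml, -1) +
                           tail(pr$conc_ng_ml, -1)) / 2)
  expect_equal(auc, 1000 * 0.8 * 100 / (0.06 * 70), tolerance = 1e-3)

  # very large ka: early concentration approaches the IV-bolus level
  d <- tramadol_disposition()
  pr2 <- simulate_two_compartment_oral(d, 5000, 1,
                                       list(dose_mg = 100,
                                            dose_times_h = 0),
                                       c(0, 0.005, 0.01))
  c0 <- 1000 * 100 / (d$Vc * 70)
  expect_equal(pr2$conc_ng_ml[3], c0, tolerance = 0.01)

  # coincident-eigenvalue guard flags instead of failing
  dco <- disposition_params(Vc = 1, k12 = 0.1, k21 = 0.1, CL = 0.1,
                            body_weight_kg = 70)
  lam <- osmoforge:::.macro_constants(dco)
  prco <- simulate_two_compartment_oral(dco, lam[["lambda1"]], 1,
                                        list(dose_mg = 10,
                                             dose_times_h = 0),
                                        seq(0, 10, 0.5))
  expect_true(attr(prco, "degenerate"))
  expect_true(all(is.finite(prco$conc_ng_ml)))
})

test_that("dose linearity holds for both simulators", {
  d <- tramadol_disposition()
  drug <- tramadol_drug()
  tt <- seq(0, 24, by = 1)
  p1 <- simulate_two_compartment_oral(d, 1.7, 0.75,
                                      list(dose_mg = 50, dose_times_h = 0),
                                      tt)
  p2 <- simulate_two_compartment_oral(d, 1.7, 0.75,
                                      list(dose_mg = 100, dose_times_h = 0),
                                      tt)
  expect_equal(p2$conc_ng_ml, 2 * p1$conc_ng_ml, tolerance = 1e-12)

  r1 <- release_input(0:16, pmin(0:16 / 16, 1), 95)
  r2 <- release_input(0:16, pmin(0:16 / 16, 1), 190)
  s1 <- transit_absorption_simulate(r1, drug, d, times = seq(0, 24, 1),
                                    F = 0.75, dt = 0.02)
  s2 <- transit_absorption_simulate(r2, drug, d, times = seq(0, 24, 1),
                                    F = 0.75, dt = 0.02)
  expect_equal(s2$conc_ng_ml, 2 * s1$conc_ng_ml, tolerance = 1e-9)
})

test_that("transit model conserves mass at every step", {
  d <- tramadol_disposition()
  drug <- tramadol_drug()
  rel <- release_input(0:16, pmin(0:16 / 16, 1), 190)
  sim <- transit_absorption_simulate(rel, drug, d,
                                     times = seq(0, 48, 0.5), F = 0.75,
                                     dt = 0.02)
  expect_lt(attr(sim, "mass_balance"), 1e-6)
  comps <- attr(sim, "compartments")
  expect_equal(sum(comps[-1]), comps[["released"]], tolerance = 1e-9)
})

test_that("fast-transit limit reproduces the first-order oral solution", {
  d <- tramadol_disposition()
  drug <- tramadol_drug()
  ka_eff <- 2 * drug$Peff_cm_s * 3600 / 1.75
  rel <- release_input(c(0, 0.01, 1), c(0, 1, 1), 100)
  cfg <- transit_config(n_intestinal = 3, transit_time_h = 0.02,
                        gastric_rate = 500, colon_scale = 1,
                        radius_cm = 1.75)
  tt <- seq(0, 24, by = 0.5)
  sim <- transit_absorption_simulate(rel, drug, d, cfg, times = tt,
                                     F = 0.75, dt = 5e-4)
  oral <- simulate_two_compartment_oral(d, ka_eff, 0.75,
                                        list(dose_mg = 100,
                                             dose_times_h = 0), tt)
  i <- which(tt >= 1)
  rel_diff <- abs(sim$conc_ng_ml[i] - oral$conc_ng_ml[i]) /
    oral$conc_ng_ml[i]
  expect_lt(max(rel_diff), 0.01)
})

test_that("controlled-release inputs delay and depress the peak", {
  d <- tramadol_disposition()
  drug <- tramadol_drug()
  tt <- seq(0, 48, by = 0.25)
  # 16-h zero-order release, 190 mg
  cr <- transit_absorption_simulate(
    release_input(0:16, pmin(0:16 / 16, 1), 190), drug, d, times = tt,
    F = 0.75, dt = 0.02)
  ir <- transit_absorption_simulate(
    release_input(c(0, 0.25, 1), c(0, 1, 1), 190), drug, d, times = tt,
    F = 0.75, dt = 0.02)
  n_cr <- nca(cr); n_ir <- nca(ir)
  expect_gte(n_cr$Tmax, 8)
  expect_lt(n_cr$Cmax, n_ir$Cmax)
  expect_lt(n_cr$Cmax, 2000)               # below the toxic threshold
  expect_gte(n_cr$AUCinf, n_cr$AUCt)
  expect_gte(n_cr$Tmax, n_ir$Tmax)
})

test_that("release exceeding physical bounds is rejected", {
  expect_error(release_input(0:2, c(0, 0.5, 1.2), 100), "\\[0, 1\\]")
  expect_error(release_input(0:2, c(0, 0.8, 0.5), 100), "non-decreasing")
  expect_error(release_input(c(0, 1, 1), c(0, 0.5, 1), 100),
               "strictly increasing")
})

test_that("noiseless plasma data recover the generating parameters", {
  d <- tramadol_disposition()
  tt <- c(seq(0.25, 4, 0.25), seq(5, 24, 1), seq(28, 96, 4),
          round(exp(seq(log(120), log(6000), length.out = 10))))
  prof <- generate_plasma(d, ka = 1.7, F = 0.75,
                          regimen = list(dose_mg = 50, dose_times_h = 0),
                          times = tt, cv = 0, seed = 1)$profile
  fit <- fit_two_compartment(prof, 50, F = 0.75, n_restarts = 3, seed = 2)
  truth <- c(1.7, 1.4776, 0.4021, 0.0569, 0.00572)
  est <- c(fit$ka, fit$params$Vc, fit$params$k12, fit$params$k21,
           fit$params$CL)
  expect_lt(max(abs(est - truth) / truth), 1e-4)
  expect_false(fit$monoexponential_warning)
})

test_that("one-compartment data pin k12 near zero with a warning", {
  d1 <- disposition_params(Vc = 1.5, k12 = 1e-9, k21 = 0.1, CL = 0.15,
                           body_weight_kg = 70)
  tt <- c(seq(0.25, 4, 0.25), seq(5, 48, 1))
  prof <- generate_plasma(d1, ka = 1.2, F = 1,
                          regimen = list(dose_mg = 100, dose_times_h = 0),
                          times = tt, cv = 0, seed = 3)$profile
  expect_warning(fit <- fit_two_compartment(prof, 100, F = 1,
                                            n_restarts = 3, seed = 4),
                 "mono-exponential")
  expect_lte(fit$params$k12, 1e-3)
})

test_that("superposition is exact for linear kinetics", {
  d <- tramadol_disposition()
  tt <- seq(0, 48, by = 0.25)
  single <- simulate_two_compartment_oral(d, 1.7, 0.75,
                                          list(dose_mg = 50,
                                               dose_times_h = 0), tt)
  multi <- superpose(single, interval_h = 6, n_doses = 4)
  direct <- simulate_two_compartment_oral(d, 1.7, 0.75,
                                          list(dose_mg = 50,
                                               dose_times_h = c(0, 6, 12,
                                                                18)), tt)
  expect_equal(multi$conc_ng_ml, direct$conc_ng_ml, tolerance = 1e-3)

  # n = 1 is the identity
  one <- superpose(single, 6, 1)
  expect_equal(one$conc_ng_ml, single$conc_ng_ml)

  # accumulation: multi-dose Cmax and troughs dominate single dose
  expect_gte(max(multi$conc_ng_ml), max(single$conc_ng_ml))
  trough1 <- multi$conc_ng_ml[which.min(abs(tt - 6))]
  trough4 <- multi$conc_ng_ml[which.min(abs(tt - 24))]
  expect_gte(trough4, trough1)
})

test_that("NCA recovers the closed-form mono-exponential summary", {
  tt <- seq(0, 60, by = 0.5)
  prof <- plasma_profile(tt, 100 * exp(-0.1 * tt))
  res <- nca(prof)
  expect_equal(res$lambda_z, 0.1, tolerance = 1e-3)
  expect_equal(res$AUCinf, 1000, tolerance = 0.005 * 1000)
  expect_equal(res$Cmax, 100)
  expect_equal(res$Tmax, 0)
  expect_gte(res$AUCinf, res$AUCt)

  # halving the sampling step reduces the trapezoid error
  coarse <- nca(plasma_profile(seq(0, 60, 1), 100 * exp(-0.1 *
                                                          seq(0, 60, 1))))
  errs <- c(abs(coarse$AUCt - (1000 - 1000 * exp(-6))),
            abs(res$AUCt - (1000 - 1000 * exp(-6))))
  expect_lt(errs[2], errs[1])
})

test_that("relative bioavailability reproduces the printed arithmetic", {
  expect_equal(relative_bioavailability(7388.4, 190, 7917.4, 200)$printed,
               98.23)
  expect_equal(round(relative_bioavailability(7663.8, 190, 7917.4,
                                              200)$value, 1), 101.9)
  expect_equal(relative_bioavailability(5000, 100, 5000, 100)$printed,
               100.00)
  expect_error(relative_bioavailability(100, 0, 100, 100), "positive")
})

test_that("ka calibration hits the target Tmax", {
  d <- tramadol_disposition()
  ka <- calibrate_ka(d, target_tmax_h = 1.12, F = 0.75)
  pr <- simulate_two_compartment_oral(d, ka, 0.75,
                                      list(dose_mg = 50, dose_times_h = 0),
                                      seq(0, 12, by = 0.01))
  expect_equal(pr$time_h[which.max(pr$conc_ng_ml)], 1.12,
               tolerance = 0.02)
})
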