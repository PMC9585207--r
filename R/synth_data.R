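# Synthetic-data generators. Every generator emits data plus a
# "synthetic_truth" sidecar recording the generating parameters, noise
# model and seed, so zero-noise output pushed back through its analysis
# stage must return the truth (a property the test-suite enforces).

.with_seed <- function(seed, expr) {
  seed <- as.integer(seed)   # force before snapshotting the RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(expr)
}

.truth <- function(kind, params, noise, seed) {
  structure(list(generator = kind, params = params, noise = noise,
                 seed = seed),
            class = "synthetic_truth")
}

#' Default SeDeM radius targets emulating a drug with two deficiencies
#'
#' A 12-radius target set in which the cohesion index and inter-particle
#' porosity fall below 5 while everything else complies -- the classic
#' profile of a freely flowing but poorly compactable crystalline API
#' (exactly 10 of 12 radii >= 5, so IP = 0.83). The density-derived radii
#' (Ie, IC, IH) are mutually consistent with the Da/Dc targets.
#'
#' @return named numeric vector of 12 radii.
#' @export
deficient_api_targets <- function() {
  Da <- 0.55; Dc <- 0.75
  c(Da = 10 * Da, Dc = 10 * Dc,
    Ie = 10 * ((Dc - Da) / (Dc * Da)) / 1.2,   # 4.04  (deficient)
    IC = ((Dc - Da) / Dc * 100) / 5,           # 5.33
    Icd = 90 / 20,                             # 4.50  (deficient)
    IH = 5 * (3 - Dc / Da),                    # 8.18
    alpha = 6.0, t_flow = 8.0, HR = 7.5, H = 9.0, Pf = 8.0, Itheta = 5.0)
}

#' Generate raw powder measurements hitting target SeDeM radii
#'
#' Inverts the linearization table: target radii for the independently
#' measurable quantities (Da, Dc, Icd, angle of repose, flow time, loss on
#' drying, hygroscopicity, fines, homogeneity index) are mapped back to
#' bench measurements; the density-derived parameters (Ie, IC, IH) follow
#' from the generated Da and Dc, so their targets are reported back as
#' realized values rather than imposed. Gaussian measurement noise
#' (coefficient of variation `noise_cv`) can be applied to the raw
#' measurements.
#'
#' @param target_radii named radii in `[0, 10]`; missing names filled from
#'   [deficient_api_targets()]. Targets of exactly 0 or 10 for Da/Dc/Itheta
#'   are unreachable (they invert to zero/degenerate measurements) and
#'   raise an error.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (0 = exact).
#' @param seed RNG seed.
#' @return list with `measurements` (a [powder_measurements()]), `truth`
#'   (sidecar incl. the realized radii at zero noise).
#' @export
generate_powder <- function(target_radii = deficient_api_targets(),
                            noise_cv = 0, seed = 1) {
  full <- deficient_api_targets()
  full[names(target_radii)] <- target_radii
  if (any(full < 0 | full > 10))
    stop("target radii must lie in [0, 10]", call. = FALSE)
  if (full[["Da"]] <= 0 || full[["Dc"]] <= 0 || full[["Itheta"]] <= 0)
    stop("unreachable target: Da, Dc and Itheta radii must be > 0 ",
         "(they invert to zero measurements)", call. = FALSE)
  if (full[["Da"]] > full[["Dc"]])
    stop("unreachable target: Da radius must not exceed Dc radius ",
         "(tapped volume cannot exceed bulk volume)", call. = FALSE)

  Da <- inverse_linearize("Da", full[["Da"]])
  Dc <- inverse_linearize("Dc", full[["Dc"]])
  mass <- 10
  icd <- inverse_linearize("Icd", full[["Icd"]])
  alpha <- inverse_linearize("alpha", full[["alpha"]])
  cone_d <- 8
  cone_h <- cone_d * tan(alpha * pi / 180) / 2
  t_flow <- inverse_linearize("t_flow", full[["t_flow"]])
  HR <- inverse_linearize("HR", full[["HR"]])
  H <- inverse_linearize("H", full[["H"]])
  Pf <- inverse_linearize("Pf", full[["Pf"]])
  itheta <- inverse_linearize("Itheta", full[["Itheta"]])

  # three-fraction sieve table on the 355/212/100/50 um series midpoints:
  # the modal fraction Fm sits at 156 um and the remainder is split evenly
  # over the two flanking fractions, giving
  # Itheta = Fm / (100 + (100 - Fm)/2 * (gap_lo + gap_hi)).
  d_major <- 156; d_flank <- c(283.5, 75)           # um (sieve midpoints)
  gsum <- sum(abs(d_flank - d_major)) / 2
  Fm <- itheta * 100 * (1 + gsum) / (1 + itheta * gsum)
  rest <- (100 - Fm) / 2
  if (Fm <= rest || Fm >= 100)
    stop("unreachable target: Itheta radius ", full[["Itheta"]],
         " cannot be realized with the default three-fraction sieve table",
         call. = FALSE)
  sieve <- data.frame(mean_diameter_um = c(d_flank[1], d_major, d_flank[2]),
                      mass_pct = c(rest, Fm, rest))

  raw <- list(sample_mass_g = mass, bulk_volume_ml = mass / Da,
              tapped_volume_ml = mass / Dc, tablet_hardness_N = icd,
              cone_height_cm = cone_h, cone_diameter_cm = cone_d,
              flow_time_s = t_flow, loss_on_drying_pct = HR,
              hygroscopicity_pct = H, fines_pct = Pf)
  if (noise_cv > 0) {
    noisy <- .with_seed(seed, {
      jitter <- stats::rnorm(length(raw), 1, noise_cv)
      mapply(function(v, j) max(v * j, 1e-6), raw, jitter)
    })
    raw <- as.list(noisy)
    # keep physical ordering after noise
    raw$tapped_volume_ml <- min(raw$tapped_volume_ml, raw$bulk_volume_ml)
  }
  m <- do.call(powder_measurements, c(raw, list(sieve_fractions = sieve)))
  realized <- linearize_profile(compute_micromeritic_parameters(m))$radii
  list(measurements = m,
       truth = .truth("powder",
                      list(target_radii = as.list(full),
                           realized_radii_zero_noise = as.list(realized)),
                      list(model = "multiplicative_gaussian",
                           cv = noise_cv),
                      seed))
}

#' Generate a synthetic dissolution profile
#'
#' Evaluates a kinetic model on the sampling schedule and adds additive
#' Gaussian noise (default sigma 2% of label claim, matching typical
#' USP-apparatus variability); values are clipped to `[0, 110]`. The
#' default schedule is hourly over 24 h with the two-stage medium
#' annotation (pH 1.2 for the first 2 h, then pH 6.8).
#'
#' @param model kinetic model name.
#' @param params model parameters (see [predict_release()]).
#' @param schedule sampling times (h).
#' @param noise_sd additive noise standard deviation (percent points).
#' @param seed RNG seed.
#' @param id profile id.
#' @return list with `profile` (a [dissolution_profile()]) and `truth`.
#' @export
generate_dissolution <- function(model, params, schedule = 1:24,
                                 noise_sd = 2, seed = 1, id = "synthetic") {
  f <- predict_release(model, params, schedule)
  if (noise_sd > 0)
    f <- .with_seed(seed, f + stats::rnorm(length(f), 0, noise_sd))
  f <- pmin(pmax(f, 0), 110)
  list(profile = dissolution_profile(schedule, f, id = id),
       truth = .truth("dissolution",
                      list(model = model, params = as.list(params),
                           schedule = schedule),
                      list(model = "additive_gaussian", sd = noise_sd),
                      seed))
}

#' Generate a synthetic plasma concentration profile
#'
#' Closed-form two-compartment oral simulation with proportional
#' log-normal error of coefficient of variation `cv` (default 10%, a
#' typical bioanalytical + biological variability for tramadol plasma
#' assays).
#'
#' @param d a [disposition_params()].
#' @param ka absorption rate constant (1/h).
#' @param F bioavailable fraction.
#' @param regimen list with `dose_mg`, `dose_times_h`.
#' @param times sampling times (h).
#' @param cv proportional error CV (0 = noiseless).
#' @param seed RNG seed.
#' @return list with `profile` (a `plasma_profile`) and `truth`.
#' @export
generate_plasma <- function(d, ka, F = 1,
                            regimen = list(dose_mg = 50, dose_times_h = 0),
                            times = seq(0, 24, by = 0.5), cv = 0.1,
                            seed = 1) {
  clean <- simulate_two_compartment_oral(d, ka, F, regimen, times)
  conc <- clean$conc_ng_ml
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    conc <- .with_seed(seed,
      conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog))
  }
  list(profile = plasma_profile(times, conc, regimen),
       truth = .truth("plasma",
                      list(Vc = d$Vc, k12 = d$k12, k21 = d$k21, CL = d$CL,
                           body_weight_kg = d$body_weight_kg, ka = ka,
                           F = F, regimen = regimen),
                      list(model = "proportional_lognormal", cv = cv),
                      seed))
}

#' Generate factorial response data from coded-unit coefficients
#'
#' `y = b0 + X beta + N(0, sigma^2)` over the design's coded matrix -- the
#' generative counterpart of [fit_main_effects()]. The default noise level
#' gives R^2 around 0.95 for response surfaces on the scale of typical
#' dissolution percentages.
#'
#' @param design a `design_matrix` from [build_design()].
#' @param coefficients numeric vector `c(intercept, beta_1..beta_k)`.
#' @param sigma residual standard deviation.
#' @param seed RNG seed.
#' @return list with `responses` (data.frame: run_id, y) and `truth`.
#' @export
generate_factorial_responses <- function(design, coefficients, sigma = 0,
                                         seed = 1) {
  stopifnot(inherits(design, "design_matrix"))
  X <- .coded_matrix(design)
  if (length(coefficients) != ncol(X) + 1L)
    stop("need ", ncol(X) + 1L, " coefficients (intercept + ", ncol(X),
         " main effects), got ", length(coefficients), call. = FALSE)
  y <- coefficients[1] + drop(X %*% coefficients[-1])
  if (sigma > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), 0, sigma))
  list(responses = data.frame(run_id = design$design$run_id, y = y),
       truth = .truth("factorial",
                      list(coefficients = coefficients, k = design$k,
                           design_seed = design$seed),
                      list(model = "additive_gaussian", sd = sigma),
                      seed))
}

#' Write a dataset and its truth sidecar to disk
#'
#' @param data a data.frame to write as CSV.
#' @param truth the `synthetic_truth` sidecar.
#' @param path output CSV path; the sidecar goes to `<path>.truth.json`.
#' @return invisibly, the two paths written.
#' @export
write_synthetic <- function(data, truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  truth_path <- paste0(path, ".truth.json")
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(data = path, truth = truth_path))
}
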