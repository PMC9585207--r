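# Dissolution-kinetics predictors, fitting, mechanism classification, f2.

test_that("model predictors reproduce closed-form values", {
  expect_equal(predict_release("zero_order", c(k0 = 5.898), 10), 58.98)
  expect_equal(predict_release("first_order", c(k1 = 0.2), 1e4), 100,
               tolerance = 1e-9)                     # asymptote
  expect_equal(predict_release("higuchi", c(kH = 19.146), 4),
               19.146 * 2)
  expect_equal(predict_release("korsmeyer_peppas", c(kKP = 8.02, n = 0.902),
                               1), 8.02)
  # Weibull characteristic point: t^beta = alpha -> 63.21%
  expect_equal(predict_release("weibull", c(alpha = 8, beta = 1.5), 4),
               100 * (1 - exp(-1)), tolerance = 1e-9)
  # Hixson-Crowell past its domain caps at 100
  expect_equal(predict_release("hixson_crowell", c(kHC = 0.1), 15), 100)
  expect_error(predict_release("zero_order", c(k0 = 5), -1),
               "non-negative")
  expect_error(predict_release("zero_order", c(k0 = -5), 1), "positive")
  expect_error(predict_release("korsmeyer_peppas", c(kKP = 8, n = 2.5), 1),
               "n must lie")
  expect_error(predict_release("weibull", c(alpha = 8), 1), "beta")
})

test_that("all predictors start at zero and are non-decreasing", {
  pars <- list(zero_order = c(k0 = 5), first_order = c(k1 = 0.15),
               higuchi = c(kH = 18), korsmeyer_peppas = c(kKP = 8, n = 0.9),
               hixson_crowell = c(kHC = 0.03),
               baker_lonsdale = c(kBL = 0.008),
               weibull = c(alpha = 20, beta = 1.3))
  tt <- seq(0, 24, by = 0.5)
  for (m in kinetic_model_names()) {
    f <- predict_release(m, pars[[m]], tt)
    expect_equal(f[1], 0, label = m)
    expect_true(all(diff(f) >= -1e-9), label = m)
  }
})

test_that("Baker-Lonsdale inversion agrees with forward evaluation", {
  kBL <- 0.009
  tt <- c(0.5, 2, 8, 20, 40)
  F <- predict_release("baker_lonsdale", c(kBL = kBL), tt)
  # forward map applied to the recovered root must return kBL * t
  g <- function(x) 1.5 * (1 - (1 - x)^(2 / 3)) - x
  expect_equal(g(F / 100), pmin(kBL * tt, 0.5), tolerance = 1e-9)
})

test_that("noiseless data recover generating parameters for all models", {
  truths <- list(zero_order = c(k0 = 6.271),
                 first_order = c(k1 = 0.097),
                 higuchi = c(kH = 20.308),
                 korsmeyer_peppas = c(kKP = 8.02, n = 0.902),
                 hixson_crowell = c(kHC = 0.031),
                 baker_lonsdale = c(kBL = 0.009),
                 weibull = c(alpha = 22.609, beta = 1.407))
  tt <- 1:15                       # within the physical range for all sets
  for (m in kinetic_model_names()) {
    prof <- dissolution_profile(tt, predict_release(m, truths[[m]], tt))
    fit <- fit_model(prof, m)
    expect_true(fit$converged, label = m)
    expect_equal(unname(fit$parameters), unname(truths[[m]]),
                 tolerance = 1e-6, label = m)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9, label = m)
  }
})

test_that("fit matches a dense grid-search oracle on a toy profile", {
  prof <- dissolution_profile(c(1, 2, 4, 8, 12),
                              c(9.1, 15.8, 29.5, 55.2, 78.3))
  fit <- fit_model(prof, "korsmeyer_peppas")
  # dumb exhaustive grid, no least-squares shortcuts
  grid_k <- seq(4, 14, by = 0.02)
  grid_n <- seq(0.5, 1.3, by = 0.004)
  best_sse <- Inf; best_k <- NA; best_n <- NA
  for (n in grid_n) {
    u <- prof$time_h^n
    for (k in grid_k) {
      s <- sum((prof$release_pct - k * u)^2)
      if (s < best_sse) { best_sse <- s; best_k <- k; best_n <- n }
    }
  }
  expect_equal(unname(fit$parameters[["kKP"]]), best_k, tolerance = 1e-2)
  expect_equal(unname(fit$parameters[["n"]]), best_n, tolerance = 1e-2)
  expect_lte(fit$sse, best_sse + 1e-6)     # NLS at least as good as grid
})

test_that("mechanism classification follows the exponent thresholds", {
  expect_equal(classify_mechanism(0.476)$mechanism, "Fickian")
  expect_equal(classify_mechanism(0.5)$mechanism, "Fickian")
  expect_equal(classify_mechanism(0.6)$mechanism, "anomalous")
  expect_equal(classify_mechanism(0.85)$mechanism, "anomalous")
  expect_equal(classify_mechanism(0.902)$mechanism, "case II")
  expect_equal(classify_mechanism(1.0)$mechanism, "case II")
  expect_equal(classify_mechanism(1.229)$mechanism, "super case II")
  expect_error(classify_mechanism(0), "positive")
  expect_error(classify_mechanism(-1), "positive")
})

test_that("f2 boundary behaviour matches hand arithmetic", {
  tt <- 1:10
  r <- dissolution_profile(tt, seq(8, 80, by = 8))
  expect_equal(f2_similarity(r, r)$f2, 100)
  # uniform 10-point difference: 50 log10(100/sqrt(101))
  ref <- dissolution_profile(tt, seq(18, 90, by = 8))
  shifted <- dissolution_profile(tt, seq(18, 90, by = 8) - 10)
  out <- f2_similarity(ref, shifted, truncate_85 = FALSE)
  expect_equal(out$f2, 50 * log10(100 / sqrt(101)), tolerance = 1e-12)
  expect_equal(round(out$f2, 2), 49.89)
  # uniform 2-point difference: 50 log10(100/sqrt(5)) = 82.53
  t2 <- dissolution_profile(tt, seq(18, 90, by = 8) - 2)
  out2 <- f2_similarity(ref, t2, truncate_85 = FALSE)
  expect_equal(out2$f2, 50 * log10(100 / sqrt(5)), tolerance = 1e-12)
  expect_equal(round(out2$f2, 2), 82.53)
})

test_that("f2 symmetry, grid checks and the 85% truncation rule", {
  tt <- 1:8
  a <- dissolution_profile(tt, c(10, 25, 40, 55, 65, 72, 78, 83))
  b <- dissolution_profile(tt, c(12, 28, 44, 58, 69, 75, 80, 84))
  expect_equal(f2_similarity(a, b)$f2, f2_similarity(b, a)$f2,
               tolerance = 1e-9)
  # adding identical points to both leaves f2 unchanged (no truncation)
  a2 <- dissolution_profile(c(tt, 9), c(a$release_pct, 84))
  b2 <- dissolution_profile(c(tt, 9), c(b$release_pct, 84))
  expect_equal(f2_similarity(a2, b2, truncate_85 = FALSE)$f2,
               50 * log10(100 / sqrt(1 + mean(c((a$release_pct -
                 b$release_pct)^2, 0)))), tolerance = 1e-9)

  # truncation: only one point beyond 85% of the reference is kept
  ref <- dissolution_profile(1:6, c(40, 60, 80, 88, 95, 99))
  tst <- dissolution_profile(1:6, c(42, 63, 78, 90, 94, 98))
  res <- f2_similarity(ref, tst)
  expect_equal(res$n_points, 4)
  expect_equal(res$truncated_points, 2)
  manual <- 50 * log10(100 / sqrt(1 + mean((c(40, 60, 80, 88) -
                                              c(42, 63, 78, 90))^2)))
  expect_equal(res$f2, manual, tolerance = 1e-12)

  expect_error(f2_similarity(ref, dissolution_profile(2:7, tst$release_pct)),
               "identical time grid")
  short_r <- dissolution_profile(1:2, c(10, 20))
  short_t <- dissolution_profile(1:2, c(11, 21))
  expect_error(f2_similarity(short_r, short_t), "3")
})

test_that("model ranking orders by r2 then parsimony then AIC", {
  tt <- 1:15
  prof <- dissolution_profile(tt, predict_release("zero_order",
                                                  c(k0 = 5.5), tt))
  fits <- lapply(c("zero_order", "first_order", "korsmeyer_peppas"),
                 function(m) fit_model(prof, m))
  tab <- rank_models(fits)
  # KP nests zero-order (n = 1) so both hit r2 = 1; fewer params wins
  expect_equal(tab$model[1], "zero_order")
  expect_lt(match("first_order", tab$model), 4)
  # pairwise-comparison oracle
  better <- function(a, b) {
    if (abs(a$r_squared - b$r_squared) > 1e-12)
      return(a$r_squared > b$r_squared)
    if (length(a$parameters) != length(b$parameters))
      return(length(a$parameters) < length(b$parameters))
    a$aic < b$aic
  }
  for (i in seq_len(nrow(tab) - 1)) {
    fa <- fits[[match(tab$model[i], vapply(fits, `[[`, "", "model"))]]
    fb <- fits[[match(tab$model[i + 1], vapply(fits, `[[`, "", "model"))]]
    expect_true(better(fa, fb) ||
                  abs(fa$r_squared - fb$r_squared) < 1e-9)
  }
  expect_error(rank_models(list()), "no successful fits")
})

test_that("dissolution profile container flags decreases and bad inputs", {
  expect_error(dissolution_profile(c(1, 1, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(dissolution_profile(1:3, c(10, 120, 30)), "\\[0, 110\\]")
  p <- dissolution_profile(1:4, c(10, 30, 28, 50))    # 2-point dip
  expect_equal(attr(p, "monotonicity_violations"), 2L)
  expect_equal(p$pH, c(1.2, 1.2, 6.8, 6.8))           # 2-stage annotation
})
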