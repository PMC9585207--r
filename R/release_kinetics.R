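# Dissolution-kinetics model fitting, release-mechanism classification and
# f2 profile similarity.
#
# Seven classical models are supported, all fitted by nonlinear least
# squares on the untransformed cumulative-release scale (the DD-Solver
# convention), never by log-linearization.

.kinetic_models <- list(
  zero_order = list(
    params = "k0",
    fn = function(t, p) p[["k0"]] * t
  ),
  first_order = list(
    params = "k1",
    fn = function(t, p) 100 * (1 - exp(-p[["k1"]] * t))
  ),
  higuchi = list(
    params = "kH",
    fn = function(t, p) p[["kH"]] * sqrt(t)
  ),
  korsmeyer_peppas = list(
    params = c("kKP", "n"),
    fn = function(t, p) p[["kKP"]] * t^p[["n"]]
  ),
  hixson_crowell = list(
    params = "kHC",
    fn = function(t, p) {
      x <- pmin(p[["kHC"]] * t, 1)   # domain ends where the cube root hits 0
      100 * (1 - (1 - x)^3)
    }
  ),
  baker_lonsdale = list(
    params = "kBL",
    fn = function(t, p) .baker_lonsdale_forward(p[["kBL"]] * t)
  ),
  weibull = list(
    params = c("alpha", "beta"),
    fn = function(t, p) 100 * (1 - exp(-t^p[["beta"]] / p[["alpha"]]))
  )
)

#' Names of the supported dissolution-kinetics models
#' @return character vector of model identifiers.
#' @export
kinetic_model_names <- function() names(.kinetic_models)

# Baker-Lonsdale left-hand side g(x) = 3/2 [1 - (1-x)^(2/3)] - x for
# x = F/100; increasing from 0 to 1/2 on [0, 1]. The forward curve solves
# g(x) = kBL * t by bracketed root-finding; kBL*t >= 1/2 means complete
# release.
.baker_lonsdale_g <- function(x) 1.5 * (1 - (1 - x)^(2 / 3)) - x

.baker_lonsdale_forward <- function(kt) {
  vapply(kt, function(v) {
    if (v <= 0) return(0)
    if (v >= 0.5) return(100)
    100 * stats::uniroot(function(x) .baker_lonsdale_g(x) - v,
                         interval = c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

#' Predicted cumulative release for a kinetic model
#'
#' Evaluates the chosen model at the given times:
#' zero order `F = k0 t`; first order `F = 100 (1 - e^(-k1 t))`; Higuchi
#' `F = kH sqrt(t)`; Korsmeyer-Peppas `F = kKP t^n`; Hixson-Crowell
#' `F = 100 (1 - (1 - kHC t)^3)` (capped at 100 past its domain);
#' Baker-Lonsdale, `3/2 (1 - (1 - F/100)^(2/3)) - F/100 = kBL t` solved
#' numerically; Weibull `F = 100 (1 - e^(-t^beta / alpha))` (lag time fixed
#' at zero, so large `alpha` values simply stretch the time scale).
#'
#' @param model model name, one of [kinetic_model_names()].
#' @param params named list/vector of parameters (`k0`, `k1`, `kH`,
#'   `kKP` + `n`, `kHC`, `kBL`, or `alpha` + `beta`). All rate constants
#'   must be positive; `n` must lie in (0, 2).
#' @param times numeric vector of non-negative times (h).
#' @return cumulative release (percent of label claim).
#' @export
predict_release <- function(model, params, times) {
  model <- match.arg(model, names(.kinetic_models))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  spec <- .kinetic_models[[model]]
  p <- as.list(params)
  missing <- setdiff(spec$params, names(p))
  if (length(missing))
    stop("model '", model, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rates <- setdiff(spec$params, "n")
  if (any(unlist(p[rates]) <= 0))
    stop("rate constants must be positive", call. = FALSE)
  if ("n" %in% spec$params && (p$n <= 0 || p$n >= 2))
    stop("release exponent n must lie in (0, 2)", call. = FALSE)
  spec$fn(times, p)
}

#' Dissolution time-course container
#'
#' @param time_h strictly increasing sampling times (h).
#' @param release_pct cumulative release (percent of label claim), expected
#'   in `[0, 110]`. Decreases beyond 0.5 percentage points between adjacent
#'   samples are flagged (attribute `monotonicity_violations`), not
#'   rejected, since late-profile scatter is common.
#' @param pH per-point medium pH annotation (scalar or vector); the default
#'   two-stage schedule is pH 1.2 up to 2 h then pH 6.8.
#' @param rpm paddle speed annotation.
#' @param id profile identifier.
#' @return a `dissolution_profile` data.frame.
#' @export
dissolution_profile <- function(time_h, release_pct, pH = NULL, rpm = 75,
                                id = "profile") {
  stopifnot(is.numeric(time_h), is.numeric(release_pct),
            length(time_h) == length(release_pct))
  if (any(diff(time_h) <= 0))
    stop("time_h must be strictly increasing", call. = FALSE)
  if (any(release_pct < 0 | release_pct > 110))
    stop("release_pct must lie within [0, 110]", call. = FALSE)
  if (is.null(pH)) pH <- ifelse(time_h <= 2, 1.2, 6.8)
  viol <- which(diff(release_pct) < -0.5)
  out <- data.frame(time_h = time_h, release_pct = release_pct,
                    pH = pH, rpm = rpm)
  structure(out, class = c("dissolution_profile", "data.frame"),
            id = id, monotonicity_violations = viol)
}

# Closed-form starting values per model, from simple transforms of the data.
.kinetic_start <- function(model, t, f) {
  pos <- t > 0 & f > 0 & f < 100
  tp <- t[pos]; fp <- f[pos]
  safe <- function(x, fallback) if (is.finite(x) && x > 0) x else fallback
  switch(model,
    zero_order = list(k0 = safe(sum(fp * tp) / sum(tp^2), 5)),
    first_order = list(k1 = safe(-stats::coef(stats::lm(
      log(pmax(1 - fp / 100, 1e-6)) ~ tp - 1))[[1]], 0.1)),
    higuchi = list(kH = safe(sum(fp * sqrt(tp)) / sum(tp), 20)),
    korsmeyer_peppas = {
      cf <- stats::coef(stats::lm(log(fp) ~ log(tp)))
      n0 <- cf[[2]]
      list(kKP = safe(exp(cf[[1]]), 10),
           n = if (is.finite(n0) && n0 > 0.05 && n0 < 1.95) n0 else 0.5)
    },
    hixson_crowell = {
      x <- 1 - (1 - pmin(fp, 99.9) / 100)^(1 / 3)
      list(kHC = safe(sum(x * tp) / sum(tp^2), 0.03))
    },
    baker_lonsdale = {
      g <- .baker_lonsdale_g(pmin(fp, 99.9) / 100)
      list(kBL = safe(sum(g * tp) / sum(tp^2), 0.01))
    },
    weibull = {
      y <- log(-log(pmax(1 - fp / 100, 1e-6)))
      cf <- stats::coef(stats::lm(y ~ log(tp)))
      beta0 <- cf[[2]]
      list(alpha = safe(exp(-cf[[1]]), 5),
           beta = if (is.finite(beta0) && beta0 > 0.05) beta0 else 1)
    }
  )
}

#' Fit a dissolution-kinetics model
#'
#' Nonlinear least squares on the untransformed release scale. Starting
#' values come from closed-form transforms (e.g. the log-log slope for the
#' Korsmeyer-Peppas exponent) and are refined by `optim` on log-scaled
#' parameters; `n_restarts` jittered restarts (seeded, logged) guard
#' against local minima. Non-convergence across every start yields an
#' explicit failed result, never silent NaNs.
#'
#' @param profile a [dissolution_profile()] (or data.frame with `time_h`,
#'   `release_pct`).
#' @param model model name, one of [kinetic_model_names()].
#' @param n_restarts jittered restarts around the closed-form start.
#' @param seed seed for the restart jitter.
#' @return a `kinetic_fit` object: `model`, `parameters` (named), `r_squared`,
#'   `adj_r_squared`, `aic`, `residuals`, `fitted`, `converged`, `sse`,
#'   `n_obs`, `seed`.
#' @export
fit_model <- function(profile, model, n_restarts = 5, seed = 1) {
  model <- match.arg(model, names(.kinetic_models))
  t <- profile$time_h
  f <- profile$release_pct
  spec <- .kinetic_models[[model]]
  npar <- length(spec$params)
  if (length(t) < npar + 2)
    stop("need at least ", npar + 2, " points to fit '", model, "'",
         call. = FALSE)

  # parameters are positive (n additionally < 2): optimize on log scale
  to_par <- function(theta) {
    p <- as.list(exp(theta))
    names(p) <- spec$params
    if ("n" %in% spec$params) p$n <- min(p$n, 1.999)
    p
  }
  sse_fn <- function(theta) {
    p <- to_par(theta)
    pred <- tryCatch(spec$fn(t, p), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((f - pred)^2)
  }

  start <- unlist(.kinetic_start(model, t, f))[spec$params]
  start[!is.finite(start) | start <= 0] <- 1
  theta0 <- log(start)

  seed <- as.integer(seed)   # force before snapshotting the RNG state
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))

  starts <- c(list(theta0),
              lapply(seq_len(n_restarts),
                     function(i) theta0 + stats::rnorm(npar, 0, 0.5)))
  run_opt <- function(th, maxit) {
    if (npar == 1L)
      stats::optim(th, sse_fn, method = "Brent", lower = th - 12,
                   upper = th + 12, control = list(maxit = maxit))
    else
      stats::optim(th, sse_fn, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-14))
  }
  best <- NULL
  for (th in starts) {
    res <- tryCatch(run_opt(th, 5000), error = function(e) NULL)
    if (!is.null(res) && res$value < 1e11 &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(structure(list(model = model, parameters = NULL,
                          r_squared = NA_real_, adj_r_squared = NA_real_,
                          aic = NA_real_, residuals = NULL, fitted = NULL,
                          converged = FALSE, sse = NA_real_,
                          n_obs = length(t), seed = seed),
                     class = "kinetic_fit"))
  }
  # gradient polish from the winner (smooth least-squares surface)
  if (npar > 1L)
    best <- tryCatch(stats::optim(best$par, sse_fn, method = "BFGS",
                                  control = list(maxit = 10000,
                                                 reltol = 1e-15)),
                     error = function(e) best)
  best <- run_opt(best$par, 20000)
  p <- to_par(best$par)
  pred <- spec$fn(t, p)
  res <- f - pred
  sse <- sum(res^2)
  sst <- sum((f - mean(f))^2)
  n <- length(t)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (sst > 0 && n - npar - 1 > 0)
    1 - (1 - r2) * (n - 1) / (n - npar - 1) else NA_real_
  # Gaussian log-likelihood AIC with sigma2 = SSE/n
  aic <- n * log(max(sse, 1e-300) / n) + 2 * (npar + 1)

  structure(list(model = model, parameters = unlist(p), r_squared = r2,
                 adj_r_squared = adj, aic = aic, residuals = res,
                 fitted = pred, converged = TRUE, sse = sse, n_obs = n,
                 seed = seed),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("kinetic fit: %s FAILED to converge\n", x$model))
    return(invisible(x))
  }
  cat(sprintf("kinetic fit: %s  r2 = %.4f  AIC = %.2f\n", x$model,
              x$r_squared, x$aic))
  print(round(x$parameters, 5))
  invisible(x)
}

#' Classify the drug-release mechanism from the Korsmeyer-Peppas exponent
#'
#' For cylindrical matrices: `n <= 0.5` Fickian diffusion; `0.5 < n <= 0.85`
#' anomalous (coupled diffusion/erosion) transport; `0.85 < n <= 1` case II
#' (swelling-controlled, near zero-order) transport; `n > 1` super case II.
#'
#' @param n release exponent (> 0).
#' @return a `mechanism_class` object with `mechanism` and `n`.
#' @export
classify_mechanism <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (!is.finite(n) || n <= 0) stop("n must be positive", call. = FALSE)
  mech <- if (n <= 0.5) "Fickian"
          else if (n <= 0.85) "anomalous"
          else if (n <= 1) "case II"
          else "super case II"
  structure(list(mechanism = mech, n = n), class = "mechanism_class")
}

#' @export
print.mechanism_class <- function(x, ...) {
  cat(sprintf("n = %.3f -> %s transport\n", x$n, x$mechanism))
  invisible(x)
}

#' f2 similarity factor between two dissolution profiles
#'
#' `f2 = 50 log10( 100 / sqrt(1 + mean((R_t - T_t)^2)) )`. Identical
#' profiles give 100; an average point-wise difference of 10 percentage
#' points gives ~50, the conventional similarity boundary. Following
#' regulatory practice, at most one sampling point beyond 85% release of
#' the reference is included (`truncate_85 = FALSE` evaluates the plain
#' formula on all shared points).
#'
#' @param reference,test [dissolution_profile()]s (or data.frames) on an
#'   identical time grid with at least 3 points.
#' @param truncate_85 apply the 85%-release truncation rule (default TRUE).
#' @return a `similarity_result`: `f2`, `n_points` compared,
#'   `truncated_points` dropped by the 85% rule.
#' @export
f2_similarity <- function(reference, test, truncate_85 = TRUE) {
  rt <- reference$time_h; tt <- test$time_h
  if (length(rt) != length(tt) || any(abs(rt - tt) > 1e-9))
    stop("profiles must share an identical time grid", call. = FALSE)
  R <- reference$release_pct; T_ <- test$release_pct
  keep <- rep(TRUE, length(R))
  dropped <- 0L
  if (truncate_85) {
    over <- which(R > 85)
    if (length(over) > 1L) {           # keep only the first point past 85%
      drop_idx <- over[-1]
      keep[drop_idx] <- FALSE
      dropped <- length(drop_idx)
    }
  }
  n <- sum(keep)
  if (n < 3) stop("need at least 3 comparable time points", call. = FALSE)
  msd <- mean((R[keep] - T_[keep])^2)
  f2 <- 50 * log10(100 / sqrt(1 + msd))
  structure(list(f2 = f2, n_points = n, truncated_points = dropped),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("f2 = %.2f over %d points (%d dropped by 85%% rule) -> %s\n",
              x$f2, x$n_points, x$truncated_points,
              if (x$f2 >= 50) "similar" else "not similar"))
  invisible(x)
}

#' Rank fitted kinetic models
#'
#' Sorts successful fits by descending r-squared; ties go to the model with
#' fewer parameters, then to the lower AIC.
#'
#' @param results list of `kinetic_fit` objects.
#' @return data.frame with one row per converged fit: model, n_params, r2,
#'   adj_r2, aic, rank, and one column per estimated parameter.
#' @export
rank_models <- function(results) {
  ok <- Filter(function(x) inherits(x, "kinetic_fit") && x$converged,
               results)
  if (!length(ok)) stop("no successful fits to rank", call. = FALSE)
  tab <- do.call(rbind, lapply(ok, function(x) data.frame(
    model = x$model, n_params = length(x$parameters),
    r2 = x$r_squared, adj_r2 = x$adj_r_squared, aic = x$aic,
    stringsAsFactors = FALSE)))
  ord <- order(-tab$r2, tab$n_params, tab$aic)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  params <- lapply(ok[ord], function(x) x$parameters)
  all_names <- unique(unlist(lapply(params, names)))
  for (nm in all_names)
    tab[[nm]] <- vapply(params, function(p)
      if (nm %in% names(p)) p[[nm]] else NA_real_, numeric(1))
  rownames(tab) <- NULL
  tab
}
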