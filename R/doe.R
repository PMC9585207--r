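# Two-level full factorial design, coded-unit main-effects regression,
# ANOVA, and Derringer-Suich desirability optimization.

#' Specify a design factor
#'
#' @param name factor name.
#' @param low,high actual-unit levels coded as -1 and +1; `low < high`.
#' @param units optional units label.
#' @return a `factor_spec` object.
#' @export
factor_spec <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high))
  if (!(low < high))
    stop("degenerate factor '", name, "': low must be < high", call. = FALSE)
  structure(list(name = name, low = low, high = high, units = units),
            class = "factor_spec")
}

#' Code and decode factor levels
#'
#' `code_value()` maps an actual-unit value onto the coded scale,
#' `coded = (actual - midpoint) / half_range`; `decode_value()` is its exact
#' inverse. Design levels map to +-1, the centre point to 0.
#'
#' @param f a [factor_spec()].
#' @param actual,coded numeric vectors.
#' @return numeric vector on the other scale.
#' @export
code_value <- function(f, actual) {
  stopifnot(inherits(f, "factor_spec"))
  mid <- (f$low + f$high) / 2
  half <- (f$high - f$low) / 2
  (actual - mid) / half
}

#' @rdname code_value
#' @export
decode_value <- function(f, coded) {
  stopifnot(inherits(f, "factor_spec"))
  mid <- (f$low + f$high) / 2
  half <- (f$high - f$low) / 2
  coded * half + mid
}

#' Build a 2^k full factorial design
#'
#' Generates the complete 2^k design in standard (Yates) order -- the first
#' factor alternating fastest -- plus a seed-determined randomized run
#' order, as factorial experiments are executed in randomized sequence to
#' guard against drift.
#'
#' @param k number of two-level factors, 2 <= k <= 8.
#' @param seed integer seed for the run-order randomization (required; it is
#'   part of the design's provenance).
#' @param factor_names optional character vector of length `k` (defaults to
#'   X1..Xk).
#' @return a `design_matrix` object: list with `design` (data.frame of coded
#'   +-1 levels, rows in standard order, `run_id` column), `run_order`
#'   (integer permutation giving execution order), `k`, `seed`.
#' @export
build_design <- function(k, seed, factor_names = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L)
  if (k < 2 || k > 8 || k != round(k))
    stop("k must be an integer in [2, 8]", call. = FALSE)
  k <- as.integer(k)
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is required (it is logged with the design)",
         call. = FALSE)
  if (is.null(factor_names)) factor_names <- paste0("X", seq_len(k))
  stopifnot(length(factor_names) == k)

  levels <- rep(list(c(-1, 1)), k)
  names(levels) <- factor_names
  design <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  design <- cbind(run_id = seq_len(nrow(design)), design)

  run_order <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sample.int(nrow(design))
  })

  structure(list(design = design, run_order = run_order, k = k, seed = seed,
                 factor_names = factor_names),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("2^%d full factorial design (%d runs, seed %s)\n",
              x$k, nrow(x$design), format(x$seed)))
  print(x$design)
  invisible(x)
}

.coded_matrix <- function(design) {
  if (inherits(design, "design_matrix")) {
    as.matrix(design$design[, design$factor_names, drop = FALSE])
  } else if (is.matrix(design) || is.data.frame(design)) {
    as.matrix(design)
  } else stop("design must be a design_matrix or a coded matrix",
              call. = FALSE)
}

#' Fit a coded-unit main-effects model
#'
#' Ordinary least squares of a response on the coded factor columns, main
#' effects only (the standard model form for screening 2^k designs). On an
#' orthogonal design each coefficient equals half the difference between the
#' mean response at the +1 level and at the -1 level of its factor.
#'
#' @param design a `design_matrix` (or coded +-1 matrix).
#' @param y numeric response vector, one value per run, in standard order.
#' @param response name of the response (for reporting).
#' @return a `fitted_model` object: `intercept`, `coefficients` (named, in
#'   coded units), `residuals`, `sigma2` (residual variance), `r_squared`,
#'   `fit` (the underlying `lm`), `response`.
#' @export
fit_main_effects <- function(design, y, response = "y") {
  X <- .coded_matrix(design)
  if (length(y) != nrow(X))
    stop("length(y) = ", length(y), " but the design has ", nrow(X),
         " runs", call. = FALSE)
  if (any(apply(X, 2, function(col) length(unique(col)) < 2L)))
    stop("constant factor column in design", call. = FALSE)
  dat <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  df_res <- fit$df.residual
  sst <- sum((y - mean(y))^2)
  ssr <- sum(res^2)
  structure(list(
    response = response,
    intercept = unname(cf[1]),
    coefficients = cf[-1],
    residuals = res,
    sigma2 = if (df_res > 0) ssr / df_res else NA_real_,
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
    fit = fit
  ), class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g %s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("%s = %.4g %s  (R2 = %.4f)\n", x$response, x$intercept, terms,
              ifelse(is.na(x$r_squared), NaN, x$r_squared)))
  invisible(x)
}

#' Construct a fitted model from known coefficients
#'
#' Builds a `fitted_model` directly from an intercept and coded-unit
#' main-effect coefficients, e.g. published regression equations, so they
#' can be used for prediction and desirability optimization without the raw
#' per-run responses.
#'
#' @param intercept model intercept.
#' @param coefficients named numeric vector of main effects in coded units.
#' @param response response name.
#' @return a `fitted_model`.
#' @export
model_from_coefficients <- function(intercept, coefficients, response = "y") {
  stopifnot(is.numeric(intercept), is.numeric(coefficients),
            !is.null(names(coefficients)))
  structure(list(response = response, intercept = unname(intercept),
                 coefficients = coefficients, residuals = NULL,
                 sigma2 = NA_real_, r_squared = NA_real_, fit = NULL),
            class = "fitted_model")
}

#' ANOVA for a main-effects factorial model
#'
#' Partitions the total sum of squares term-wise (the coded design is
#' orthogonal, so sequential and partial sums of squares coincide) and
#' tests each term and the whole model against the residual mean square.
#' With a saturated model (zero residual degrees of freedom) p-values are
#' reported as `NA` rather than a misleading 0.
#'
#' @param model a `fitted_model` from [fit_main_effects()].
#' @param alpha significance level used to flag terms (default 0.05).
#' @return an `anova_table` object: data.frame of term, df, sum_sq, mean_sq,
#'   F, p, significant; plus attributes `model_F`, `model_p`,
#'   `model_significant`.
#' @export
anova_main_effects <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "fitted_model"))
  if (is.null(model$fit))
    stop("ANOVA needs a model fitted from data, not bare coefficients",
         call. = FALSE)
  fit <- model$fit
  # saturated/perfect fits are handled explicitly below; silence the
  # stats::anova.lm advisory about them
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  terms <- rownames(an)
  resid_row <- terms == "Residuals"
  df_res <- an$Df[resid_row]
  ms_res <- an$`Mean Sq`[resid_row]

  tab <- data.frame(
    term = terms[!resid_row],
    df = an$Df[!resid_row],
    sum_sq = an$`Sum Sq`[!resid_row],
    mean_sq = an$`Mean Sq`[!resid_row],
    F = an$`F value`[!resid_row],
    p = an$`Pr(>F)`[!resid_row],
    stringsAsFactors = FALSE
  )
  if (df_res == 0) { tab$F <- NA_real_; tab$p <- NA_real_ }
  tab$significant <- !is.na(tab$p) & tab$p <= alpha

  ss_model <- sum(tab$sum_sq)
  df_model <- sum(tab$df)
  if (df_res > 0) {
    F_model <- (ss_model / df_model) / ms_res
    p_model <- stats::pf(F_model, df_model, df_res, lower.tail = FALSE)
  } else {
    F_model <- NA_real_; p_model <- NA_real_
  }
  structure(tab, class = c("anova_table", "data.frame"),
            residual_df = df_res, residual_ms = ms_res,
            model_F = F_model, model_p = p_model,
            model_significant = !is.na(p_model) && p_model <= alpha,
            alpha = alpha)
}

#' Predict from a coded-unit main-effects model
#'
#' @param object a `fitted_model`.
#' @param newdata coded point(s): numeric vector of length k or matrix with
#'   k columns.
#' @param ... ignored.
#' @return numeric vector of predictions `intercept + X %*% beta`.
#' @export
predict.fitted_model <- function(object, newdata, ...) {
  beta <- object$coefficients
  k <- length(beta)
  X <- if (is.null(dim(newdata))) {
    if (length(newdata) != k)
      stop("coded point has length ", length(newdata), " but model has ",
           k, " factors", call. = FALSE)
    matrix(newdata, nrow = 1)
  } else {
    if (ncol(newdata) != k)
      stop("newdata has ", ncol(newdata), " columns but model has ", k,
           " factors", call. = FALSE)
    as.matrix(newdata)
  }
  drop(object$intercept + X %*% beta)
}

#' Desirability specification for one response
#'
#' Derringer-Suich individual desirability with linear ramps. Goals:
#' * `"range"`: d rises linearly from 0 at `low` to 1 at `target`
#'   (defaulting to the midpoint) and falls back to 0 at `high`;
#' * `"maximize"`: 0 at `low`, 1 at or above `high`;
#' * `"minimize"`: 1 at or below `low`, 0 at `high`.
#'
#' @param response response name (must match a fitted model).
#' @param goal one of "range", "maximize", "minimize".
#' @param low,high constraint bounds in response units.
#' @param target optional target for two-sided goals (default midpoint).
#' @param weight geometric-mean weight (default 1).
#' @return a `desirability_spec` object.
#' @export
desirability_spec <- function(response, goal = c("range", "maximize",
                                                 "minimize"),
                              low, high, target = NULL, weight = 1) {
  goal <- match.arg(goal)
  stopifnot(is.numeric(low), is.numeric(high), low < high, weight > 0)
  if (goal == "range") {
    if (is.null(target)) target <- (low + high) / 2
    stopifnot(target > low, target < high)
  }
  structure(list(response = response, goal = goal, low = low, high = high,
                 target = target, weight = weight),
            class = "desirability_spec")
}

#' Individual desirability of predicted response values
#'
#' @param spec a [desirability_spec()].
#' @param y predicted response values.
#' @return desirabilities in `[0, 1]`.
#' @export
desirability <- function(spec, y) {
  stopifnot(inherits(spec, "desirability_spec"))
  d <- switch(spec$goal,
    maximize = (y - spec$low) / (spec$high - spec$low),
    minimize = (spec$high - y) / (spec$high - spec$low),
    range = ifelse(y <= spec$target,
                   (y - spec$low) / (spec$target - spec$low),
                   (spec$high - y) / (spec$high - spec$target))
  )
  pmin(1, pmax(0, d))
}

#' Optimize overall desirability over the coded factor space
#'
#' Evaluates every fitted model on an exhaustive grid over `[-1, 1]^k` at
#' the given resolution, maps predictions through their desirability
#' specifications, combines them by the weighted geometric mean, and returns
#' the maximizing coded point. Ties are broken by the lexicographically
#' smallest coded point; all tied optima are reported.
#'
#' @param models named list of `fitted_model` objects (names = responses).
#' @param specs list of [desirability_spec()] objects covering the same
#'   responses.
#' @param resolution grid step on the coded scale (default 0.1).
#' @return list with `optimum` (coded point), `D` (overall desirability),
#'   `individual` (per-response desirabilities at the optimum), `predicted`
#'   (per-response predictions), `ties` (matrix of all tied optima),
#'   `feasible` (TRUE unless the best D is 0, in which case a warning is
#'   issued and the flag set FALSE).
#' @export
optimize_desirability <- function(models, specs, resolution = 0.1) {
  stopifnot(is.list(models), length(models) >= 1L, is.list(specs))
  spec_names <- vapply(specs, function(s) s$response, character(1))
  names(specs) <- spec_names
  if (!setequal(names(models), spec_names))
    stop("models and desirability specs must cover the same responses",
         call. = FALSE)
  ks <- vapply(models, function(m) length(m$coefficients), integer(1))
  if (length(unique(ks)) != 1L)
    stop("all models must share the same factors", call. = FALSE)
  k <- ks[[1]]

  grid_1d <- seq(-1, 1, by = resolution)
  if (abs(grid_1d[length(grid_1d)] - 1) > 1e-12) grid_1d <- c(grid_1d, 1)
  grid <- as.matrix(expand.grid(rep(list(grid_1d), k),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- names(models[[1]]$coefficients)

  weights <- vapply(specs, function(s) s$weight, numeric(1))
  logD <- matrix(0, nrow(grid), length(models),
                 dimnames = list(NULL, names(models)))
  preds <- logD
  for (nm in names(models)) {
    yhat <- predict(models[[nm]], grid)
    preds[, nm] <- yhat
    logD[, nm] <- weights[[nm]] * log(pmax(desirability(specs[[nm]], yhat),
                                           .Machine$double.xmin))
  }
  D <- exp(rowSums(logD) / sum(weights))
  D[apply(logD, 1, function(r) any(r <= log(.Machine$double.xmin)))] <- 0

  best <- max(D)
  tied <- which(abs(D - best) <= 1e-12)
  # lexicographic tie-break on the coded coordinates
  ord <- do.call(order, as.data.frame(grid[tied, , drop = FALSE]))
  tied <- tied[ord]
  opt_i <- tied[1]

  feasible <- best > 0
  if (!feasible)
    warning("no grid point achieves positive desirability; ",
            "returning the lexicographically smallest point", call. = FALSE)

  opt <- grid[opt_i, ]
  list(
    optimum = opt,
    D = best,
    individual = vapply(names(models), function(nm)
      desirability(specs[[nm]], preds[opt_i, nm]), numeric(1)),
    predicted = preds[opt_i, ],
    ties = grid[tied, , drop = FALSE],
    feasible = feasible,
    resolution = resolution
  )
}
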