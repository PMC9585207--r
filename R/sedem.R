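# SeDeM expert-system powder scoring.
#
# Twelve micromeritic parameters are linearized onto a common 0-10 "radius"
# scale, drawn as a 12-axis radar diagram, and condensed into three indices
# (IP, IPP, IGC) that judge whether a powder can be tableted by direct
# compression without granulation.

# Canonical parameter order (radar axis order, clockwise from 12 o'clock)
# and the five incidence groups.
.sedem_params <- c("Da", "Dc", "Ie", "IC", "Icd", "IH",
                   "alpha", "t_flow", "HR", "H", "Pf", "Itheta")

.sedem_incidences <- list(
  dimension           = c("Da", "Dc"),
  compressibility     = c("Ie", "IC", "Icd"),
  flowability         = c("IH", "alpha", "t_flow"),
  lubricity_stability = c("HR", "H"),
  lubricity_dosage    = c("Pf", "Itheta")
)

#' SeDeM parameter names and incidence groups
#'
#' @return `sedem_parameter_names()` returns the 12 parameter codes in radar
#'   axis order; `sedem_incidence_groups()` returns the named list mapping
#'   each of the five incidence factors to its parameters.
#' @export
sedem_parameter_names <- function() .sedem_params

#' @rdname sedem_parameter_names
#' @export
sedem_incidence_groups <- function() .sedem_incidences

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

.check_pct <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 100)
    stop(sprintf("'%s' must be a percentage in [0, 100]", name), call. = FALSE)
  invisible(x)
}

#' Raw powder measurements for SeDeM evaluation
#'
#' Bundles the bench measurements from which the 12 SeDeM parameters are
#' derived: the mass/volume pair before and after tapping (2500 taps), the
#' mean crushing force of three compacts, the repose-cone geometry, the
#' 100 g funnel flow time, loss on drying, hygroscopicity, the fines
#' fraction (< 50 um), and the sieve-analysis fractions used for the
#' homogeneity index.
#'
#' @param sample_mass_g powder mass P (g) used for the density measurements.
#' @param bulk_volume_ml untapped volume Va (ml).
#' @param tapped_volume_ml volume Vc (ml) after 2500 taps; must not exceed
#'   `bulk_volume_ml`.
#' @param tablet_hardness_N mean crushing force of 3 compacts (N). This is
#'   the cohesion index Icd; if your hardness tester reports kg-force,
#'   convert with [kgf_to_newton()] before constructing the object.
#' @param cone_height_cm,cone_diameter_cm repose cone height h and base
#'   diameter d (cm).
#' @param flow_time_s time (s) for 100 g to pass the standard funnel.
#' @param loss_on_drying_pct %HR, loss on drying (percent).
#' @param hygroscopicity_pct %H, mass gain after 24 h at ~76% RH (percent).
#' @param fines_pct %Pf, percent of particles below 50 um.
#' @param sieve_fractions data.frame with columns `mean_diameter_um` and
#'   `mass_pct`; percentages must sum to 100 +- 0.5.
#' @return an object of class `powder_measurements`.
#' @seealso [compute_micromeritic_parameters()]
#' @export
powder_measurements <- function(sample_mass_g, bulk_volume_ml,
                                tapped_volume_ml, tablet_hardness_N,
                                cone_height_cm, cone_diameter_cm,
                                flow_time_s, loss_on_drying_pct,
                                hygroscopicity_pct, fines_pct,
                                sieve_fractions) {
  .check_positive(sample_mass_g, "sample_mass_g")
  .check_positive(bulk_volume_ml, "bulk_volume_ml")
  .check_positive(tapped_volume_ml, "tapped_volume_ml")
  .check_positive(tablet_hardness_N, "tablet_hardness_N")
  .check_positive(cone_height_cm, "cone_height_cm")
  .check_positive(cone_diameter_cm, "cone_diameter_cm")
  .check_positive(flow_time_s, "flow_time_s")
  .check_pct(loss_on_drying_pct, "loss_on_drying_pct")
  .check_pct(hygroscopicity_pct, "hygroscopicity_pct")
  .check_pct(fines_pct, "fines_pct")
  if (tapped_volume_ml > bulk_volume_ml)
    stop("tapped_volume_ml must be <= bulk_volume_ml", call. = FALSE)
  sieve_fractions <- .validate_sieve_fractions(sieve_fractions)

  structure(list(
    sample_mass_g      = sample_mass_g,
    bulk_volume_ml     = bulk_volume_ml,
    tapped_volume_ml   = tapped_volume_ml,
    tablet_hardness_N  = tablet_hardness_N,
    cone_height_cm     = cone_height_cm,
    cone_diameter_cm   = cone_diameter_cm,
    flow_time_s        = flow_time_s,
    loss_on_drying_pct = loss_on_drying_pct,
    hygroscopicity_pct = hygroscopicity_pct,
    fines_pct          = fines_pct,
    sieve_fractions    = sieve_fractions
  ), class = "powder_measurements")
}

.validate_sieve_fractions <- function(sf) {
  if (!is.data.frame(sf) ||
      !all(c("mean_diameter_um", "mass_pct") %in% names(sf)))
    stop("sieve_fractions must be a data.frame with columns ",
         "'mean_diameter_um' and 'mass_pct'", call. = FALSE)
  if (nrow(sf) < 1L) stop("sieve_fractions must have >= 1 row", call. = FALSE)
  if (any(!is.finite(sf$mean_diameter_um)) || any(sf$mean_diameter_um <= 0))
    stop("sieve mean diameters must be positive", call. = FALSE)
  if (any(!is.finite(sf$mass_pct)) || any(sf$mass_pct < 0))
    stop("sieve mass percentages must be non-negative", call. = FALSE)
  if (abs(sum(sf$mass_pct) - 100) > 0.5)
    stop(sprintf("sieve mass percentages must sum to 100 +- 0.5 (got %.3f)",
                 sum(sf$mass_pct)), call. = FALSE)
  sf[order(-sf$mean_diameter_um), c("mean_diameter_um", "mass_pct")]
}

#' Convert kilogram-force hardness readings to newtons
#'
#' Hardness testers commonly print kg-force while the cohesion index is
#' defined in newtons; the conversion (1 kgf = 9.807 N) is applied at data
#' ingestion, never inside the scoring formulas.
#'
#' @param kgf hardness in kilogram-force.
#' @return hardness in newtons.
#' @export
kgf_to_newton <- function(kgf) kgf * 9.807

#' Derive the 12 SeDeM parameters from raw measurements
#'
#' Computes bulk density `Da = P/Va`, tapped density `Dc = P/Vc`,
#' inter-particle porosity `Ie = (Dc - Da)/(Dc * Da)`, Carr's index
#' `IC = 100 (Dc - Da)/Dc`, Hausner ratio `IH = Dc/Da`, the angle of repose
#' from `tan(alpha) = 2h/d` (degrees), the homogeneity index from the sieve
#' fractions, and passes through the direct measurements (cohesion index,
#' flow time, loss on drying, hygroscopicity, fines).
#'
#' @param m a [powder_measurements()] object.
#' @return an object of class `derived_parameters`: a named list with
#'   elements `Da`, `Dc` (g/ml), `Ie`, `IC` (%), `IH`, `Icd` (N),
#'   `alpha` (degrees), `t_flow` (s), `HR` (%), `H` (%), `Pf` (%), `Itheta`.
#' @export
compute_micromeritic_parameters <- function(m) {
  stopifnot(inherits(m, "powder_measurements"))
  Da <- m$sample_mass_g / m$bulk_volume_ml
  Dc <- m$sample_mass_g / m$tapped_volume_ml
  Ie <- (Dc - Da) / (Dc * Da)
  IC <- (Dc - Da) / Dc * 100
  IH <- Dc / Da
  alpha <- atan(2 * m$cone_height_cm / m$cone_diameter_cm) * 180 / pi

  structure(list(
    Da = Da, Dc = Dc, Ie = Ie, IC = IC, IH = IH,
    Icd = m$tablet_hardness_N,
    alpha = alpha,
    t_flow = m$flow_time_s,
    HR = m$loss_on_drying_pct,
    H = m$hygroscopicity_pct,
    Pf = m$fines_pct,
    Itheta = homogeneity_index(m$sieve_fractions)
  ), class = "derived_parameters")
}

#' Particle-size homogeneity index
#'
#' `Itheta = Fm / (100 + sum_i |d_m - d_i| * F_i)` where `Fm` is the mass
#' percentage in the modal (largest) fraction, `d_m` its mean diameter (um),
#' and the sum runs over all other fractions. All mass concentrated in a
#' single fraction gives the maximum value 1; broad distributions give small
#' values (a well-mixed direct-compression blend sits near 0.01-0.02, the
#' top of the 500*v radius scale).
#'
#' @param fractions data.frame with columns `mean_diameter_um` and
#'   `mass_pct` (summing to ~100).
#' @return the homogeneity index (dimensionless).
#' @export
homogeneity_index <- function(fractions) {
  sf <- .validate_sieve_fractions(fractions)
  m <- which.max(sf$mass_pct)
  dm <- sf$mean_diameter_um[m]
  Fm <- sf$mass_pct[m]
  others <- sf[-m, , drop = FALSE]
  denom <- 100 + sum(abs(dm - others$mean_diameter_um) * others$mass_pct)
  Fm / denom
}

# Linearization factors of the SeDeM table. Each maps a measured value v to
# a radius, clamped afterwards to [0, 10].
.sedem_factors <- list(
  Da     = function(v) 10 * v,
  Dc     = function(v) 10 * v,
  Ie     = function(v) 10 * v / 1.2,
  IC     = function(v) v / 5,
  Icd    = function(v) v / 20,
  IH     = function(v) 5 * (3 - v),
  alpha  = function(v) 10 - v / 5,
  t_flow = function(v) 10 - v / 2,
  HR     = function(v) 10 - v,
  H      = function(v) 10 - v / 2,
  Pf     = function(v) 10 - v / 5,
  Itheta = function(v) 500 * v
)

# Inverses of the linearization maps, for the synthetic generator.
.sedem_inverse_factors <- list(
  Da     = function(r) r / 10,
  Dc     = function(r) r / 10,
  Ie     = function(r) r * 1.2 / 10,
  IC     = function(r) r * 5,
  Icd    = function(r) r * 20,
  IH     = function(r) 3 - r / 5,
  alpha  = function(r) (10 - r) * 5,
  t_flow = function(r) (10 - r) * 2,
  HR     = function(r) 10 - r,
  H      = function(r) (10 - r) * 2,
  Pf     = function(r) (10 - r) * 5,
  Itheta = function(r) r / 500
)

#' Linearize derived parameters into a SeDeM radius profile
#'
#' Applies the standard conversion factor of each parameter (e.g. `10 v` for
#' the densities, `v/20` for the cohesion index, `5 (3 - v)` for the Hausner
#' ratio) and clamps every radius to the common 0-10 scale. Radii >= 5 are
#' considered acceptable for direct compression.
#'
#' @param p a `derived_parameters` object, or a named list/vector providing
#'   the 12 parameter values on their measurement scales.
#' @return an object of class `sedem_profile` holding the 12 radii (named,
#'   in canonical axis order) and the incidence grouping.
#' @export
linearize_profile <- function(p) {
  vals <- unclass(p)
  missing <- setdiff(.sedem_params, names(vals))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  radii <- vapply(.sedem_params, function(nm) {
    r <- .sedem_factors[[nm]](as.numeric(vals[[nm]]))
    min(10, max(0, r))
  }, numeric(1))
  sedem_profile(radii)
}

#' Construct a SeDeM profile from radius values
#'
#' @param radii named numeric vector of 12 radii in `[0, 10]`, named after
#'   [sedem_parameter_names()] (any order; stored canonically).
#' @return a `sedem_profile` object.
#' @export
sedem_profile <- function(radii) {
  if (is.null(names(radii)) || !setequal(names(radii), .sedem_params))
    stop("radii must be named with exactly the 12 SeDeM parameters: ",
         paste(.sedem_params, collapse = ", "), call. = FALSE)
  radii <- radii[.sedem_params]
  if (any(!is.finite(radii)) || any(radii < 0) || any(radii > 10))
    stop("all radii must be finite and within [0, 10]", call. = FALSE)
  structure(list(radii = radii, incidence_groups = .sedem_incidences),
            class = "sedem_profile")
}

#' @export
print.sedem_profile <- function(x, ...) {
  cat("SeDeM profile (12 parameters, radius 0-10)\n")
  print(round(x$radii, 2))
  invisible(x)
}

#' Reliability factor of an n-parameter SeDeM diagram
#'
#' Ratio of the regular n-gon area to its circumscribed circle. For the
#' standard 12-parameter diagram the published constant 0.952 is used (the
#' exact geometric ratio is 0.9549; the rounded value is the field's
#' convention and every downstream IGC figure depends on it). For other n
#' the geometric formula `n sin(2 pi / n) / (2 pi)` applies.
#'
#' @param n number of parameters on the diagram.
#' @return the reliability factor f in (0, 1).
#' @export
reliability_factor <- function(n = 12) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 3)
  if (n == 12) return(0.952)
  n * sin(2 * pi / n) / (2 * pi)
}

#' SeDeM diagram indices
#'
#' Computes the parameter index `IP` (fraction of radii >= 5), the parameter
#' profile index `IPP` (mean of all radii), the reliability factor `f`, and
#' the good compressibility index `IGC = IPP * f`. An IGC of at least 5
#' marks a powder suitable for direct compression. Deficient parameters
#' (radius < 5) and per-incidence mean radii are reported for diagnosis.
#'
#' @param profile a `sedem_profile`. Profiles with other than 12 radii are
#'   rejected unless `generalized = TRUE`, in which case the reliability
#'   factor is computed geometrically for the actual parameter count.
#' @param generalized allow n != 12 parameters (default FALSE).
#' @return an object of class `sedem_indices` with elements `IP`, `IPP`,
#'   `f`, `IGC`, `deficient_parameters`, `incidence_means`, `n_parameters`.
#' @export
compute_indices <- function(profile, generalized = FALSE) {
  if (inherits(profile, "sedem_profile")) {
    radii <- profile$radii
    groups <- profile$incidence_groups
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    radii <- profile
    groups <- NULL
  } else {
    stop("profile must be a sedem_profile or a named numeric vector",
         call. = FALSE)
  }
  n <- length(radii)
  if (n != 12L && !generalized)
    stop("profile has ", n, " radii; the standard SeDeM diagram needs 12 ",
         "(use generalized = TRUE for other sizes)", call. = FALSE)

  IP  <- sum(radii >= 5) / n
  IPP <- mean(radii)
  f   <- reliability_factor(n)
  IGC <- IPP * f
  incidence_means <- if (!is.null(groups))
    vapply(groups, function(g) mean(radii[g]), numeric(1)) else NULL

  structure(list(
    IP = IP, IPP = IPP, f = f, IGC = IGC,
    deficient_parameters = names(radii)[radii < 5],
    incidence_means = incidence_means,
    n_parameters = n
  ), class = "sedem_indices")
}

#' @export
print.sedem_indices <- function(x, ...) {
  cat(sprintf("SeDeM indices (n = %d)\n", x$n_parameters))
  cat(sprintf("  IP  = %.2f\n  IPP = %.2f\n  f   = %.3f\n  IGC = %.2f\n",
              x$IP, x$IPP, x$f, x$IGC))
  if (length(x$deficient_parameters))
    cat("  deficient (< 5):",
        paste(x$deficient_parameters, collapse = ", "), "\n")
  else cat("  no deficient parameters\n")
  invisible(x)
}

#' Minimum corrective-excipient fraction
#'
#' The fraction of a well-performing excipient needed to lift a deficient
#' powder parameter to its acceptance radius:
#' `CP = 100 - (RE - R)/(RE - RP) * 100`, where `RE` is the excipient's
#' radius, `RP` the powder's deficient radius and `R` the target radius
#' (conventionally 5). Correction is only feasible when the excipient
#' outperforms both the powder (`RE > RP`) and the target (`RE >= R`).
#'
#' @param RE excipient radius for the deficient parameter or incidence.
#' @param RP powder radius to be corrected.
#' @param R desired minimum radius (default 5).
#' @return an object of class `correction_plan` with `CP_pct`, `RE`, `RP`,
#'   `R`.
#' @export
corrective_excipient_fraction <- function(RE, RP, R = 5) {
  stopifnot(is.numeric(RE), is.numeric(RP), is.numeric(R))
  if (RE <= RP)
    stop("infeasible correction: excipient radius RE (", RE,
         ") must exceed powder radius RP (", RP, ")", call. = FALSE)
  if (RE < R)
    stop("excipient insufficient: RE (", RE, ") is below the target R (",
         R, ")", call. = FALSE)
  CP <- 100 - (RE - R) / (RE - RP) * 100
  structure(list(CP_pct = CP, RE = RE, RP = RP, R = R),
            class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  cat(sprintf("Corrective excipient: %.2f%% (RE = %.2f, RP = %.2f, R = %.2f)\n",
              x$CP_pct, x$RE, x$RP, x$R))
  invisible(x)
}

#' Radar-chart geometry for a SeDeM profile
#'
#' Places the 12 radii on equally spaced axes (first axis at 12 o'clock,
#' proceeding clockwise in canonical order) and reports the polygon vertices
#' and its area by the shoelace formula. A perfect profile (all radii 10)
#' encloses 300 square units, i.e. 0.952 of the radius-10 circle up to the
#' convention's rounding.
#'
#' @param profile a `sedem_profile`.
#' @return list with `vertices` (data.frame: parameter, radius, angle_rad,
#'   x, y) and `area`.
#' @export
radar_chart_data <- function(profile) {
  stopifnot(inherits(profile, "sedem_profile"))
  r <- profile$radii
  n <- length(r)
  # 12 o'clock start, clockwise
  theta <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  x <- r * cos(theta)
  y <- r * sin(theta)
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  list(
    vertices = data.frame(parameter = names(r), radius = unname(r),
                          angle_rad = theta, x = x, y = y,
                          row.names = NULL),
    area = area
  )
}

# Inverse linearization (exported for the synthetic generator and tests).
#' Map a radius back to the measurement scale of a SeDeM parameter
#'
#' Exact inverse of the linearization factors for radii inside (0, 10);
#' clamped radii are not invertible.
#'
#' @param parameter one of [sedem_parameter_names()].
#' @param radius radius value in `[0, 10]`.
#' @return the measurement-scale value v.
#' @export
inverse_linearize <- function(parameter, radius) {
  parameter <- match.arg(parameter, .sedem_params)
  stopifnot(is.numeric(radius), all(radius >= 0), all(radius <= 10))
  .sedem_inverse_factors[[parameter]](radius)
}
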