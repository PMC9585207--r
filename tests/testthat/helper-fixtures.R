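# Shared fixtures: the tramadol-like parameter set used across PK tests and
# a reference powder measurement built in code.

tramadol_disposition <- function(weight = 70) {
  disposition_params(Vc = 1.4776, k12 = 0.4021, k21 = 0.0569,
                     CL = 0.00572, body_weight_kg = weight)
}

tramadol_drug <- function() {
  drug_properties(logP = 2.64, pKa = 9.2, MW = 263.38,
                  solubility_mg_ml = 0.75, diffusion_cm2_s = 0.75e-5,
                  density_g_ml = 1.2, Peff_cm_s = 3.26e-4,
                  fup_pct = 77.5, Rbp = 1.03)
}

# measurements chosen to give round derived values: Da 0.5, Dc 0.625,
# Ie 0.4, IC 20, IH 1.25, alpha = atan(0.5)
reference_measurements <- function() {
  powder_measurements(
    sample_mass_g = 10, bulk_volume_ml = 20, tapped_volume_ml = 16,
    tablet_hardness_N = 122, cone_height_cm = 2, cone_diameter_cm = 8,
    flow_time_s = 10, loss_on_drying_pct = 2, hygroscopicity_pct = 3,
    fines_pct = 10,
    sieve_fractions = data.frame(
      mean_diameter_um = c(283.5, 156, 75),
      mass_pct = c(20, 60, 20)))
}

# independent shoelace oracle used against radar_chart_data()
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
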