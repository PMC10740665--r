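# shared fixture builders (everything is generated in code)

make_profile <- function(K, concs, params = model_params()) {
  data.frame(conc_mg_ml = concs, visc_cP = viscosity(K, concs, params))
}

# collinear (K, measurement) pairs lying exactly on a calibration line
make_line_pairs <- function(K, line) {
  data.frame(molecule_id = sprintf("P%02d", seq_along(K)), K = K,
             measurement = line$intercept - line$slope * K)
}

# a small hand-built cohort with known K values and exact viscosity profiles
make_exact_cohort <- function(K, concs = c(110, 150, 200),
                              params = model_params(),
                              lines = reference_lines()) {
  ids <- sprintf("M%02d", seq_along(K))
  molecules <- data.frame(
    molecule_id = ids,
    dnp_um2_per_s = lines$acsins$intercept - lines$acsins$slope * K,
    kd_ml_per_g = lines$dls$intercept - lines$dls$slope * K
  )
  visc <- do.call(rbind, lapply(seq_along(K), function(i) {
    data.frame(molecule_id = ids[i], conc_mg_ml = concs,
               visc_cP = viscosity(K[i], concs, params))
  }))
  ab_cohort(molecules, visc)
}
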