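# Shared fixtures: small noiseless models and curve builders.

noiseless_model <- function(lipid = "DMPC", scaffold = "LUV") {
  update(condition_model(lipid, scaffold), noise_sd = 0)
}

# Analytic GP curve on a grid (no spectra involved): independent of the
# spectrum-synthesis path.
ideal_curve <- function(model, temperatures, condition = NULL) {
  gp_curve(temperatures, ideal_gp(temperatures, model), condition = condition)
}

# Build a tiny spectrum from explicit intensities at the GP wavelengths.
two_point_spectrum <- function(i440, i490, temperature = 25) {
  emission_spectrum(c(400, 440, 490, 540), c(0, i440, i490, 0), temperature)
}

# Hand-built derivative object (for tie-break / truncated-peak cases).
make_derivative <- function(temperature, values,
                            endpoint = c(TRUE, rep(FALSE, length(values) - 2L),
                                         TRUE)) {
  structure(data.frame(temperature = temperature, neg_dgp_dt = values),
            class = c("gp_derivative", "data.frame"), endpoint = endpoint)
}
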