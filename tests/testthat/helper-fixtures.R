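# Shared fixtures, built once per test run and cached: the noise-free
# default VSMC recording and its analysis are used by several files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

vsmc_phi <- function(genotype = "protective") {
  fixture(paste0("vsmc_phi_", genotype), function()
    simulate_phi_trace(scenario_params("vsmc", genotype),
                       default_protocol("co2_dma")))
}

vsmc_fluor_clean <- function(genotype = "protective") {
  fixture(paste0("vsmc_fluor_clean_", genotype), function()
    render_fluorescence(vsmc_phi(genotype),
                        optics_params(noise_cv = 0), seed = 1))
}

vsmc_analysis_clean <- function(genotype = "protective") {
  fixture(paste0("vsmc_analysis_clean_", genotype), function()
    analyze_cell(vsmc_fluor_clean(genotype)))
}

# A minimal single-segment recovery protocol for steady-state checks.
recovery_only_protocol <- function(end_s = 3600, co2_on = TRUE,
                                   dma_on = TRUE, interval_s = 15) {
  protocol_spec(
    data.frame(name = "recovery", start_s = 0, end_s = end_s,
               co2_on = co2_on, dma_on = dma_on, na_on = TRUE,
               nh4cl_mM = 0, ph_o = 7.4),
    data.frame(interval_s = interval_s, segments = "recovery"))
}

# Exact linear calibration points on ratio = intercept + slope * ph.
linear_cal_points <- function(slope = 1.2, intercept = 0.5,
                              ph = c(6.5, 7.0, 7.5)) {
  data.frame(buffer_ph = ph, ratio = intercept + slope * ph)
}
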