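# Reference configurations shared across tests: the published fluorescein
# calibration of the reader and its detector constants.

ref_params <- function() {
  calibration_params(rb = 1650, d_rb = 22, k = 0.0283, d_k = 0.0010,
                     gamma = 1.054, d_gamma = 0.019, n_blanks = 18)
}

ref_cfg <- function(...) detector_config(...)

# Detector configuration with a warm-up long enough that the simulated LDR
# equilibration lag is numerically negligible (exp(-40) of the dark offset);
# used by tests that exercise the exact zero-noise limit.
settled_cfg <- function(...) detector_config(warmup_s = 120, ...)

noiseless_sim <- function(...) {
  simulator_config(count_noise_rel = 0, sample_noise_rel = 0,
                   quantize = FALSE, ...)
}
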