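# shared fixtures, all generated in code

noiseless <- function(preset) {
  preset$ee_noise_sd <- 0
  preset$rer_noise_sd <- 0
  preset
}

baseline_preset <- function() builtin_presets()$baseline

# tiny noiseless baseline series, reused across files
noiseless_baseline_series <- function(seed = 1) {
  derive_metabolic_series(
    generate_calorimetry_trace(noiseless(baseline_preset()), seed = seed)
  )
}

bin_mean <- function(binned, chan, ph = NULL) {
  i <- binned$channel == chan
  if (!is.null(ph)) i <- i & binned$phase == ph
  binned$mean[i]
}
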