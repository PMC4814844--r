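# Noise-free amplitude model (default levels) for deterministic tests.
noise_free_model <- function(...) {
  amplitude_model(noise_sd_fam = 0, noise_sd_hex = 0, ...)
}

# Standard error of a class's estimated percentage of total copies, from a
# quant_estimate (delta method with the total rate treated as fixed).
freq_se_pct <- function(q, class) {
  100 * q$se[[class]] / sum(q$lambda)
}

# Estimated percentage of total copies for one class.
freq_pct <- function(q, class) {
  100 * q$lambda[[class]] / sum(q$lambda)
}
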