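# deterministic fixtures shared across the test files

# waveform spec with every stochastic component switched off: trials are
# exact template + artifact + decay realisations
quiet_wspec <- function(noise_rms = 0, trial_cv = 0, m_trial_cv = 0,
                        m_recruit_noise = 0, drift_sd_ma = 0, ...) {
  waveform_spec(noise_rms = noise_rms, trial_cv = trial_cv,
                m_trial_cv = m_trial_cv, m_recruit_noise = m_recruit_noise,
                drift_sd_ma = drift_sd_ma, ...)
}

# short noiseless run for contract checks
quiet_run <- function(truth = recruitment_truth(), seed = 7,
                      protocol = sweep_protocol(trials_per_step = 2), ...) {
  generate_run(truth, protocol, quiet_wspec(...), seed = seed)
}

# per-intensity means of a recruitment_data column, ordered by intensity
step_mean <- function(data, col) {
  a <- stats::aggregate(data[[col]], list(s = data$intensity_mA), mean)
  a[order(a$s), ]
}

# build an epoch object directly from a sample vector
make_epoch <- function(samples, fs = 3200, t0_index = 0, intensity = 10) {
  structure(list(samples = samples, fs = fs, intensity = intensity,
                 t0_index = t0_index), class = "epoch")
}
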