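#' Recruitment-curve sweep protocol
#'
#' Describes how stimulation intensity is ramped during a recruitment-curve
#' run: the acquisition system increases the intensity in predefined steps
#' after a set number of trials, stimulating at ~1 Hz with a jittered
#' inter-stimulus interval, up to a hard safety cap of 50 mA.
#'
#' @param start_intensity First ramp intensity (mA).
#' @param step Ramp increment (mA); must be > 0.
#' @param trials_per_step Number of trials delivered at each intensity.
#' @param max_intensity Safety cap (mA), at most 50.
#' @param isi_mean Mean inter-stimulus interval (s).
#' @param isi_jitter_frac Uniform ISI jitter as a fraction of `isi_mean`.
#' @param fs Base sampling rate (Hz).
#' @return An object of class `sweep_protocol`.
#' @export
sweep_protocol <- function(start_intensity = 8, step = 1, trials_per_step = 4,
                           max_intensity = 50, isi_mean = 1.0,
                           isi_jitter_frac = 0.10, fs = 3200) {
  if (step <= 0) stop("step must be > 0")
  if (max_intensity > 50) stop("max_intensity exceeds the 50 mA safety cap")
  if (trials_per_step < 1) stop("trials_per_step must be >= 1")
  if (start_intensity < 0) stop("start_intensity must be non-negative")
  if (start_intensity > max_intensity) stop("empty ramp: start beyond cap")
  structure(list(start_intensity = start_intensity, step = step,
                 trials_per_step = trials_per_step,
                 max_intensity = max_intensity, isi_mean = isi_mean,
                 isi_jitter_frac = isi_jitter_frac, fs = fs),
            class = "sweep_protocol")
}

#' Per-trial EMG waveform specification
#'
#' Controls the shape of each simulated trial: a 1-ms stimulus-artifact
#' boxcar followed by an exponential decay tail, an M-wave template in the
#' 6-23 ms band, an H-reflex template in the 28-45 ms band with main
#' positive/negative peaks 5 ms apart, band-limited background noise, and
#' multiplicative (lognormal) trial-to-trial amplitude variability.
#'
#' The M template is a Gaussian-windowed one-cycle sinusoid; the H template
#' is a one-cycle sinusoid (half-period = `h_peak_separation`) followed by a
#' slower terminal recovery half-wave, approximating the triphasic
#' morphology of surface-recorded soleus H-reflexes. Each template is scaled
#' so that its mean rectified value inside the canonical window
#' (`m_window`, `h_window`) equals the requested recruitment amplitude.
#'
#' @param artifact_amp Stimulus artifact amplitude (uV).
#' @param artifact_width Artifact pulse width (ms).
#' @param decay_amp Initial amplitude of the post-artifact exponential
#'   decay tail (uV).
#' @param decay_tau Decay time constant (ms).
#' @param m_latency M-wave onset latency (ms post-trigger).
#' @param m_duration M-wave template duration (ms).
#' @param h_latency H-reflex onset latency (ms post-trigger).
#' @param h_peak_separation Separation of the H-reflex main positive and
#'   negative peaks (ms); implies a ~100 Hz fundamental at the default 5 ms.
#' @param h_tail_frac Relative amplitude of the slow recovery phase.
#' @param h_tail_ms Duration of the slow recovery phase (ms).
#' @param noise_rms Background EMG noise RMS (uV), band-limited 10-500 Hz.
#' @param trial_cv Coefficient of variation of the multiplicative lognormal
#'   trial-to-trial H-reflex amplitude factor (the H-reflex is the more
#'   variable response, reflecting fluctuating motoneuron excitability).
#' @param m_trial_cv Trial-to-trial CV of the M-wave amplitude (the direct
#'   muscle response is considerably more stable).
#' @param m_recruit_noise Trial-to-trial M-wave recruitment noise scale as
#'   a fraction of `m_max`. The noise has a binomial-like variance profile
#'   (`2*sqrt(p*(1-p))` with `p` the recruited fraction): zero below
#'   threshold and at the plateau, maximal mid-recruitment, emulating the
#'   granularity and excitability fluctuation of motor-axon recruitment.
#' @param drift_sd_ma Stationary standard deviation (mA) of the slow
#'   within-run drift of effective stimulation intensity: the excitation
#'   actually reaching the nerve wanders around the commanded current as
#'   posture and electrode coupling change. Modelled as an AR(1) process
#'   across trials.
#' @param drift_tau_s Correlation time of the drift process (s).
#' @param m_window,h_window Canonical measurement windows (ms post-trigger)
#'   used for template normalisation and as the default manual windows.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(artifact_amp = 300, artifact_width = 1.0,
                          decay_amp = 100, decay_tau = 1.5,
                          m_latency = 6.5, m_duration = 15,
                          h_latency = 27.5, h_peak_separation = 5.0,
                          h_tail_frac = 0.6, h_tail_ms = 6,
                          noise_rms = 4, trial_cv = 0.15, m_trial_cv = 0.05,
                          m_recruit_noise = 0.02,
                          drift_sd_ma = 0.1, drift_tau_s = 60,
                          m_window = c(6, 23), h_window = c(28, 45)) {
  if (h_peak_separation <= 0) stop("h_peak_separation must be > 0")
  if (m_latency + m_duration >= h_latency)
    stop("M-wave must end before the H-reflex begins")
  structure(list(artifact_amp = artifact_amp, artifact_width = artifact_width,
                 decay_amp = decay_amp, decay_tau = decay_tau,
                 m_latency = m_latency, m_duration = m_duration,
                 h_latency = h_latency, h_peak_separation = h_peak_separation,
                 h_tail_frac = h_tail_frac, h_tail_ms = h_tail_ms,
                 noise_rms = noise_rms, trial_cv = trial_cv,
                 m_trial_cv = m_trial_cv, m_recruit_noise = m_recruit_noise,
                 drift_sd_ma = drift_sd_ma, drift_tau_s = drift_tau_s,
                 m_window = m_window, h_window = h_window),
            class = "waveform_spec")
}

#' Fundamental frequency implied by the H-reflex peak separation
#'
#' Main positive and negative peaks separated by `h_peak_separation` ms
#' correspond to a half-period of that length, i.e. a fundamental of
#' `1000 / (2 * h_peak_separation)` Hz (100 Hz at the default 5 ms).
#'
#' @param wspec A [waveform_spec()] object.
#' @return Fundamental frequency in Hz.
#' @export
h_fundamental_hz <- function(wspec = waveform_spec()) {
  1000 / (2 * wspec$h_peak_separation)
}

#' Background-EMG gating specification
#'
#' Stimulation is only permitted once the rectified background EMG has
#' stayed at a predefined low level (5-18 uV in soleus during normal
#' standing) for at least `hold_duration` seconds.
#'
#' @param background_limit_low,background_limit_high Acceptable background
#'   band (uV).
#' @param hold_duration Time the background must remain below the high
#'   limit before a trigger is permitted (s).
#' @return An object of class `gating_spec`.
#' @export
gating_spec <- function(background_limit_low = 5, background_limit_high = 18,
                        hold_duration = 2) {
  if (background_limit_low >= background_limit_high)
    stop("background_limit_low must be < background_limit_high")
  if (hold_duration <= 0) stop("hold_duration must be > 0")
  structure(list(background_limit_low = background_limit_low,
                 background_limit_high = background_limit_high,
                 hold_duration = hold_duration),
            class = "gating_spec")
}
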