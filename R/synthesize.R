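#' @rdname generate_run
#' @param fs Sampling rate (Hz).
#' @param trials List of trials as produced by [generate_trial()].
#' @param subject_id Subject label.
#' @param truth Optional [recruitment_truth()] carried for validation.
#' @param seed Seed the run was generated with (or `NA`).
#' @export
sweep_run <- function(fs, trials, subject_id = "S1", truth = NULL,
                      seed = NA_integer_) {
  stopifnot(length(trials) > 0)
  intens <- vapply(trials, `[[`, numeric(1), "intensity")
  if (any(diff(intens) < 0))
    stop("trial intensities must be non-decreasing across the ramp")
  structure(list(fs = fs, trials = trials, subject_id = subject_id,
                 truth = truth, seed = seed),
            class = "sweep_run")
}

#' @export
print.sweep_run <- function(x, ...) {
  intens <- intensities(x)
  cat(sprintf("Recruitment-curve run '%s': %d trials, %g Hz, %g-%g mA\n",
              x$subject_id, length(x$trials), x$fs, min(intens), max(intens)))
  if (!is.null(x$truth)) cat("  (ground truth attached)\n")
  invisible(x)
}

#' Stimulation intensities of a run
#' @param run A [sweep_run()] object.
#' @return Numeric vector, one intensity (mA) per trial.
#' @export
intensities <- function(run) {
  vapply(run$trials, `[[`, numeric(1), "intensity")
}

# time axis in ms relative to the trigger for a trial of n samples whose
# trigger sits at 0-based sample `trigger_index`
trial_time_ms <- function(n, trigger_index, fs) {
  ((seq_len(n) - 1) - trigger_index) / fs * 1000
}

# Biphasic M-wave template: Gaussian-windowed one-cycle sinusoid spanning
# [m_latency, m_latency + m_duration) ms.
m_template <- function(t_ms, wspec) {
  lat <- wspec$m_latency; dur <- wspec$m_duration
  ctr <- lat + dur / 2
  x <- numeric(length(t_ms))
  i <- t_ms >= lat & t_ms < lat + dur
  x[i] <- sin(2 * pi * (t_ms[i] - lat) / dur) *
    exp(-0.5 * ((t_ms[i] - ctr) / (dur / 4))^2)
  x
}

# Triphasic H-reflex template: one-cycle sinusoid with half-period equal to
# the main peak separation, followed by a slower terminal recovery
# half-wave of the same polarity as the second phase.
h_template <- function(t_ms, wspec) {
  lat <- wspec$h_latency; per <- 2 * wspec$h_peak_separation
  x <- numeric(length(t_ms))
  i <- t_ms >= lat & t_ms < lat + per
  x[i] <- sin(2 * pi * (t_ms[i] - lat) / per)
  j <- t_ms >= lat + per & t_ms < lat + per + wspec$h_tail_ms
  x[j] <- x[j] - wspec$h_tail_frac * sin(pi * (t_ms[j] - lat - per) / wspec$h_tail_ms)
  x
}

# scale template so its MRV inside `window` equals 1 (at this fs/alignment)
normalise_template <- function(x, t_ms, window) {
  i <- t_ms >= window[1] & t_ms < window[2]
  m <- mean(abs(x[i]))
  if (m <= 0) stop("template has no energy inside its canonical window")
  x / m
}

# Band-limited Gaussian background noise with the spectral shape of quiet
# standing soleus EMG: most power concentrated below ~150 Hz (motor-unit
# activity), plus a smaller broadband component up to 500 Hz. Scaled to an
# exact RMS.
band_limited_noise <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  unit <- function(lo, hi) {
    bf <- signal::butter(2, c(lo, min(hi, 0.45 * fs)) / (fs / 2),
                         type = "pass")
    x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
    x / sqrt(mean(x^2))
  }
  x <- sqrt(0.85) * unit(15, 150) + sqrt(0.15) * unit(10, 500)
  x * rms / sqrt(mean(x^2))
}

# multiplicative lognormal factor with mean 1 and coefficient of variation cv
lognormal_factor <- function(cv) {
  if (cv <= 0) return(1)
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(1, mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate one simulated recruitment-curve trial
#'
#' Synthesises a single soleus EMG trial at stimulation intensity `s`:
#' biphasic stimulus-artifact pulse, exponential decay tail, M-wave and H-reflex
#' templates scaled so that their mean rectified values in the canonical
#' windows equal the ground-truth recruitment amplitudes (times a
#' multiplicative lognormal trial factor with CV `trial_cv`), plus
#' band-limited Gaussian background noise. The trial spans -250 to +450 ms
#' around the trigger, comfortably covering the -200..+400 ms epoch.
#'
#' @param s Stimulation intensity (mA).
#' @param truth A [recruitment_truth()] object.
#' @param wspec A [waveform_spec()] object.
#' @param fs Sampling rate (Hz); integer, at least 320.
#' @param isi Inter-stimulus interval to record with the trial (s).
#' @param seed Optional seed; when given, the trial is generated under a
#'   local RNG state (bit-identical for identical seeds) and the caller's
#'   RNG is untouched. When `NULL` the current RNG state is consumed.
#' @return A `trial` list with fields `intensity`, `samples` (uV),
#'   `trigger_index` (0-based sample index of the stimulus onset) and `isi`.
#' @export
generate_trial <- function(s, truth, wspec = waveform_spec(), fs = 3200,
                           isi = 1.0, seed = NULL, s_effective = s) {
  if (fs != round(fs)) stop("fs must be an integer number of Hz")
  if (fs < 320) stop("fs must be at least 320 Hz")
  if (!is.null(seed)) {
    return(with_local_seed(seed,
      generate_trial(s, truth, wspec, fs, isi, seed = NULL,
                     s_effective = s_effective)))
  }
  n_pre <- round(0.25 * fs); n_post <- round(0.45 * fs)
  n <- n_pre + n_post
  # the stimulus is asynchronous with the sampling clock: jitter the
  # trigger sample within a 40-sample window so that decimation by any
  # factor up to 10 sees uniformly distributed sub-sample trigger offsets
  trig <- n_pre + sample.int(40L, 1L) - 1L
  t_ms <- trial_time_ms(n, trig, fs)

  x <- numeric(n)
  # charge-balanced biphasic stimulus pulse: positive then negative lobe
  half <- wspec$artifact_width / 2
  x[t_ms >= 0 & t_ms < half] <- wspec$artifact_amp
  x[t_ms >= half & t_ms < wspec$artifact_width] <- -wspec$artifact_amp
  post <- t_ms >= 0
  x[post] <- x[post] + wspec$decay_amp * exp(-t_ms[post] / wspec$decay_tau)

  # motor-unit recruitment noise: binomial-like variance profile, zero
  # below threshold and at the plateau, maximal mid-recruitment
  p_rec <- true_m_amplitude(s_effective, truth) / truth$m_max
  m_amp <- true_m_amplitude(s_effective, truth) *
    lognormal_factor(wspec$m_trial_cv) +
    wspec$m_recruit_noise * truth$m_max * 2 * sqrt(p_rec * (1 - p_rec)) *
      stats::rnorm(1)
  m_amp <- max(m_amp, 0)
  h_amp <- true_h_amplitude(s_effective, truth) *
    lognormal_factor(wspec$trial_cv)
  x <- x + m_amp * normalise_template(m_template(t_ms, wspec), t_ms, wspec$m_window)
  x <- x + h_amp * normalise_template(h_template(t_ms, wspec), t_ms, wspec$h_window)
  x <- x + band_limited_noise(n, fs, wspec$noise_rms)

  list(intensity = s, samples = x, trigger_index = trig, isi = isi)
}

#' Generate a full recruitment-curve run
#'
#' Ramps stimulation intensity in `protocol$step` increments from
#' `protocol$start_intensity`, delivering `protocol$trials_per_step` trials
#' per step, until either the safety cap is reached or the ground-truth
#' M-wave has exceeded 99% of `m_max` for two consecutive steps (the
#' M-wave plateau, at which point the operator stops the ramp). ISIs are
#' drawn uniformly within `isi_mean * (1 +/- isi_jitter_frac)`.
#'
#' Runs are deterministic given `(seed, subject_id)`: the effective seed is
#' derived from both, so different subjects get different noise streams.
#'
#' @param truth A [recruitment_truth()] object.
#' @param protocol A [sweep_protocol()] object.
#' @param wspec A [waveform_spec()] object.
#' @param subject_id Subject label.
#' @param seed Integer seed.
#' @return A [sweep_run()] object with the truth attached.
#' @export
generate_run <- function(truth, protocol = sweep_protocol(),
                         wspec = waveform_spec(), subject_id = "S1",
                         seed = 1L) {
  steps <- seq(protocol$start_intensity, protocol$max_intensity,
               by = protocol$step)
  if (length(steps) == 0) stop("empty ramp")
  keep <- length(steps)
  for (i in seq_along(steps)) {
    if (i >= 2 &&
        all(true_m_amplitude(steps[c(i - 1, i)], truth) >
            0.99 * truth$m_max)) { keep <- i; break }
  }
  steps <- steps[seq_len(keep)]
  eff_seed <- derive_seed(seed, subject_hash(subject_id))
  trials <- with_local_seed(eff_seed, {
    out <- vector("list", length(steps) * protocol$trials_per_step)
    k <- 0
    drift <- stats::rnorm(1, 0, wspec$drift_sd_ma)
    for (s in steps) for (j in seq_len(protocol$trials_per_step)) {
      isi <- protocol$isi_mean *
        (1 + stats::runif(1, -protocol$isi_jitter_frac,
                          protocol$isi_jitter_frac))
      # slow AR(1) wander of the effective afferent excitation
      rho <- exp(-isi / wspec$drift_tau_s)
      drift <- rho * drift +
        sqrt(1 - rho^2) * stats::rnorm(1, 0, wspec$drift_sd_ma)
      k <- k + 1
      out[[k]] <- generate_trial(s, truth, wspec, protocol$fs, isi = isi,
                                 s_effective = max(s + drift, 0))
    }
    out
  })
  sweep_run(protocol$fs, trials, subject_id, truth, seed)
}

# stable small hash of a subject label
subject_hash <- function(subject_id) {
  sum(utf8ToInt(as.character(subject_id)) *
        seq_along(utf8ToInt(as.character(subject_id)))) %% 99991L
}

# counter-based seed derivation: adding subjects never perturbs earlier ones
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 69091 + as.double(counter) * 7901 + 17) %%
               2147483647)
}

#' Background-EMG trigger gating
#'
#' A sample is trigger-permitted if and only if the rectified (optionally
#' moving-average smoothed) background EMG has stayed at or below
#' `gspec$background_limit_high` for the preceding `gspec$hold_duration`
#' seconds.
#'
#' @param background Background EMG series (uV).
#' @param gspec A [gating_spec()] object.
#' @param fs Sampling rate (Hz).
#' @param smooth_ms Moving-average smoothing window applied to the
#'   rectified series before thresholding (ms); 0 disables smoothing.
#' @return Logical vector, `TRUE` where a trigger is permitted.
#' @export
simulate_gating <- function(background, gspec = gating_spec(), fs,
                            smooth_ms = 0) {
  hold_n <- round(gspec$hold_duration * fs)
  if (length(background) < hold_n)
    stop("background series shorter than the hold duration")
  r <- abs(background)
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * fs))
    r <- as.numeric(stats::filter(r, rep(1 / w, w), sides = 1))
    r[seq_len(w - 1)] <- r[w]
  }
  bad <- as.integer(r > gspec$background_limit_high)
  cs <- cumsum(bad)
  n <- length(r)
  ok <- logical(n)
  i <- hold_n:n
  ok[i] <- (cs[i] - c(0, cs)[i - hold_n + 1]) == 0
  ok
}

#' Simulate a cohort of recruitment-curve runs
#'
#' Draws per-subject ground truths (see [draw_truth()]) and generates one
#' run per subject. Per-subject seeds are derived from `master_seed` with a
#' counter, so enlarging the cohort never changes existing subjects.
#'
#' @param n_subjects Number of subjects.
#' @param master_seed Cohort master seed.
#' @param protocol,wspec Protocol and waveform settings shared by the cohort.
#' @param ranges Truth parameter ranges passed to [draw_truth()].
#' @param out_dir Optional directory; when given each run is also written
#'   with [write_run()].
#' @return A list of [sweep_run()] objects named by subject id.
#' @export
simulate_cohort <- function(n_subjects, master_seed = 1L,
                            protocol = sweep_protocol(),
                            wspec = waveform_spec(), ranges = list(),
                            out_dir = NULL) {
  stopifnot(n_subjects >= 1)
  runs <- vector("list", n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    truth <- draw_truth(derive_seed(master_seed, 1000L + i))
    runs[[i]] <- generate_run(truth, protocol, wspec, subject_id = ids[i],
                              seed = derive_seed(master_seed, i))
    if (!is.null(out_dir)) write_run(runs[[i]], out_dir)
  }
  names(runs) <- ids
  runs
}
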