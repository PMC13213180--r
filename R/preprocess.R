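#' Butterworth filter specification
#'
#' All filters used by the pipeline are 2nd-order Butterworth designs: the
#' 10 Hz high-pass that emulates the acquisition path, and the low-pass
#' anti-alias filters applied before downsampling (200 Hz for 640 Hz,
#' 100 Hz for 320 Hz).
#'
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff Cutoff frequency (Hz); must be below Nyquist when applied.
#' @param order Filter order (2 throughout the pipeline).
#' @param phase `"causal"` (single forward pass, -3 dB at cutoff) or
#'   `"zero-phase"` (forward-backward, -6 dB at cutoff, zero group delay).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("lowpass", "highpass"), cutoff, order = 2,
                        phase = c("causal", "zero-phase")) {
  kind <- match.arg(kind); phase <- match.arg(phase)
  stopifnot(cutoff > 0, order >= 1)
  structure(list(kind = kind, cutoff = cutoff, order = order, phase = phase),
            class = "filter_spec")
}

#' Apply a Butterworth filter
#'
#' @param x Signal (uV series).
#' @param fs Sampling rate (Hz).
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_filter <- function(x, fs, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff >= fs / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, fs / 2))
  bf <- signal::butter(spec$order, spec$cutoff / (fs / 2),
                       type = if (spec$kind == "lowpass") "low" else "high")
  if (spec$phase == "causal") as.numeric(signal::filter(bf, x))
  else signal::filtfilt(bf, x)
}

#' Anti-alias cutoff rule
#'
#' The low-pass cutoff used before decimation is `0.3125 * target_fs`,
#' which reproduces the 200 Hz @ 640 Hz and 100 Hz @ 320 Hz pairs used in
#' practice, stays well below the new Nyquist frequency, and generalises to
#' the interim rates (1600 -> 500 Hz, 800 -> 250 Hz, 400 -> 125 Hz).
#'
#' @param target_fs Target sampling rate (Hz).
#' @return Cutoff frequency in Hz.
#' @export
antialias_cutoff <- function(target_fs) 0.3125 * target_fs

#' Downsample a run by an integer factor with trigger quantisation
#'
#' Applies the zero-phase anti-alias low-pass (see [antialias_cutoff()]),
#' keeps every k-th sample, and maps each trial's trigger index by floor
#' division. The floor mapping deliberately reproduces the trigger-onset
#' quantisation jitter of a genuinely low-rate acquisition system: the
#' quantised trigger falls up to `(k-1)/fs` seconds before the true
#' stimulus onset, and the residual sub-sample offset is recorded per trial
#' (`residual_offset_s`).
#'
#' @param run A [sweep_run()].
#' @param target_fs Target rate (Hz); must divide the source rate.
#' @param phase Anti-alias filter phase, `"zero-phase"` by default (the
#'   analysis is retrospective, so zero group delay keeps the response
#'   windows aligned across rates).
#' @return A new [sweep_run()] at `target_fs`.
#' @export
downsample_run <- function(run, target_fs, phase = "zero-phase") {
  stopifnot(inherits(run, "sweep_run"))
  if (target_fs == run$fs) return(run)
  k <- run$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop(sprintf("source rate %g Hz is not an integer multiple of %g Hz",
                 run$fs, target_fs))
  k <- as.integer(round(k))
  if (target_fs < 320)
    warning("target rate below 320 Hz: the H-reflex waveform will be lost")
  spec <- filter_spec("lowpass", antialias_cutoff(target_fs), 2, phase)
  trials <- lapply(run$trials, function(tr) {
    y <- butterworth_filter(tr$samples, run$fs, spec)
    idx0 <- seq(0L, length(y) - 1L, by = k)        # 0-based kept samples
    tr$samples <- y[idx0 + 1L]
    tr$residual_offset_s <- (tr$trigger_index %% k) / run$fs
    tr$trigger_index <- tr$trigger_index %/% k
    tr
  })
  out <- sweep_run(target_fs, trials, run$subject_id, run$truth, run$seed)
  out
}

#' Epoch specification
#'
#' @param t_start,t_end Epoch limits in ms relative to the trigger
#'   (default -200 to +400 ms, a 600 ms epoch).
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(t_start = -200, t_end = 400) {
  stopifnot(t_start < 0, t_end > 0)
  structure(list(t_start = t_start, t_end = t_end), class = "epoch_spec")
}

#' Segment a run into trigger-locked epochs
#'
#' Cuts each trial to `[t_start, t_end)` ms around its (possibly quantised)
#' trigger; the sample at the trigger belongs to the epoch. At 3200 Hz the
#' default spec yields 1920 samples with the trigger at 0-based index 640.
#'
#' @param run A [sweep_run()].
#' @param espec An [epoch_spec()].
#' @return A list of `epoch` objects (fields `samples`, `fs`, `intensity`,
#'   `t0_index` 0-based).
#' @export
epoch_run <- function(run, espec = epoch_spec()) {
  fs <- run$fs
  n_pre <- round(-espec$t_start * fs / 1000)
  n_len <- round((espec$t_end - espec$t_start) * fs / 1000)
  lapply(seq_along(run$trials), function(i) {
    tr <- run$trials[[i]]
    s0 <- tr$trigger_index - n_pre            # 0-based start
    if (s0 < 0 || s0 + n_len > length(tr$samples))
      stop(sprintf("trial %d does not cover the epoch span", i))
    structure(list(samples = tr$samples[(s0 + 1):(s0 + n_len)],
                   fs = fs, intensity = tr$intensity, t0_index = n_pre),
              class = "epoch")
  })
}

# epoch sample times in ms relative to the trigger
epoch_time_ms <- function(epoch) {
  trial_time_ms(length(epoch$samples), epoch$t0_index, epoch$fs)
}

#' Re-anchor an epoch on the stimulus artifact
#'
#' Moves the trigger reference to the sample of maximum absolute amplitude
#' within 0-3 ms after the nominal trigger, compensating trigger-onset
#' quantisation. When no sample in that window exceeds 5x the pre-trigger
#' RMS the epoch is returned unchanged with attribute `aligned = FALSE`.
#'
#' @param epoch An epoch from [epoch_run()].
#' @param search_ms Search window after the nominal trigger (ms).
#' @return The epoch, with `t0_index` possibly shifted and an `aligned`
#'   attribute.
#' @export
align_to_artifact <- function(epoch, search_ms = 3) {
  t <- epoch_time_ms(epoch)
  win <- which(t >= 0 & t < search_ms)
  pre <- epoch$samples[t < 0]
  pre_rms <- if (length(pre)) sqrt(mean(pre^2)) else 0
  if (!length(win) || max(abs(epoch$samples[win])) <= 5 * pre_rms) {
    attr(epoch, "aligned") <- FALSE
    return(epoch)
  }
  epoch$t0_index <- win[which.max(abs(epoch$samples[win]))] - 1L
  attr(epoch, "aligned") <- TRUE
  epoch
}
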