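#' Response measurement windows
#'
#' Fixed post-trigger windows in which the M-wave and H-reflex are
#' quantified. Manual windows come from configuration (defaults match the
#' typical soleus latencies used by the synthetic generator: M 6-23 ms,
#' H 28-45 ms) and are kept constant across all trials; automated windows
#' are produced by [delineate_auto()] from a whole recruitment-curve run.
#'
#' @param m_window,h_window `c(start, end)` in ms post-trigger.
#' @param method `"manual"` or `"automated"`.
#' @return An object of class `response_windows`.
#' @export
response_windows <- function(m_window = c(6, 23), h_window = c(28, 45),
                             method = c("manual", "automated")) {
  method <- match.arg(method)
  stopifnot(length(m_window) == 2, length(h_window) == 2)
  if (diff(m_window) < 3 || diff(h_window) < 3)
    stop("each response window must be at least 3 ms wide")
  if (m_window[2] > h_window[1])
    stop("the M-wave window must precede the H-reflex window")
  if (m_window[1] <= 0 || h_window[2] > 400)
    stop("windows must lie within (0, 400] ms post-trigger")
  structure(list(m_window = m_window, h_window = h_window, method = method),
            class = "response_windows")
}

#' @export
print.response_windows <- function(x, ...) {
  cat(sprintf("Response windows (%s): M %g-%g ms, H %g-%g ms\n", x$method,
              x$m_window[1], x$m_window[2], x$h_window[1], x$h_window[2]))
  invisible(x)
}

#' Mean rectified value within a window
#'
#' The per-trial response measure: the mean of the absolute signal over the
#' samples whose post-trigger time lies in `[window[1], window[2])` ms.
#'
#' @param epoch An epoch from [epoch_run()].
#' @param window `c(start, end)` in ms post-trigger.
#' @return Mean rectified value (uV), non-negative.
#' @export
mean_rectified_value <- function(epoch, window) {
  t <- epoch_time_ms(epoch)
  i <- t >= window[1] & t < window[2]
  if (!any(i))
    stop(sprintf("window %g-%g ms contains no samples at %g Hz",
                 window[1], window[2], epoch$fs))
  mean(abs(epoch$samples[i]))
}

#' Blank the stimulus artifact
#'
#' Replaces the samples in `[0, blank_ms)` ms post-trigger with zero.
#'
#' @param epoch An epoch.
#' @param blank_ms Blanking duration (ms), default 3 ms (the artifact pulse
#'   is 1 ms; the margin absorbs ringing and filter smear).
#' @return The blanked epoch.
#' @export
blank_artifact <- function(epoch, blank_ms = 3) {
  stopifnot(blank_ms > 0)
  t <- epoch_time_ms(epoch)
  epoch$samples[t >= 0 & t < blank_ms] <- 0
  epoch
}

# least-squares fit of a*exp(-t/tau) + c over (t, y); tau bounded (0.1, 50]
fit_decay <- function(t, y) {
  a0 <- max(y[1] - y[length(y)], 1e-3)
  best <- NULL
  for (start in list(list(a = a0, tau = 5, c = y[length(y)]),
                     list(a = a0, tau = 1, c = 0),
                     list(a = max(abs(y)), tau = 15, c = 0))) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c,
                        data = data.frame(t = t, y = y), start = start,
                        lower = c(a = -Inf, tau = 0.1, c = -Inf),
                        upper = c(a = Inf, tau = 50, c = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- c(as.list(stats::coef(fit)), list(ssr = ssr))
  }
  if (is.null(best)) return(NULL)
  best[c("a", "tau", "c")]
}

#' Remove the post-artifact exponential decay
#'
#' Fits `a * exp(-t/tau) + c` to the epoch over `fit_window` (least
#' squares, `tau` bounded within (0.1, 50] ms) and subtracts the decay term
#' `a * exp(-t/tau)` from all samples at `t >= blank_ms`. When the fit does
#' not converge the epoch is returned unchanged and flagged.
#'
#' @param epoch An epoch (normally already blanked).
#' @param fit_window Fit window in ms post-trigger; must start at or after
#'   the blanked region.
#' @param blank_ms Start of the subtraction region (ms).
#' @param decay Optional precomputed decay coefficients (list `a`, `tau`)
#'   to subtract instead of fitting, e.g. pooled across sub-threshold
#'   trials.
#' @return The corrected epoch; attributes `decay` (fitted `a`, `tau`, `c`)
#'   and `decay_removed` (logical flag).
#' @export
remove_decay <- function(epoch, fit_window = c(3, 15), blank_ms = fit_window[1],
                         decay = NULL) {
  t <- epoch_time_ms(epoch)
  if (is.null(decay)) {
    i <- t >= fit_window[1] & t < fit_window[2]
    decay <- if (sum(i) >= 3) fit_decay(t[i], epoch$samples[i])
  }
  if (is.null(decay)) {
    attr(epoch, "decay_removed") <- FALSE
    return(epoch)
  }
  j <- t >= blank_ms
  epoch$samples[j] <- epoch$samples[j] - decay$a * exp(-t[j] / decay$tau)
  attr(epoch, "decay") <- decay
  attr(epoch, "decay_removed") <- TRUE
  epoch
}

# Trials where neither response is present: H-window and late-M-window MRV
# both at most 5% of their run maxima. The H criterion alone would also
# select supra-maximal intensities, where the bell-shaped H-reflex has
# fallen off but the M-wave is maximal. Falls back to the lowest
# intensities when fewer than 4 trials qualify.
subthreshold_idx <- function(epochs, fit_window = c(3, 15),
                             h_window = c(28, 45)) {
  h_mrv <- vapply(epochs, mean_rectified_value, numeric(1), window = h_window)
  m_mrv <- vapply(epochs, mean_rectified_value, numeric(1),
                  window = c(fit_window[2], h_window[1]))
  low <- which(h_mrv <= 0.05 * max(h_mrv) & m_mrv <= 0.05 * max(m_mrv))
  if (length(low) < 4) {
    intens <- vapply(epochs, `[[`, numeric(1), "intensity")
    low <- order(intens)[seq_len(min(4, length(epochs)))]
  }
  low
}

# Blank every epoch, fit one pooled decay on the sub-H-threshold trials
# (H-window MRV at most 5% of the run's maximum, i.e. intensities where
# neither response contaminates the early fit window), and subtract it
# from all epochs. Falls back to per-epoch fits when fewer than 4 such
# trials exist.
prepare_epochs <- function(epochs, blank_ms = 3, fit_window = c(3, 15),
                           h_window = c(28, 45)) {
  epochs <- lapply(epochs, blank_artifact, blank_ms = blank_ms)
  low <- subthreshold_idx(epochs, fit_window, h_window)
  t <- epoch_time_ms(epochs[[low[1]]])
  i <- t >= fit_window[1] & t < fit_window[2]
  decay <- NULL
  if (sum(i) >= 3) {
    tt <- rep(t[i], length(low))
    yy <- unlist(lapply(epochs[low], function(e) e$samples[i]))
    decay <- fit_decay(tt, yy)
  }
  if (is.null(decay)) {
    # pooled fit unavailable: leave the epochs blanked rather than risk
    # per-epoch fits, whose window is contaminated by the M-wave on
    # supra-threshold trials
    return(lapply(epochs, function(e) {
      attr(e, "decay_removed") <- FALSE
      e
    }))
  }
  lapply(epochs, remove_decay, fit_window = fit_window, blank_ms = blank_ms,
         decay = decay)
}

#' Measure a run's recruitment data
#'
#' Runs the per-trial measurement pipeline: epoching (-200..+400 ms),
#' stimulus-artifact blanking, exponential decay removal (pooled over the
#' lowest-intensity trials, see [remove_decay()]), then the mean rectified
#' value in the M and H windows. Trial order is preserved.
#'
#' @param run A [sweep_run()].
#' @param windows A [response_windows()] object.
#' @param blank_ms Artifact blanking duration (ms).
#' @param decay_removal Apply exponential decay removal (default `TRUE`).
#' @param baseline_correct Subtract the rectified noise floor estimated
#'   from the pre-trigger segment (-150..-50 ms, averaged over trials)
#'   from both response columns (default `TRUE`). Rectified means have an
#'   additive floor from background noise; the floor depends on the
#'   sampling rate (the anti-alias filter removes part of the noise band),
#'   so removing it keeps threshold-type parameters comparable across
#'   rates.
#' @return A `recruitment_data` data frame with columns `intensity_mA`,
#'   `mrv_m_uV`, `mrv_h_uV`, one row per trial, and the windows attached as
#'   attribute `windows`.
#' @export
measure_run <- function(run, windows = response_windows(), blank_ms = 3,
                        decay_removal = TRUE, baseline_correct = TRUE) {
  epochs <- epoch_run(run)
  epochs <- if (decay_removal) prepare_epochs(epochs, blank_ms)
            else lapply(epochs, blank_artifact, blank_ms = blank_ms)
  mrv_m <- vapply(epochs, mean_rectified_value, numeric(1),
                  window = windows$m_window)
  mrv_h <- vapply(epochs, mean_rectified_value, numeric(1),
                  window = windows$h_window)
  if (baseline_correct) {
    floor_mrv <- mean(vapply(epochs, mean_rectified_value, numeric(1),
                             window = c(-150, -50)))
    mrv_m <- pmax(mrv_m - floor_mrv, 0)
    mrv_h <- pmax(mrv_h - floor_mrv, 0)
  }
  out <- data.frame(
    intensity_mA = vapply(epochs, `[[`, numeric(1), "intensity"),
    mrv_m_uV = mrv_m, mrv_h_uV = mrv_h)
  attr(out, "windows") <- windows
  class(out) <- c("recruitment_data", "data.frame")
  out
}
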