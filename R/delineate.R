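#' Automated response-window delineation
#'
#' Determines the M-wave and H-reflex measurement windows objectively from
#' a complete recruitment-curve run, so that no investigator judgement is
#' involved. The procedure:
#'
#' 1. epochs every trial, blanks the stimulus artifact and removes the
#'    exponential decay tail (pooled over the lowest-intensity trials);
#' 2. divides 3-60 ms post-trigger into bins of `bin_ms` (default 1 ms;
#'    when a bin would hold less than one sample, e.g. at 320 Hz, bins
#'    widen to exactly one sample);
#' 3. computes the rectified-mean amplitude per bin per trial and fits,
#'    across stimulation intensity, both a logistic and a hill model to
#'    each bin's amplitudes;
#' 4. labels a bin `M` when the logistic fit has the lower residual MSE and
#'    `H` when the hill fit does, but only when the better fit reduces the
#'    MSE by at least `label_threshold` (default 20%) relative to a
#'    constant fit — otherwise the bin stays unlabeled;
#' 5. takes the longest contiguous `M` run as the M window and the longest
#'    contiguous `H` run after it as the H window.
#'
#' The criteria in steps 2-5 are this package's reconstruction of the
#' whole-run delineation idea (exposed as configuration), not a published
#' reference algorithm. The returned windows are then kept constant for
#' the entire run.
#'
#' @param run A [sweep_run()] spanning sub-threshold to supra-maximal
#'   intensities.
#' @param span_ms Search region post-trigger (ms).
#' @param bin_ms Nominal bin width (ms).
#' @param label_threshold Minimum relative MSE reduction vs a constant fit
#'   for a bin to be labeled.
#' @param blank_ms Artifact blanking passed to the preprocessing step.
#' @return A [response_windows()] object with `method = "automated"`.
#' @export
delineate_auto <- function(run, span_ms = c(3, 60), bin_ms = 1,
                           label_threshold = 0.20, blank_ms = 3) {
  epochs <- prepare_epochs(epoch_run(run), blank_ms)
  fs <- run$fs
  w <- max(bin_ms, 1000 / fs)          # >= one sample per bin
  edges <- seq(span_ms[1], span_ms[2], by = w)
  if (length(edges) < 3) stop("search region holds too few bins")
  intens <- vapply(epochs, `[[`, numeric(1), "intensity")
  t <- epoch_time_ms(epochs[[1]])
  nb <- length(edges) - 1
  labels <- character(nb)
  margins <- numeric(nb)
  amps <- lapply(seq_len(nb), function(b) {
    i <- t >= edges[b] & t < edges[b + 1]
    if (!any(i)) return(NULL)
    vapply(epochs, function(e) mean(abs(e$samples[i])), numeric(1))
  })
  peak_amp <- max(vapply(amps, function(a) if (is.null(a)) 0 else max(a),
                         numeric(1)))
  for (b in seq_len(nb)) {
    amp <- amps[[b]]
    # bins with negligible response energy stay unlabeled
    if (is.null(amp) || max(amp) < 0.05 * peak_amp) {
      labels[b] <- "none"; next
    }
    mse_const <- mean((amp - mean(amp))^2)
    lf <- fit_logistic(intens, amp)
    hf <- fit_hill(intens, amp)
    mse_l <- if (is.null(lf)) Inf else lf$ssr / length(amp)
    mse_h <- if (is.null(hf)) Inf else hf$ssr / length(amp)
    best <- min(mse_l, mse_h)
    if (!is.finite(best) || best > (1 - label_threshold) * mse_const) {
      labels[b] <- "none"
    } else if (mse_l <= mse_h) {
      labels[b] <- "M"
      margins[b] <- (mse_const - best) / mse_const
    } else {
      # a winning hill only indicates an H-reflex when its fitted curve
      # genuinely falls off within the sampled range; a hill whose value
      # at the top intensity is still near its peak is effectively
      # monotone, i.e. M-wave-like
      g <- seq(min(intens), max(intens), by = 0.1)
      hg <- do.call(hill_curve, c(list(s = g), hf[c(
        "h_scale", "h_rise_center", "h_rise_slope", "h_fall_center",
        "h_fall_slope")]))
      labels[b] <- if (hg[length(hg)] < 0.75 * max(hg)) "H" else "M"
      margins[b] <- (mse_const - best) / mse_const
    }
  }
  m_run <- longest_run(labels == "M")
  if (is.null(m_run)) stop("M-wave not delineated")
  h_run <- longest_run(labels == "H" & seq_len(nb) > m_run[2])
  if (is.null(h_run)) stop("H-reflex not delineated")
  response_windows(m_window = c(edges[m_run[1]], edges[m_run[2] + 1]),
                   h_window = c(edges[h_run[1]], edges[h_run[2] + 1]),
                   method = "automated")
}

# first/last index of the longest TRUE run, or NULL
longest_run <- function(flag) {
  r <- rle(flag)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)[which.max(r$lengths[r$values])]
  c(starts[i], ends[i])
}
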