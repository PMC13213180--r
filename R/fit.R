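#' Recruitment-curve models
#'
#' The M-wave recruitment curve is a logistic in stimulation intensity;
#' the H-reflex recruitment curve is the "hill" curve, the product of a
#' rising and a falling sigmoid.
#'
#' @param s Stimulation intensity (mA).
#' @param m_max,m_center,m_slope Logistic parameters.
#' @return Model amplitude (uV).
#' @keywords internal
logistic_curve <- function(s, m_max, m_center, m_slope) {
  m_max * stats::plogis(m_slope * (s - m_center))
}

#' @rdname logistic_curve
#' @param h_scale,h_rise_center,h_rise_slope,h_fall_center,h_fall_slope
#'   Hill-curve parameters.
#' @keywords internal
hill_curve <- function(s, h_scale, h_rise_center, h_rise_slope,
                       h_fall_center, h_fall_slope) {
  h_scale * stats::plogis(h_rise_slope * (s - h_rise_center)) *
    stats::plogis(-h_fall_slope * (s - h_fall_center))
}

# per-intensity means, lightly smoothed, used only to build starting values
step_means <- function(x, y) {
  xs <- sort(unique(x))
  ys <- vapply(split(y, match(x, xs)), mean, numeric(1))
  if (length(ys) >= 3)
    ys <- stats::filter(ys, c(0.25, 0.5, 0.25), sides = 2) |>
      as.numeric() |> (\(v) ifelse(is.na(v), ys, v))()
  list(x = xs, y = ys)
}

# multi-start bounded Levenberg-Marquardt helper; returns best converged
# fit (list of coefficients + ssr) or NULL
best_nls <- function(formula, data, starts, lower, upper, valid = NULL) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- as.list(stats::coef(fit))
    if (!is.null(valid) && !valid(cf)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- c(cf, list(ssr = ssr))
  }
  best
}

# deterministic multi-start logistic fit; NULL when nothing converges
fit_logistic <- function(x, y) {
  sm <- step_means(x, y)
  a0 <- max(sm$y); r <- diff(range(x))
  c0 <- sm$x[which(sm$y >= a0 / 2)[1]]
  starts <- lapply(c(0.15, 0.3, 0.6, 1.2, 2.4),
                   function(b) list(m_max = a0, m_center = c0, m_slope = b))
  best_nls(y ~ m_max * 1 / (1 + exp(-m_slope * (s - m_center))),
           data.frame(s = x, y = y), starts,
           lower = c(m_max = 1e-9, m_center = min(x) - 0.5 * r,
                     m_slope = 0.01),
           upper = c(m_max = 3 * max(y), m_center = max(x) + 0.5 * r,
                     m_slope = 10))
}

# deterministic multi-start hill fit; enforces rise center < fall center
# and a maximum strictly inside the sampled intensity range (a hill whose
# peak sits at the range edge is a degenerate rising- or falling-only fit)
fit_hill <- function(x, y) {
  sm <- step_means(x, y)
  a0 <- max(sm$y); r <- diff(range(x))
  x0 <- sm$x[which.max(sm$y)]
  step <- stats::median(diff(sm$x))
  interior_max <- function(cf) {
    g <- seq(min(x) - step, max(x) + step, by = 0.1)
    i <- which.max(do.call(hill_curve, c(list(s = g), cf[c(
      "h_scale", "h_rise_center", "h_rise_slope", "h_fall_center",
      "h_fall_slope")])))
    i > 1 && i < length(g)
  }
  above <- sm$x[sm$y >= a0 / 2]
  c1 <- min(above); c2 <- max(above)
  if (c2 - c1 < 1) { c1 <- x0 - 2; c2 <- x0 + 2 }
  starts <- list(
    list(h_scale = a0, h_rise_center = c1, h_rise_slope = 0.8,
         h_fall_center = c2, h_fall_slope = 0.5),
    list(h_scale = 1.5 * a0, h_rise_center = c1, h_rise_slope = 0.4,
         h_fall_center = c2, h_fall_slope = 0.3),
    list(h_scale = a0, h_rise_center = x0 - 3, h_rise_slope = 1.5,
         h_fall_center = x0 + 3, h_fall_slope = 1.0),
    list(h_scale = 2 * a0, h_rise_center = c1 - 2, h_rise_slope = 0.6,
         h_fall_center = c2 + 2, h_fall_slope = 0.4),
    list(h_scale = a0, h_rise_center = x0 - 6, h_rise_slope = 0.3,
         h_fall_center = x0 + 6, h_fall_slope = 0.8),
    list(h_scale = a0, h_rise_center = x0 - 1.5, h_rise_slope = 2,
         h_fall_center = x0 + 1.5, h_fall_slope = 1.5),
    list(h_scale = 3 * a0, h_rise_center = c1, h_rise_slope = 0.6,
         h_fall_center = c2, h_fall_slope = 0.15))
  fit <- best_nls(
    y ~ h_scale * (1 / (1 + exp(-h_rise_slope * (s - h_rise_center)))) *
      (1 / (1 + exp(h_fall_slope * (s - h_fall_center)))),
    data.frame(s = x, y = y), starts,
    lower = c(h_scale = 1e-9, h_rise_center = min(x) - 0.5 * r,
              h_rise_slope = 0.01, h_fall_center = min(x) - 0.5 * r,
              h_fall_slope = 0.01),
    upper = c(h_scale = 20 * max(y), h_rise_center = max(x) + 0.5 * r,
              h_rise_slope = 10, h_fall_center = max(x) + 0.5 * r,
              h_fall_slope = 10),
    valid = function(cf) cf$h_rise_center < cf$h_fall_center &&
      interior_max(cf))
  if (!is.null(fit)) return(fit)
  # fallback: rise/fall order enforced structurally via a positive gap
  gap_starts <- lapply(c(0.5, 2, 5), function(g)
    list(h_scale = a0, h_rise_center = min(c1, x0 - g / 2), gap = g,
         h_rise_slope = 0.8, h_fall_slope = 0.5))
  fit <- best_nls(
    y ~ h_scale * (1 / (1 + exp(-h_rise_slope * (s - h_rise_center)))) *
      (1 / (1 + exp(h_fall_slope * (s - (h_rise_center + gap))))),
    data.frame(s = x, y = y), gap_starts,
    lower = c(h_scale = 1e-9, h_rise_center = min(x) - 0.5 * r, gap = 0.1,
              h_rise_slope = 0.01, h_fall_slope = 0.01),
    upper = c(h_scale = 20 * max(y), h_rise_center = max(x) + 0.5 * r,
              gap = 2 * r, h_rise_slope = 10, h_fall_slope = 10))
  if (is.null(fit)) return(NULL)
  fit$h_fall_center <- fit$h_rise_center + fit$gap
  fit <- fit[c("h_scale", "h_rise_center", "h_rise_slope", "h_fall_center",
               "h_fall_slope", "ssr")]
  if (!interior_max(fit)) return(NULL)
  fit
}

#' Fit recruitment curves to measured data
#'
#' Nonlinear least squares of the logistic model to the per-trial
#' `(intensity, mrv_m)` points and of the hill model (product of two
#' sigmoids) to `(intensity, mrv_h)`. Each fit uses five deterministic
#' starting points derived from per-intensity means, bounded slopes
#' ((0.01, 10] /mA) and centers (data range +/- 50%), keeping the solution
#' with the smallest residual sum of squares; the result is deterministic
#' given the data.
#'
#' @param data A `recruitment_data` frame from [measure_run()] (columns
#'   `intensity_mA`, `mrv_m_uV`, `mrv_h_uV`).
#' @return An object of class `fitted_curves`: `m_params`, `h_params`,
#'   `converged` flags, `n_points`, and the intensity range.
#' @export
fit_recruitment <- function(data) {
  x <- data$intensity_mA
  if (length(unique(x)) < 8)
    stop("at least 8 distinct stimulation intensities are required")
  for (col in c("mrv_m_uV", "mrv_h_uV"))
    if (all(data[[col]] == 0))
      stop(sprintf("degenerate (all-zero) response column: %s", col))
  mf <- fit_logistic(x, data$mrv_m_uV)
  hf <- fit_hill(x, data$mrv_h_uV)
  if (is.null(mf) && is.null(hf))
    stop("no start converged for either recruitment curve")
  structure(list(
    m_params = if (!is.null(mf))
      list(m_max = mf$m_max, m_center = mf$m_center, m_slope = mf$m_slope),
    h_params = if (!is.null(hf))
      list(h_scale = hf$h_scale, h_rise_center = hf$h_rise_center,
           h_rise_slope = hf$h_rise_slope, h_fall_center = hf$h_fall_center,
           h_fall_slope = hf$h_fall_slope),
    converged = c(m = !is.null(mf), h = !is.null(hf)),
    n_points = length(x),
    intensity_range = range(x),
    step = stats::median(diff(sort(unique(x))))),
    class = "fitted_curves")
}

#' @export
print.fitted_curves <- function(x, ...) {
  cat("Fitted recruitment curves\n")
  if (x$converged["m"])
    cat(sprintf("  M: m_max %.1f uV, center %.2f mA, slope %.3f /mA\n",
                x$m_params$m_max, x$m_params$m_center, x$m_params$m_slope))
  if (x$converged["h"])
    cat(sprintf("  H: scale %.1f uV, rise %.2f mA (%.3f), fall %.2f mA (%.3f)\n",
                x$h_params$h_scale, x$h_params$h_rise_center,
                x$h_params$h_rise_slope, x$h_params$h_fall_center,
                x$h_params$h_fall_slope))
  invisible(x)
}

#' Evaluate fitted recruitment curves
#'
#' @param curves A [fit_recruitment()] result.
#' @param s Intensities (mA).
#' @return Fitted amplitudes (uV).
#' @export
predict_m <- function(curves, s) {
  do.call(logistic_curve, c(list(s = s), curves$m_params))
}

#' @rdname predict_m
#' @export
predict_h <- function(curves, s) {
  do.call(hill_curve, c(list(s = s), curves$h_params))
}

# 0.01 mA evaluation grid over the data range extended by one ramp step
params_grid <- function(curves, grid_res = 0.01) {
  seq(max(0, curves$intensity_range[1] - curves$step),
      curves$intensity_range[2] + curves$step, by = grid_res)
}

#' Extract the six recruitment-curve parameters
#'
#' Computes, from fitted curves and the measured data: the residual errors
#' (mean squared error) of the H and M fits, the fitted maxima `h_max` and
#' `m_max`, and the stimulation intensities at `h_max` and at the M-wave
#' threshold. The hill maximum is found by 0.01 mA grid search over the
#' data's intensity range extended by one ramp step. The M-wave threshold
#' is operationalised as the smallest grid intensity where the fitted
#' M-wave reaches `mthreshold_frac` (default 5%) of `m_max`; this fraction
#' is a configurable operational definition and is reported in the result.
#'
#' MSEs are computed on dimensionless residuals: data and fit are divided
#' by the fitted maximum of that response, which makes MSEs comparable
#' across subjects; raw uV^2 MSEs are also reported.
#'
#' @param curves A [fit_recruitment()] result (both curves converged).
#' @param data The `recruitment_data` the curves were fitted to.
#' @param mthreshold_frac M-threshold fraction of `m_max`.
#' @param grid_res Grid resolution (mA).
#' @return An object of class `curve_params` with fields `mse_h`, `mse_m`
#'   (normalised), `mse_h_raw`, `mse_m_raw` (uV^2), `h_max`, `m_max` (uV),
#'   `stim_at_hmax`, `stim_at_mthreshold`, `target_intensity` (mA), and
#'   `flags`.
#' @export
extract_params <- function(curves, data, mthreshold_frac = 0.05,
                           grid_res = 0.01) {
  if (!all(curves$converged))
    return(structure(list(flags = "fit not converged"),
                     class = "curve_params"))
  g <- params_grid(curves, grid_res)
  hg <- predict_h(curves, g)
  mg <- predict_m(curves, g)
  h_max <- max(hg)
  stim_at_hmax <- g[which.max(hg)]
  m_max <- curves$m_params$m_max
  i_thr <- which(mg >= mthreshold_frac * m_max)[1]
  stim_at_mthreshold <- if (is.na(i_thr)) NA_real_ else g[i_thr]

  x <- data$intensity_mA
  res_h <- data$mrv_h_uV - predict_h(curves, x)
  res_m <- data$mrv_m_uV - predict_m(curves, x)
  flags <- character(0)
  if (is.na(stim_at_mthreshold))
    flags <- c(flags, "M-threshold crossing outside measured range")

  tgt <- tryCatch(target_intensity(curves, grid_res = grid_res),
                  error = function(e) {
                    flags <<- c(flags, conditionMessage(e))
                    list(target_intensity = NA_real_, flags = character(0))
                  })
  structure(list(
    mse_h = mean((res_h / h_max)^2), mse_m = mean((res_m / m_max)^2),
    mse_h_raw = mean(res_h^2), mse_m_raw = mean(res_m^2),
    h_max = h_max, m_max = m_max,
    stim_at_hmax = stim_at_hmax, stim_at_mthreshold = stim_at_mthreshold,
    target_intensity = tgt$target_intensity,
    mthreshold_frac = mthreshold_frac,
    flags = c(flags, tgt$flags)),
    class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat("Recruitment-curve parameters\n")
  cat(sprintf("  H: max %.1f uV at %.2f mA (MSE %.4g)\n",
              x$h_max, x$stim_at_hmax, x$mse_h))
  cat(sprintf("  M: max %.1f uV, threshold (%.0f%%) at %.2f mA (MSE %.4g)\n",
              x$m_max, 100 * x$mthreshold_frac, x$stim_at_mthreshold, x$mse_m))
  cat(sprintf("  target intensity: %.2f mA%s\n", x$target_intensity,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = "; "),
                                          "]") else ""))
  invisible(x)
}

#' Target stimulation intensity
#'
#' The stimulation intensity used to standardise effective afferent
#' excitation: the smallest intensity (0.01 mA grid) at which the fitted
#' M-wave reaches 10% of `m_max`. At a well-behaved recruitment curve the
#' H-reflex is near-maximal there; when the fitted H-reflex at the target
#' is below 75% of `h_max` the advisory flag `"H-criterion unmet"` is
#' attached.
#'
#' @param curves A [fit_recruitment()] result (both curves converged).
#' @param m_frac M-wave fraction defining the target (default 0.10).
#' @param h_frac H-reflex fraction for the advisory check (default 0.75).
#' @param grid_res Grid resolution (mA).
#' @return List with `target_intensity` (mA) and `flags` (character).
#' @export
target_intensity <- function(curves, m_frac = 0.10, h_frac = 0.75,
                             grid_res = 0.01) {
  if (!all(curves$converged)) stop("both curves must have converged")
  g <- params_grid(curves, grid_res)
  mg <- predict_m(curves, g)
  i <- which(mg >= m_frac * curves$m_params$m_max)[1]
  if (is.na(i))
    stop(sprintf("%.0f%% M-wave crossing lies outside the measured range",
                 100 * m_frac))
  s_star <- g[i]
  hg <- predict_h(curves, g)
  flags <- if (predict_h(curves, s_star) < h_frac * max(hg))
    "H-criterion unmet" else character(0)
  list(target_intensity = s_star, flags = flags)
}
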