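#' Ground-truth recruitment functions
#'
#' A `recruitment_truth` object holds the data-generating recruitment model
#' of one simulated subject: the M-wave follows a logistic (sigmoid) function
#' of stimulation intensity saturating at `m_max`, and the H-reflex follows a
#' bell-shaped "hill" curve, the product of a rising and a falling sigmoid.
#'
#' @param h_scale Amplitude scale of the H-reflex hill curve (uV, MRV units).
#' @param h_rise_center Intensity at which the rising sigmoid is at its
#'   midpoint (mA).
#' @param h_rise_slope Slope of the rising sigmoid (1/mA).
#' @param h_fall_center Intensity at which the falling sigmoid is at its
#'   midpoint (mA); must exceed `h_rise_center` so that the curve is
#'   bell-shaped.
#' @param h_fall_slope Slope of the falling sigmoid (1/mA).
#' @param m_max Asymptotic M-wave amplitude (uV, MRV units).
#' @param m_center Intensity at the M-wave sigmoid midpoint (mA).
#' @param m_slope Slope of the M-wave sigmoid (1/mA).
#'
#' @return An object of class `recruitment_truth`.
#' @seealso [true_m_amplitude()], [true_h_amplitude()], [draw_truth()]
#' @export
#' @examples
#' tr <- recruitment_truth()
#' true_m_amplitude(tr$m_center, tr)  # half of m_max
recruitment_truth <- function(h_scale = 200, h_rise_center = 15,
                              h_rise_slope = 0.8, h_fall_center = 24,
                              h_fall_slope = 0.55, m_max = 500,
                              m_center = 24, m_slope = 0.5) {
  truth <- list(h_scale = h_scale, h_rise_center = h_rise_center,
                h_rise_slope = h_rise_slope, h_fall_center = h_fall_center,
                h_fall_slope = h_fall_slope, m_max = m_max,
                m_center = m_center, m_slope = m_slope)
  amps <- c(h_scale = h_scale, m_max = m_max)
  slopes <- c(h_rise_slope = h_rise_slope, h_fall_slope = h_fall_slope,
              m_slope = m_slope)
  if (any(amps <= 0)) stop("all amplitudes must be > 0")
  if (any(slopes <= 0)) stop("all slopes must be > 0")
  if (h_rise_center >= h_fall_center)
    stop("h_rise_center must be < h_fall_center (bell-shaped H curve)")
  class(truth) <- "recruitment_truth"
  truth
}

#' @export
print.recruitment_truth <- function(x, ...) {
  cat("Ground-truth recruitment functions\n")
  cat(sprintf("  M-wave : logistic, m_max = %.1f uV, center = %.1f mA, slope = %.2f /mA\n",
              x$m_max, x$m_center, x$m_slope))
  cat(sprintf("  H-reflex: hill, scale = %.1f uV, rise %.1f mA (%.2f /mA), fall %.1f mA (%.2f /mA)\n",
              x$h_scale, x$h_rise_center, x$h_rise_slope,
              x$h_fall_center, x$h_fall_slope))
  invisible(x)
}

#' True M-wave amplitude at a stimulation intensity
#'
#' Evaluates the ground-truth M-wave recruitment function, a logistic in
#' stimulation intensity: `m_max / (1 + exp(-m_slope * (s - m_center)))`.
#'
#' @param s Stimulation intensity (mA); non-negative, vectorised.
#' @param truth A [recruitment_truth()] object.
#' @return M-wave amplitude(s) in uV (MRV units).
#' @export
true_m_amplitude <- function(s, truth) {
  stopifnot(inherits(truth, "recruitment_truth"))
  if (any(s < 0)) stop("stimulation intensity must be non-negative")
  truth$m_max * stats::plogis(truth$m_slope * (s - truth$m_center))
}

#' True H-reflex amplitude at a stimulation intensity
#'
#' Evaluates the ground-truth H-reflex recruitment function, a "hill" curve:
#' the product of a rising and a falling standard logistic,
#' `h_scale * sigma(h_rise_slope*(s - h_rise_center)) *
#'  sigma(-h_fall_slope*(s - h_fall_center))`.
#'
#' @inheritParams true_m_amplitude
#' @return H-reflex amplitude(s) in uV (MRV units).
#' @export
true_h_amplitude <- function(s, truth) {
  stopifnot(inherits(truth, "recruitment_truth"))
  if (any(s < 0)) stop("stimulation intensity must be non-negative")
  truth$h_scale *
    stats::plogis(truth$h_rise_slope * (s - truth$h_rise_center)) *
    stats::plogis(-truth$h_fall_slope * (s - truth$h_fall_center))
}

#' Draw heterogeneous subject truths for a simulated cohort
#'
#' Subject-to-subject variability is modelled by drawing each ground-truth
#' parameter uniformly from a physiologically plausible range (soleus
#' H-reflex/M-wave recruitment during tibial-nerve stimulation). The ranges
#' guarantee `h_rise_center < h_fall_center` by construction.
#'
#' @param seed Integer seed for the draw (local to this call; the global RNG
#'   state is restored on exit).
#' @param ranges Named list of `c(lo, hi)` ranges overriding the defaults.
#' @return A [recruitment_truth()] object.
#' @export
draw_truth <- function(seed, ranges = list()) {
  defaults <- list(
    h_scale = c(120, 300), h_rise_center = c(12, 17),
    h_rise_slope = c(0.5, 1.1), h_fall_center = c(20, 27),
    h_fall_slope = c(0.35, 0.8), m_max = c(350, 700),
    m_center = c(20, 28), m_slope = c(0.35, 0.8))
  defaults[names(ranges)] <- ranges
  pars <- with_local_seed(seed, {
    lapply(defaults, function(r) stats::runif(1, r[1], r[2]))
  })
  do.call(recruitment_truth, pars)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
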