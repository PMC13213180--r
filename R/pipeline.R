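#' Pseudo-online experiment configuration
#'
#' Describes a full multi-rate experiment: a synthetic cohort is generated
#' at the 3200 Hz reference rate, degraded to each lower rate by
#' anti-aliased decimation, delineated with the requested method(s),
#' fitted, and the curve parameters compared across rates.
#'
#' @param n_subjects Cohort size (default 21).
#' @param rates Sampling rates (Hz); must contain the 3200 Hz reference
#'   and each rate must divide 3200.
#' @param methods Delineation methods, subset of `c("manual", "automated")`.
#' @param master_seed Master seed; per-subject seeds are derived from it.
#' @param protocol,wspec Generator settings ([sweep_protocol()],
#'   [waveform_spec()]).
#' @param truth_ranges Cohort heterogeneity ranges (see [draw_truth()]).
#' @param manual_windows Fixed windows used by the manual method.
#' @param output_dir Optional directory for intermediate artifacts
#'   (runs, recruitment data, parameter table, stats report, manifest).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 21,
                              rates = c(3200, 1600, 800, 640, 400, 320),
                              methods = c("manual", "automated"),
                              master_seed = 1L,
                              protocol = sweep_protocol(),
                              wspec = waveform_spec(),
                              truth_ranges = list(),
                              manual_windows = response_windows(),
                              output_dir = NULL) {
  if (!3200 %in% rates) stop("the 3200 Hz reference rate is required")
  if (any(3200 %% rates != 0))
    stop("every rate must be an integer divisor of 3200 Hz")
  if (n_subjects < 3) stop("at least 3 subjects are required")
  methods <- match.arg(methods, c("manual", "automated"), several.ok = TRUE)
  structure(list(n_subjects = n_subjects, rates = sort(rates, TRUE),
                 methods = methods, master_seed = master_seed,
                 protocol = protocol, wspec = wspec,
                 truth_ranges = truth_ranges,
                 manual_windows = manual_windows, output_dir = output_dir),
            class = "experiment_config")
}

#' Analyse one run at one rate with one delineation method
#'
#' Convenience wrapper: delineate (or take the fixed manual windows),
#' measure, fit, extract.
#'
#' @param run A [sweep_run()] (already at its analysis rate).
#' @param method `"manual"` or `"automated"`.
#' @param manual_windows Windows used when `method = "manual"`.
#' @return A [extract_params()] result.
#' @export
analyse_run <- function(run, method = "manual",
                        manual_windows = response_windows()) {
  windows <- if (method == "manual") manual_windows else delineate_auto(run)
  data <- measure_run(run, windows)
  curves <- fit_recruitment(data)
  extract_params(curves, data)
}

param_names <- c("mse_h", "mse_m", "h_max", "m_max",
                 "stim_at_hmax", "stim_at_mthreshold")

#' Run the full pseudo-online experiment
#'
#' Generates the cohort, degrades every run to each configured rate,
#' applies each delineation method, fits the recruitment curves, extracts
#' the curve parameters and computes the cross-rate statistics. The whole
#' experiment is deterministic given `cfg$master_seed`. Per-subject stage
#' failures (e.g. delineation failures at low rates) do not abort the
#' experiment; the gaps are recorded in the returned table and in
#' `$gaps`.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-stage progress.
#' @return A list of class `rate_comparison`: `params` (one row per
#'   subject x rate x method with the six curve parameters and the target
#'   intensity), `stats` (per-method cross-rate battery from
#'   [agreement_battery()]), `icc_manual_vs_auto` (when both methods are
#'   configured), `gaps`, and `config`. With `cfg$output_dir` set, the
#'   parameter table, stats and a provenance manifest are written as
#'   CSV/JSON.
#' @export
run_experiment <- function(cfg = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list(); gaps <- list()
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  for (i in seq_len(cfg$n_subjects)) {
    truth <- draw_truth(derive_seed(cfg$master_seed, 1000L + i),
                        cfg$truth_ranges)
    run0 <- generate_run(truth, cfg$protocol, cfg$wspec, subject_id = ids[i],
                         seed = derive_seed(cfg$master_seed, i))
    if (!is.null(cfg$output_dir))
      write_run(run0, file.path(cfg$output_dir, "runs"))
    for (rate in cfg$rates) {
      run <- downsample_run(run0, rate)
      for (method in cfg$methods) {
        if (verbose)
          message(sprintf("%s @ %d Hz [%s]", ids[i], rate, method))
        cp <- tryCatch(analyse_run(run, method, cfg$manual_windows),
                       error = function(e) e)
        if (inherits(cp, "error") || is.null(cp$mse_h)) {
          gaps[[length(gaps) + 1]] <- data.frame(
            subject = ids[i], rate = rate, method = method,
            error = if (inherits(cp, "error")) conditionMessage(cp)
                    else "fit not converged")
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          subject = ids[i], rate = rate, method = method,
          mse_h = cp$mse_h, mse_m = cp$mse_m,
          h_max = cp$h_max, m_max = cp$m_max,
          stim_at_hmax = cp$stim_at_hmax,
          stim_at_mthreshold = cp$stim_at_mthreshold,
          target_intensity = cp$target_intensity,
          mthreshold_frac = cp$mthreshold_frac,
          flags = paste(cp$flags, collapse = "; "),
          true_stim_at_hmax = if (!is.null(run0$truth))
            true_hmax_intensity(run0$truth) else NA_real_)
      }
    }
  }
  params <- do.call(rbind, rows)
  gaps <- if (length(gaps)) do.call(rbind, gaps) else NULL
  stats <- lapply(stats::setNames(cfg$methods, cfg$methods), function(m)
    agreement_battery(params[params$method == m, ], conditions = cfg$rates))
  icc_mv <- if (all(c("manual", "automated") %in% cfg$methods))
    icc_manual_vs_auto(params, cfg$rates)
  out <- list(params = params, stats = stats,
              icc_manual_vs_auto = icc_mv, gaps = gaps, config = cfg)
  class(out) <- "rate_comparison"
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(params, file.path(cfg$output_dir, "curve_params.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(master_seed = cfg$master_seed, n_subjects = cfg$n_subjects,
           rates = cfg$rates, methods = cfg$methods,
           package_version = as.character(utils::packageVersion("recruitcurve")),
           stats = stats_report_frame(out)),
      file.path(cfg$output_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

# ground-truth intensity of the H-reflex maximum (0.001 mA scan)
true_hmax_intensity <- function(truth, lo = 0, hi = 50, res = 0.001) {
  g <- seq(lo, hi, by = res)
  g[which.max(true_h_amplitude(g, truth))]
}

#' Cross-condition statistical battery for one parameter table
#'
#' For each curve parameter, runs the Friedman test across the given
#' conditions (with Kendall's w and Tukey post-hoc on ranks), and for the
#' two stimulation-intensity parameters additionally the TOST equivalence
#' test (reference rate vs the next-lower configured rate) and
#' Bland-Altman limits. Subjects missing any condition are dropped
#' listwise (the dropped count is reported).
#'
#' @param params Long parameter table (columns `subject`, `rate`, and the
#'   six parameters) for a single delineation method.
#' @param conditions Rates to compare.
#' @param tost_bounds Equivalence bounds (mA).
#' @param tost_pair The two rates compared by TOST (defaults to the
#'   reference rate and the closest configured lower rate).
#' @return A list of class `stats_report`, one entry per parameter.
#' @export
agreement_battery <- function(params, conditions = unique(params$rate),
                              tost_bounds = 1.0, tost_pair = NULL) {
  conditions <- sort(conditions, decreasing = TRUE)
  if (is.null(tost_pair))
    tost_pair <- conditions[seq_len(min(2, length(conditions)))]
  out <- list(dropped = 0)
  wide_of <- function(par) {
    w <- stats::reshape(params[params$rate %in% conditions,
                               c("subject", "rate", par)],
                        idvar = "subject", timevar = "rate",
                        direction = "wide")
    m <- as.matrix(w[, -1, drop = FALSE])
    colnames(m) <- sub(paste0(par, "."), "", colnames(m))
    m[, order(as.numeric(colnames(m)), decreasing = TRUE), drop = FALSE]
  }
  for (par in param_names) {
    m <- wide_of(par)
    keep <- stats::complete.cases(m)
    out$dropped <- max(out$dropped, sum(!keep))
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 2) { out[[par]] <- list(note = "too few complete subjects"); next }
    entry <- list(friedman = friedman_rm(m), posthoc = tukey_posthoc(m))
    if (par %in% c("stim_at_hmax", "stim_at_mthreshold") &&
        all(as.character(tost_pair) %in% colnames(m)) && nrow(m) >= 3) {
      d <- m[, as.character(tost_pair[1])] - m[, as.character(tost_pair[2])]
      entry$tost <- tost_equivalence(d, tost_bounds)
      entry$bland_altman <- bland_altman(m[, as.character(tost_pair[1])],
                                         m[, as.character(tost_pair[2])])
    }
    out[[par]] <- entry
  }
  class(out) <- "stats_report"
  out
}

# manual-vs-automated agreement (ICC + Bland-Altman) per parameter per rate
icc_manual_vs_auto <- function(params, rates) {
  rows <- list()
  for (par in param_names) for (rate in rates) {
    a <- params[params$rate == rate & params$method == "manual",
                c("subject", par)]
    b <- params[params$rate == rate & params$method == "automated",
                c("subject", par)]
    mrg <- merge(a, b, by = "subject")
    mrg <- mrg[stats::complete.cases(mrg), ]
    if (nrow(mrg) < 3) next
    icc <- icc_absolute_single(as.matrix(mrg[, -1]))
    ba <- bland_altman(mrg[, 2], mrg[, 3])
    rows[[length(rows) + 1]] <- data.frame(
      parameter = par, rate = rate, n = nrow(mrg), icc = icc$icc,
      icc_label = icc$icc_label, bias = ba$bias,
      loa_low = ba$loa[1], loa_high = ba$loa[2])
  }
  do.call(rbind, rows)
}

# flatten a rate_comparison's stats into one data frame
stats_report_frame <- function(rc) {
  rows <- list()
  for (method in names(rc$stats)) {
    sr <- rc$stats[[method]]
    for (par in param_names) {
      fr <- sr[[par]]$friedman
      if (is.null(fr)) next
      rows[[length(rows) + 1]] <- data.frame(
        method = method, parameter = par, test = "friedman",
        statistic = fr$chi2, p = fr$p, effect_size = fr$w,
        ci_low = NA_real_, ci_high = NA_real_)
      if (!is.null(sr[[par]]$tost)) {
        ts <- sr[[par]]$tost
        rows[[length(rows) + 1]] <- data.frame(
          method = method, parameter = par, test = "tost",
          statistic = ts$mean_diff, p = NA_real_,
          effect_size = as.numeric(ts$equivalent),
          ci_low = ts$ci90[1], ci_high = ts$ci90[2])
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf("Pseudo-online rate comparison: %d subjects, rates %s, methods %s\n",
              x$config$n_subjects,
              paste(x$config$rates, collapse = "/"),
              paste(x$config$methods, collapse = "+")))
  cat(sprintf("  parameter rows: %d%s\n", nrow(x$params),
              if (!is.null(x$gaps)) sprintf(" (%d gaps)", nrow(x$gaps)) else ""))
  invisible(x)
}

#' Summarise a rate comparison
#'
#' Produces the human-readable outputs of the experiment: per-parameter
#' mean and standard error across subjects at each rate, the flattened
#' test table, the manual-vs-automated ICC table, and (optionally)
#' per-subject recruitment-curve plots.
#'
#' @param rc A [run_experiment()] result.
#' @param plot_dir Optional directory for per-subject recruitment-curve
#'   PNG plots (requires re-measuring; omitted when `NULL`).
#' @return A list with `descriptives`, `tests`, `icc_manual_vs_auto`,
#'   `gaps`.
#' @export
report <- function(rc, plot_dir = NULL) {
  stopifnot(inherits(rc, "rate_comparison"))
  p <- rc$params
  desc <- do.call(rbind, lapply(split(p, list(p$method, p$rate), drop = TRUE),
    function(g) {
      vals <- g[param_names]
      data.frame(method = g$method[1], rate = g$rate[1], n = nrow(g),
                 parameter = param_names,
                 mean = vapply(vals, mean, numeric(1), na.rm = TRUE),
                 se = vapply(vals, function(v)
                   stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))),
                   numeric(1)))
    }))
  rownames(desc) <- NULL
  if (!is.null(plot_dir)) plot_cohort_curves(rc, plot_dir)
  list(descriptives = desc, tests = stats_report_frame(rc),
       icc_manual_vs_auto = rc$icc_manual_vs_auto, gaps = rc$gaps)
}

# regenerate each subject's reference run and plot measured points with
# fitted curves, one PNG per (subject, rate)
plot_cohort_curves <- function(rc, plot_dir) {
  dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- rc$config
  for (i in seq_len(cfg$n_subjects)) {
    id <- sprintf("S%02d", i)
    truth <- draw_truth(derive_seed(cfg$master_seed, 1000L + i),
                        cfg$truth_ranges)
    run0 <- generate_run(truth, cfg$protocol, cfg$wspec, subject_id = id,
                         seed = derive_seed(cfg$master_seed, i))
    for (rate in cfg$rates) {
      run <- downsample_run(run0, rate)
      data <- measure_run(run, cfg$manual_windows)
      curves <- tryCatch(fit_recruitment(data), error = function(e) NULL)
      grDevices::png(file.path(plot_dir, sprintf("%s_%dHz.png", id, rate)),
                     width = 700, height = 500)
      plot_recruitment(data, curves,
                       main = sprintf("%s @ %d Hz", id, rate))
      grDevices::dev.off()
    }
  }
  invisible(NULL)
}

#' Plot measured recruitment data and fitted curves
#'
#' @param data A `recruitment_data` frame.
#' @param curves Optional [fit_recruitment()] result to overlay.
#' @param main Plot title.
#' @export
plot_recruitment <- function(data, curves = NULL, main = "Recruitment curves") {
  x <- data$intensity_mA
  graphics::plot(x, data$mrv_m_uV, pch = 1, col = "firebrick",
                 xlab = "stimulation intensity (mA)", ylab = "MRV (uV)",
                 main = main,
                 ylim = range(0, data$mrv_m_uV, data$mrv_h_uV))
  graphics::points(x, data$mrv_h_uV, pch = 2, col = "navy")
  if (!is.null(curves) && all(curves$converged)) {
    g <- params_grid(curves)
    graphics::lines(g, predict_m(curves, g), col = "firebrick")
    graphics::lines(g, predict_h(curves, g), col = "navy")
  }
  graphics::legend("topleft", c("M-wave", "H-reflex"), pch = c(1, 2),
                   col = c("firebrick", "navy"), bty = "n")
  invisible(NULL)
}
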