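#' Write / read a recruitment-curve run
#'
#' A run is stored as two files in `dir`: `<subject_id>_run.csv` with one
#' row per trial (`trial_index`, `intensity_mA`, `trigger_index` (0-based),
#' `isi_s`, then one column per sample in uV) and a JSON sidecar
#' `<subject_id>_run.json` with `fs_hz`, `subject_id`, `seed` and, for
#' synthetic runs, the ground-truth recruitment parameters. The sidecar
#' round-trips bit-exactly; samples round-trip to better than 1e-6 uV.
#'
#' @param run A [sweep_run()] object.
#' @param dir Output directory (created if needed).
#' @return `write_run()` returns the CSV path invisibly; `read_run()`
#'   returns a [sweep_run()].
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "sweep_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(run$subject_id, "_run"))
  ns <- vapply(run$trials, function(tr) length(tr$samples), integer(1))
  if (length(unique(ns)) != 1)
    stop("wide run format requires equal-length trials")
  mat <- do.call(rbind, lapply(run$trials, `[[`, "samples"))
  colnames(mat) <- sprintf("s%05d", seq_len(ncol(mat)) - 1)
  df <- data.frame(
    trial_index = seq_along(run$trials) - 1L,
    intensity_mA = intensities(run),
    trigger_index = vapply(run$trials, `[[`, numeric(1), "trigger_index"),
    isi_s = vapply(run$trials, `[[`, numeric(1), "isi"))
  utils::write.csv(cbind(df, signif(mat, 12)),
                   paste0(base, ".csv"), row.names = FALSE)
  side <- list(fs_hz = run$fs, subject_id = run$subject_id, seed = run$seed)
  if (!is.null(run$truth)) side$truth <- unclass(run$truth)
  jsonlite::write_json(side, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(base, ".csv"))
}

#' @rdname write_run
#' @param path Path to the run CSV (its `.json` sidecar must sit alongside).
#' @export
read_run <- function(path) {
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  samp_cols <- grep("^s[0-9]+$", names(df))
  trials <- lapply(seq_len(nrow(df)), function(i) {
    list(intensity = df$intensity_mA[i],
         samples = as.numeric(df[i, samp_cols]),
         trigger_index = df$trigger_index[i],
         isi = df$isi_s[i])
  })
  truth <- if (!is.null(side$truth)) do.call(recruitment_truth, side$truth)
  sweep_run(side$fs_hz, trials, side$subject_id, truth,
            if (is.null(side$seed)) NA_integer_ else side$seed)
}
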