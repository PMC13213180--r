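test_that("mean rectified value matches hand-computed rectified means", {
  e <- make_epoch(rep(3, 32), fs = 3200, t0_index = 0)
  expect_equal(mean_rectified_value(e, c(0, 10)), 3)
  e$samples <- rep(-3, 32)
  expect_equal(mean_rectified_value(e, c(0, 10)), 3)
  # hand-listed toy epoch: 6 samples at 1000 Hz, window [1, 5) ms
  toy <- make_epoch(c(2, -4, 6, -8, 1, 5), fs = 1000, t0_index = 0)
  expect_equal(mean_rectified_value(toy, c(1, 5)), mean(c(4, 6, 8, 1)))
  expect_error(mean_rectified_value(toy, c(0.1, 0.9)), "no samples")
})

test_that("MRV is invariant to a sign flip of the whole epoch", {
  set.seed(3)
  e <- make_epoch(rnorm(192), fs = 320, t0_index = 64)
  flipped <- e; flipped$samples <- -e$samples
  expect_equal(mean_rectified_value(e, c(6, 23)),
               mean_rectified_value(flipped, c(6, 23)))
})

test_that("artifact blanking zeroes exactly the first milliseconds", {
  e <- make_epoch(rep(1, 1920), t0_index = 640)
  b <- blank_artifact(e, 3)
  t <- (seq_along(b$samples) - 1 - 640) / 3200 * 1000
  expect_equal(sum(b$samples == 0), sum(t >= 0 & t < 3))
  expect_equal(sum(t >= 0 & t < 3), 10)   # ceil(3 * 3.2) samples
  # windows fully after the blank are untouched; double blank idempotent
  expect_equal(mean_rectified_value(b, c(6, 23)), 1)
  expect_identical(blank_artifact(b, 3)$samples, b$samples)
})

test_that("exponential decay removal recovers the generating decay", {
  fs <- 3200
  t <- (0:1919 - 640) / fs * 1000
  decay <- ifelse(t >= 0, 120 * exp(-t / 4), 0)
  e <- make_epoch(decay, t0_index = 640)
  out <- remove_decay(blank_artifact(e), fit_window = c(3, 15))
  expect_true(attr(out, "decay_removed"))
  expect_equal(attr(out, "decay")$tau, 4, tolerance = 0.1)
  post <- out$samples[t >= 3]
  expect_lt(sqrt(mean(post^2)), 0.01 * 120)
  # decay-free epoch: fitted amplitude is negligible, signal unchanged
  sig <- ifelse(t >= 6 & t < 23, sin(2 * pi * (t - 6) / 17), 0) * 50
  e2 <- make_epoch(sig, t0_index = 640)
  out2 <- remove_decay(e2, fit_window = c(25, 45))
  expect_equal(mean_rectified_value(out2, c(6, 23)),
               mean_rectified_value(e2, c(6, 23)), tolerance = 0.02)
})

test_that("measure_run preserves trial structure and the truth contract", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol(max_intensity = 20))
  d <- measure_run(run)
  expect_s3_class(d, "recruitment_data")
  expect_equal(nrow(d), length(run$trials))
  expect_equal(d$intensity_mA, intensities(run))
  expect_true(all(d$mrv_m_uV >= 0 & d$mrv_h_uV >= 0))
  # permuting trial order permutes rows identically
  perm <- rev(seq_along(run$trials))
  run_rev <- run; run_rev$trials <- run$trials[perm]
  class(run_rev) <- "sweep_run"
  d_rev <- measure_run(run_rev)
  expect_equal(d_rev$mrv_h_uV, d$mrv_h_uV[perm])
  # noiseless H column tracks the true recruitment values
  th <- true_h_amplitude(d$intensity_mA, tr)
  expect_lt(max(abs(d$mrv_h_uV - th)) / max(th), 0.01)
})

test_that("automated delineation recovers the generator's response windows", {
  tr <- recruitment_truth()
  run <- generate_run(tr, sweep_protocol(), waveform_spec(), seed = 55)
  overlap <- function(a, b) {
    inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
    inter / min(diff(a), diff(b))
  }
  w <- delineate_auto(run)
  expect_identical(w$method, "automated")
  expect_true(w$m_window[1] >= 5 && w$m_window[2] <= 26)
  expect_true(w$h_window[1] >= 26 && w$h_window[2] <= 48)
  expect_gte(overlap(w$m_window, c(6, 23)), 0.6)
  expect_gte(overlap(w$h_window, c(28, 45)), 0.6)
  # still delineates at 320 Hz, with a relaxed overlap requirement
  w320 <- delineate_auto(downsample_run(run, 320))
  expect_gte(overlap(w320$m_window, c(6, 23)), 0.4)
  expect_gte(overlap(w320$h_window, c(28, 45)), 0.4)
})

test_that("delineation fails loudly when no H-reflex exists", {
  tr <- recruitment_truth(h_scale = 1e-6)
  run <- generate_run(tr, sweep_protocol(), waveform_spec(), seed = 2)
  expect_error(delineate_auto(run), "H-reflex not delineated")
})

test_that("automated windows do not depend on trial presentation order", {
  tr <- recruitment_truth()
  run <- generate_run(tr, sweep_protocol(max_intensity = 30),
                      waveform_spec(), seed = 4)
  w1 <- delineate_auto(run)
  run_rev <- run; run_rev$trials <- rev(run$trials)
  class(run_rev) <- "sweep_run"
  w2 <- delineate_auto(run_rev)
  expect_equal(w1$m_window, w2$m_window)
  expect_equal(w1$h_window, w2$h_window)
})

test_that("manual and automated delineation agree on the target-relevant parameters", {
  cfg <- experiment_config(n_subjects = 8, rates = c(3200, 640),
                           methods = c("manual", "automated"),
                           master_seed = 7)
  rc <- run_experiment(cfg)
  icc <- rc$icc_manual_vs_auto
  hm <- icc[icc$parameter == "stim_at_hmax", ]
  expect_true(all(hm$icc > 0.9))
})
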