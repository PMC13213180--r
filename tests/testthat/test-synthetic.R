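test_that("noiseless trials reproduce the true amplitudes in the canonical windows", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol())
  d <- measure_run(run)
  am <- step_mean(d, "mrv_m_uV"); ah <- step_mean(d, "mrv_h_uV")
  tm <- true_m_amplitude(am$s, tr); th <- true_h_amplitude(ah$s, tr)
  # template-normalisation contract: 1% of the curve maximum at 3200 Hz
  expect_lt(max(abs(am$x - tm)) / max(tm), 0.01)
  expect_lt(max(abs(ah$x - th)) / max(th), 0.01)
})

test_that("mean measured amplitude converges to the clean value under noise", {
  tr <- recruitment_truth()
  s <- 20
  clean <- generate_trial(s, tr, quiet_wspec(), seed = 1)
  w <- quiet_wspec(noise_rms = 4)
  mrv_of <- function(trial) {
    t <- (seq_along(trial$samples) - 1 - trial$trigger_index) / 3200 * 1000
    mean(abs(trial$samples[t >= 28 & t < 45]))
  }
  mrvs <- vapply(1:100, function(i)
    mrv_of(generate_trial(s, tr, w, seed = i)), numeric(1))
  se <- sd(mrvs) / sqrt(length(mrvs))
  expect_lt(abs(mean(mrvs) - mrv_of(clean)), 3 * se + 0.05 * mrv_of(clean))
})

test_that("trial and run generation are seed-deterministic", {
  tr <- recruitment_truth()
  t1 <- generate_trial(20, tr, waveform_spec(), seed = 5)
  t2 <- generate_trial(20, tr, waveform_spec(), seed = 5)
  expect_identical(t1$samples, t2$samples)
  r1 <- generate_run(tr, sweep_protocol(max_intensity = 15), seed = 9)
  r2 <- generate_run(tr, sweep_protocol(max_intensity = 15), seed = 9)
  expect_identical(r1$trials, r2$trials)
  # different subject label => different noise stream under the same seed
  r3 <- generate_run(tr, sweep_protocol(max_intensity = 15), seed = 9,
                     subject_id = "S2")
  expect_false(identical(r1$trials[[1]]$samples, r3$trials[[1]]$samples))
})

test_that("the ramp counts trials and stops at the M-wave plateau", {
  # high m_center: the plateau rule cannot engage before the 20 mA cap
  tr <- recruitment_truth(m_center = 30)
  run <- generate_run(tr, sweep_protocol(start_intensity = 10, step = 1,
                                         trials_per_step = 4,
                                         max_intensity = 20), seed = 1)
  expect_length(run$trials, 44)
  expect_equal(intensities(run)[1:5], c(10, 10, 10, 10, 11))
  # low center, shallow cap: plateau stop engages before 50 mA
  tr2 <- recruitment_truth(m_center = 15, m_slope = 1)
  run2 <- generate_run(tr2, sweep_protocol(start_intensity = 10), seed = 1)
  expect_lt(max(intensities(run2)), 50)
  expect_gt(true_m_amplitude(max(intensities(run2)), tr2),
            0.99 * tr2$m_max)
  # ISI jitter stays within the configured band
  isis <- vapply(run$trials, `[[`, numeric(1), "isi")
  expect_true(all(isis >= 0.9 & isis <= 1.1))
})

test_that("trial generation validates its sampling rate", {
  tr <- recruitment_truth()
  expect_error(generate_trial(10, tr, fs = 1000.5), "integer")
  expect_error(generate_trial(10, tr, fs = 200), "320")
})

test_that("background gating enforces the 2 s quiet-hold rule", {
  fs <- 100
  g <- gating_spec()   # high limit 18 uV, hold 2 s
  ok <- simulate_gating(rep(3, 5 * fs), g, fs)
  expect_false(any(ok[1:(2 * fs - 1)]))
  expect_true(all(ok[(2 * fs):(5 * fs)]))
  expect_false(any(simulate_gating(rep(25, 5 * fs), g, fs)))
  # a single-sample excursion suspends permission for exactly one hold
  x <- rep(3, 10 * fs); x[401] <- 30
  ok <- simulate_gating(x, g, fs)
  expect_true(ok[400])
  expect_false(any(ok[401:(401 + 2 * fs - 1)]))
  expect_true(all(ok[(401 + 2 * fs):(10 * fs)]))
})

test_that("runs round-trip through the CSV + JSON sidecar format", {
  tr <- recruitment_truth()
  run <- generate_run(tr, sweep_protocol(max_intensity = 12), seed = 3)
  dir <- withr::local_tempdir()
  path <- write_run(run, dir)
  back <- read_run(path)
  expect_equal(back$fs, run$fs)
  expect_identical(back$subject_id, run$subject_id)
  expect_equal(unclass(back$truth), unclass(run$truth))
  expect_equal(back$trials[[5]]$trigger_index, run$trials[[5]]$trigger_index)
  expect_lt(max(abs(back$trials[[5]]$samples - run$trials[[5]]$samples)),
            1e-6)
})

test_that("cohort generation is stable under enlargement", {
  p <- sweep_protocol(max_intensity = 12)
  c3 <- simulate_cohort(3, master_seed = 11, protocol = p)
  c5 <- simulate_cohort(5, master_seed = 11, protocol = p)
  expect_identical(c3[["S02"]]$trials, c5[["S02"]]$trials)
})
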