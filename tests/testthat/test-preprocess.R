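fs <- 3200
tt <- seq(0, 2, by = 1 / fs)

test_that("Butterworth filters honour their frequency-response contracts", {
  hp10 <- filter_spec("highpass", 10, phase = "causal")
  # DC rejection: steady-state output of a constant input vanishes
  y <- butterworth_filter(rep(1, length(tt)), fs, hp10)
  expect_lt(max(abs(tail(y, fs))), 1e-6)
  # passband: 50 Hz sinusoid through the 200 Hz low-pass survives
  x50 <- sin(2 * pi * 50 * tt)
  y50 <- butterworth_filter(x50, fs, filter_spec("lowpass", 200,
                                                 phase = "causal"))
  amp <- function(v) sqrt(2 * mean(tail(v, fs)^2))
  expect_equal(amp(y50), 1, tolerance = 0.01)
  # -3 dB at the cutoff for the causal filter, within 0.2 dB
  x200 <- sin(2 * pi * 200 * tt)
  y200 <- butterworth_filter(x200, fs, filter_spec("lowpass", 200,
                                                   phase = "causal"))
  db <- 20 * log10(amp(y200))
  expect_lt(abs(db - (-3.0103)), 0.2)
  # zero-phase mode doubles the attenuation: -6 dB at the cutoff
  yzp <- butterworth_filter(x200, fs, filter_spec("lowpass", 200,
                                                  phase = "zero-phase"))
  expect_lt(abs(20 * log10(amp(yzp)) - (-6.0206)), 0.4)
})

test_that("filtering is linear and rejects cutoffs at or above Nyquist", {
  spec <- filter_spec("lowpass", 200)
  set.seed(1)
  a <- rnorm(1000); b <- rnorm(1000)
  lhs <- butterworth_filter(2 * a + 3 * b, fs, spec)
  rhs <- 2 * butterworth_filter(a, fs, spec) +
    3 * butterworth_filter(b, fs, spec)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  expect_error(butterworth_filter(a, 320, filter_spec("lowpass", 200)),
               "200.*160|160.*200")
})

test_that("the anti-alias cutoff rule reproduces the published rate pairs", {
  expect_equal(antialias_cutoff(640), 200)
  expect_equal(antialias_cutoff(320), 100)
  expect_equal(antialias_cutoff(1600), 500)
  expect_equal(antialias_cutoff(800), 250)
  expect_equal(antialias_cutoff(400), 125)
  # never at or above the target Nyquist
  for (r in c(3200, 1600, 800, 640, 400, 320))
    expect_lt(antialias_cutoff(r), r / 2)
})

test_that("downsampling decimates, quantises the trigger, and updates metadata", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol(max_intensity = 12))
  expect_identical(downsample_run(run, 3200), run)
  r640 <- downsample_run(run, 640)
  expect_equal(r640$fs, 640)
  n0 <- length(run$trials[[1]]$samples)
  expect_length(r640$trials[[1]]$samples, ceiling(n0 / 5))
  # floor mapping of a known trigger index
  run2 <- run; run2$trials[[1]]$trigger_index <- 1603
  d2 <- downsample_run(run2, 640)
  expect_equal(d2$trials[[1]]$trigger_index, 320)
  expect_equal(d2$trials[[1]]$residual_offset_s, 3 / 3200)
  expect_error(downsample_run(run, 600), "integer")
  expect_warning(downsample_run(run, 200), "320")
})

test_that("epoching yields the documented sample counts and trigger index", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol(max_intensity = 12))
  eps <- epoch_run(run)
  expect_length(eps[[1]]$samples, 1920)
  expect_equal(eps[[1]]$t0_index, 640)
  eps320 <- epoch_run(downsample_run(run, 320))
  expect_length(eps320[[1]]$samples, 192)
  expect_equal(eps320[[1]]$t0_index, 64)
  # a trial too short for the span is reported by index
  short <- run
  short$trials[[3]]$samples <- short$trials[[3]]$samples[1:100]
  expect_error(epoch_run(short), "trial 3")
})

test_that("artifact re-anchoring finds the pulse and flags flat epochs", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol(max_intensity = 12))
  e <- epoch_run(run)[[1]]
  t <- (seq_along(e$samples) - 1 - e$t0_index) / e$fs * 1000
  peak <- which(t >= 0 & t < 3)[which.max(abs(e$samples[t >= 0 & t < 3]))]
  a <- align_to_artifact(e)
  expect_true(attr(a, "aligned"))
  expect_equal(a$t0_index, peak - 1L)
  # idempotent: re-aligning an aligned epoch does not move the anchor
  expect_equal(align_to_artifact(a)$t0_index, a$t0_index)
  flat <- make_epoch(rnorm(1920, sd = 1), t0_index = 640)
  f <- align_to_artifact(flat)
  expect_false(attr(f, "aligned"))
  expect_equal(f$t0_index, 640)
})

test_that("downsampling degrades measured amplitudes only mildly", {
  tr <- recruitment_truth()
  run <- quiet_run(tr, protocol = sweep_protocol())
  d0 <- measure_run(run)
  m0 <- step_mean(d0, "mrv_m_uV"); h0 <- step_mean(d0, "mrv_h_uV")
  tm <- true_m_amplitude(m0$s, tr); th <- true_h_amplitude(h0$s, tr)
  selm <- tm > 0.1 * max(tm); selh <- th > 0.1 * max(th)
  ratios <- function(rate) {
    dr <- measure_run(downsample_run(run, rate))
    mr <- step_mean(dr, "mrv_m_uV"); hr <- step_mean(dr, "mrv_h_uV")
    c(m = median((mr$x / m0$x)[selm]), h = median((hr$x / h0$x)[selh]))
  }
  r5 <- ratios(640); r10 <- ratios(320)
  expect_true(all(abs(1 - r5) < 0.05))    # 5x decimation: < 5% change
  expect_true(all(abs(1 - r10) < 0.25))   # 10x decimation: < 25% change
  # degradation grows as the rate falls
  expect_true(all(abs(1 - r10) > abs(1 - r5)))
})
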