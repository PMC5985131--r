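test_that("detector finds every beat of a clean regular ECG", {
  sim <- synth_ecg(fs = 1000, duration_s = 30, hr_bpm = 60, jitter_pct = 0)
  det <- detect_rpeaks(sim$signal, fs = 1000)
  expect_true(abs(length(det) - 30) <= 1)
  counts <- match_beats(det, sim$beats, tol_ms = 50)
  expect_equal(counts$FP, 0)
  expect_lte(counts$FN, 1)
  # matched peaks land on the template centers
  offs <- vapply(det$samples, function(d) min(abs(sim$beats$samples - d)),
                 numeric(1))
  expect_lt(max(offs), 50)
})

test_that("flat input yields no detections and short input errors", {
  expect_equal(length(detect_rpeaks(rep(0, 5000), fs = 1000)), 0)
  expect_error(detect_rpeaks(rep(0, 500), fs = 1000), "2 s")
  expect_error(detect_rpeaks(rnorm(5000), fs = 50), "100 Hz")
})

test_that("detection is invariant to amplitude scale and polarity", {
  sim <- synth_ecg(fs = 500, duration_s = 20, hr_bpm = 75, jitter_pct = 4,
                   seed = 21)
  d1 <- detect_rpeaks(sim$signal, fs = 500)
  d10 <- detect_rpeaks(10 * sim$signal, fs = 500)
  expect_identical(d1$samples, d10$samples)
  dneg <- detect_rpeaks(-sim$signal, fs = 500)
  expect_lte(abs(length(dneg) - length(d1)), 1)
})

test_that("no two detections violate the refractory period", {
  set.seed(22)
  sim <- synth_ecg(fs = 1000, duration_s = 20, hr_bpm = 85, jitter_pct = 8)
  x <- sim$signal + rnorm(length(sim$signal), sd = 0.05)
  det <- detect_rpeaks(x, fs = 1000)
  expect_true(all(diff(det$samples) >= 0.2 * 1000))
  detf <- detect_rpeaks(x, fs = 1000, mode = "fetal")
  expect_true(all(diff(detf$samples) >= 0.15 * 1000))
})

test_that("fetal parameter set tracks a fast narrow-complex rhythm", {
  sim <- synth_ecg(fs = 1000, duration_s = 20, hr_bpm = 145, jitter_pct = 4,
                   morphology = ecg_morphology("fetal"), seed = 23)
  det <- detect_rpeaks(sim$signal, fs = 1000, mode = "fetal")
  st <- detection_stats(match_beats(det, sim$beats, tol_ms = 30))
  expect_gte(st["Sens"], 99)
  expect_gte(st["PPA"], 99)
})
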