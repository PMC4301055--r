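test_that("preprocess conserves duration and resamples to 11025 Hz", {
  w <- waveform(sin(2 * pi * 200 * seq_len(48000) / 48000), 48000)
  out <- preprocess(w)
  expect_equal(out$rate, 11025)
  expect_lte(abs(length(out$samples) - 11025), 1)
})

test_that("the 50 Hz high-pass removes infrasound and passes the call band", {
  t48 <- seq_len(2 * 48000) / 48000
  w30 <- preprocess(waveform(sin(2 * pi * 30 * t48), 48000))
  w200 <- preprocess(waveform(sin(2 * pi * 200 * t48), 48000))
  expect_lt(sd(w30$samples) / (1 / sqrt(2)), 0.01)            # >= 40 dB down
  expect_lt(abs(sd(w200$samples) / (1 / sqrt(2)) - 1), 0.05)  # passband flat
})

test_that("upsampling is refused with a clear error", {
  w <- waveform(rnorm(800), 8000)
  expect_error(preprocess(w), "refusing to upsample")
})

test_that("call bounds are detected within one energy block", {
  pad <- numeric(round(0.2 * rate_std))
  call <- make_tone(300, dur = 0.4)$samples
  w <- waveform(c(pad, call, pad), rate_std)
  b <- detect_call_bounds(w)
  expect_equal(unname(b["onset"]), 0.2, tolerance = 0.02)
  expect_equal(unname(b["offset"]), 0.6, tolerance = 0.02)
  expect_error(detect_call_bounds(waveform(numeric(1000), rate_std)),
               "undetectable")
})

test_that("f0 statistics follow from the contour arithmetic", {
  mk <- function(f0) {
    out <- data.frame(time = seq_along(f0) * 0.01, f0 = f0,
                      voiced = !is.na(f0))
    class(out) <- c("f0_contour", "data.frame")
    out
  }
  st <- measure_f0_stats(mk(c(100, 300, 200)))
  expect_equal(st[c("f0beg", "f0end", "f0max", "f0min", "f0mean", "delta_f0")],
               list(f0beg = 100, f0end = 200, f0max = 300, f0min = 100,
                    f0mean = 200, delta_f0 = 200))
  flat <- measure_f0_stats(mk(rep(200, 5)))
  expect_equal(unlist(flat[c("f0beg", "f0end", "f0max", "f0min", "f0mean")]),
               c(f0beg = 200, f0end = 200, f0max = 200, f0min = 200,
                 f0mean = 200))
  expect_equal(flat$delta_f0, 0)
  expect_error(measure_f0_stats(mk(c(NA, NA, 100))), "voiced")
})

test_that("temporal variables recover known synthetic landmarks", {
  pop <- small_population(n = 1, icc = 0)
  pr <- pop$profiles[[1]]
  pr$latent$oral["durat"] <- 0.50
  pr$latent$oral["dur_to_max"] <- 0.20
  pr$within_sd$oral[] <- 0
  cl <- synth_call(pr, "oral", seed = 23)
  ct <- extract_f0_contour(cl$wave, pitch_params("hind"),
                           onset = cl$onset, offset = cl$offset)
  tm <- measure_temporal(cl$wave, ct, onset = cl$onset, offset = cl$offset)
  expect_equal(tm$durat, 0.50, tolerance = 1e-6)
  expect_equal(tm$dur_to_max, 0.20, tolerance = 0.03)
  ## monotonically falling contour puts the maximum at the call onset
  pr$latent$oral["dur_to_max"] <- 0.02
  cl2 <- synth_call(pr, "oral", seed = 24)
  ct2 <- extract_f0_contour(cl2$wave, pitch_params("hind"),
                            onset = cl2$onset, offset = cl2$offset)
  tm2 <- measure_temporal(cl2$wave, ct2, onset = cl2$onset, offset = cl2$offset)
  expect_lt(tm2$dur_to_max, 0.06)
})

test_that("mean power spectrum resolves tones and respects call edges", {
  w <- make_tone(500, dur = 0.4)
  sp <- mean_power_spectrum_50ms(w, t_f0max = 0.2)
  expect_lt(abs(sp$freq[which.max(sp$power)] - 500), rate_std / 1024 + 1e-9)
  ## two equal tones -> two equal peaks within 1 dB
  w2 <- waveform(sin(2 * pi * 500 * seq_len(4410) / rate_std) +
                 sin(2 * pi * 1500 * seq_len(4410) / rate_std), rate_std)
  sp2 <- mean_power_spectrum_50ms(w2, t_f0max = 0.2)
  p500 <- max(sp2$power[abs(sp2$freq - 500) < 100])
  p1500 <- max(sp2$power[abs(sp2$freq - 1500) < 100])
  expect_lt(abs(10 * log10(p500 / p1500)), 1)
  ## window at the call edge is clipped, not an error
  sp3 <- mean_power_spectrum_50ms(w, t_f0max = 0.39)
  expect_s3_class(sp3, "power_spectrum")
  expect_error(mean_power_spectrum_50ms(w, t_f0max = 1.0), "outside")
})

test_that("power variables match a brute-force cumulative-energy oracle", {
  mk_spec <- function(freq, power) {
    out <- data.frame(freq = freq, power = power)
    class(out) <- c("power_spectrum", "data.frame")
    out
  }
  ## single tone: quartiles collapse onto the tone, peak_harm = 1
  freq <- seq(0, 5512.5, by = rate_std / 1024)
  p <- numeric(length(freq)); p[which.min(abs(freq - 500))] <- 1
  pv <- measure_power_vars(mk_spec(freq, p), f0_at_max = 500)
  expect_equal(pv$fpeak, pv$q25)
  expect_equal(pv$q25, pv$q50)
  expect_equal(pv$q50, pv$q75)
  expect_equal(pv$peak_harm, 1L)
  expect_equal(pv$power_f0, 0)
  ## 5 equal-power harmonics of 200 Hz: q50 at the 3rd harmonic
  p5 <- numeric(length(freq))
  for (k in 1:5) p5[which.min(abs(freq - 200 * k))] <- 1
  pv5 <- measure_power_vars(mk_spec(freq, p5), f0_at_max = 200)
  expect_lt(abs(pv5$q50 - 600), rate_std / 1024 + 1e-9)
  ## random spectra vs an independent cumulative-sum oracle
  set.seed(44)
  for (i in 1:12) {
    pr <- rexp(length(freq))
    pv_r <- measure_power_vars(mk_spec(freq, pr), f0_at_max = 180)
    cum <- cumsum(pr) / sum(pr)
    expect_equal(pv_r$q25, freq[which(cum >= 0.25)[1]])
    expect_equal(pv_r$q50, freq[which(cum >= 0.50)[1]])
    expect_equal(pv_r$q75, freq[which(cum >= 0.75)[1]])
    expect_true(pv_r$q25 <= pv_r$q50 && pv_r$q50 <= pv_r$q75)
    expect_equal(pv_r$fpeak, freq[which.max(pr)])
    expect_equal(pv_r$peak_harm, max(1L, round(pv_r$fpeak / 180)))
    expect_gte(pv_r$power_f0, 0)
  }
  expect_error(measure_power_vars(mk_spec(freq, numeric(length(freq))), 200),
               "zero-energy")
})

test_that("every successful extraction satisfies the feature invariants", {
  set.seed(46)
  for (cls in c("hind", "calf")) {
    pop <- small_population(cls, n = 4, seed = 47)
    cs <- synth_calls(pop, n_calls_per_type = 2, seed = 48)
    ft <- extract_feature_table(cs$calls)
    expect_equal(nrow(ft), 16L)
    expect_true(all(ft$f0min <= ft$f0beg + 1e-9))
    expect_true(all(ft$f0min <= ft$f0end + 1e-9))
    expect_true(all(ft$f0mean <= ft$f0max + 1e-9))
    expect_true(all(ft$f0min <= ft$f0mean + 1e-9))
    expect_equal(ft$delta_f0, ft$f0max - ft$f0min)
    expect_true(all(ft$dur_to_max >= 0 & ft$dur_to_max <= ft$durat))
    expect_true(all(ft$q25 <= ft$q50 & ft$q50 <= ft$q75))
    expect_true(all(ft$power_f0 >= 0))
    expect_true(all(ft$peak_harm >= 1))
  }
})

test_that("extraction errors are annotated with the call id", {
  w <- waveform(numeric(2000), rate_std)
  expect_error(
    extract_features(w, list(caller_class = "hind", call_id = "h01_oral_01")),
    "h01_oral_01")
})
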