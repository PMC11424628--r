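test_that("pitch_shift_config validates bands and bounds", {
  expect_s3_class(pitch_shift_config(), "pitch_shift_config")
  expect_error(pitch_shift_config(min_abs_semitones = 5, max_abs_semitones = 2),
               "min_abs")
  expect_error(pitch_shift_config(gender_bands = list(male = c(155, 85),
                                                      female = c(155, 255),
                                                      child = c(200, 320))),
               "non-degenerate")
})

test_that("sampled shifts keep the shifted F0 inside the gender band", {
  cfg <- pitch_shift_config(seed = 2)
  for (g in c("male", "female")) {
    band <- default_f0_bands()[[g]]
    f0s <- withr::with_seed(4, runif(1000, band[1] * 1.02, band[2] * 0.98))
    shifts <- vapply(seq_along(f0s), function(i)
      sample_pitch_shift(f0s[i], g, cfg, speaker_id = paste0(g, i)),
      numeric(1))
    shifted <- f0s * 2^(shifts / 12)
    expect_true(all(shifted >= band[1] & shifted <= band[2]))
    expect_true(all(abs(shifts) <= 4 + 1e-9))
  }
})

test_that("shift arithmetic: +3 st from 100 Hz lands at 118.9 Hz, in band", {
  expect_equal(100 * 2^(3 / 12), 118.92, tolerance = 1e-4)
  expect_true(100 * 2^(3 / 12) > 85 && 100 * 2^(3 / 12) < 155)
})

test_that("degenerate and deterministic draws behave", {
  zero <- pitch_shift_config(min_abs_semitones = 0, max_abs_semitones = 0)
  expect_equal(sample_pitch_shift(120, "male", zero, "a"), 0)
  cfg <- pitch_shift_config(seed = 5)
  expect_identical(sample_pitch_shift(120, "male", cfg, "a"),
                   sample_pitch_shift(120, "male", cfg, "a"))
  # F0 mid-band where neither sign of a 6 st shift stays in band: magnitude
  # must shrink to the largest feasible in-band value
  tight <- pitch_shift_config(min_abs_semitones = 6, max_abs_semitones = 6,
                              seed = 1)
  s <- sample_pitch_shift(115, "male", tight, "edge")
  expect_lt(abs(s), 6)
  expect_true(115 * 2^(s / 12) >= 85 && 115 * 2^(s / 12) <= 155)
  # no feasible shift at all: outside the band entirely
  expect_warning(s0 <- sample_pitch_shift(300, "male", tight, "oob"),
                 "no feasible")
  expect_equal(s0, 0)
})

test_that("shift_pitch scales F0 by 2^(k/12) within 3%", {
  u <- synthesize_utterance(test_profile(130), duration = 1.6, seed = 12)
  f0 <- measure_f0(u)
  for (k in c(-4, -2, 2, 4)) {
    m <- measure_f0(shift_pitch(u, k))
    expect_lt(abs(m / (f0 * 2^(k / 12)) - 1), 0.03)
  }
  expect_identical(shift_pitch(u, 0)$samples, u$samples)
  expect_error(shift_pitch(u, 15), "semitones")
})

test_that("a -12/+12 semitone round trip returns the original F0 within 3%", {
  u <- synthesize_utterance(test_profile(130), duration = 1.6, seed = 12)
  rt <- shift_pitch(shift_pitch(u, -12), 12)
  expect_length(rt$samples, length(u$samples))
  expect_lt(abs(measure_f0(rt) / measure_f0(u) - 1), 0.03)
})

test_that("noise addition + spectral subtraction denoising recovers tone", {
  u <- utterance("t", "t", 0.5 * sin(2 * pi * 500 * (0:23999) / 16000))
  off <- add_noise_then_denoise(u, pitch_shift_config(noise_snr_db = Inf))
  expect_identical(off$samples, u$samples)

  cfg <- pitch_shift_config(noise_snr_db = 20, seed = 3)
  den <- add_noise_then_denoise(u, cfg)
  expect_identical(den$samples, add_noise_then_denoise(u, cfg)$samples)
  n <- 2^14
  s <- Mod(stats::fft(den$samples[1:n] * hann_window_test(n)))^2
  fr <- (seq_len(n) - 1) * 16000 / n
  tone_band <- fr >= 450 & fr <= 550
  noise_band <- fr >= 1000 & fr <= 7000
  expect_gt(10 * log10(sum(s[tone_band]) / sum(s[noise_band])), 10)
})

test_that("Griffin-Lim resynthesis round-trips the mel features", {
  u <- synthesize_utterance(test_profile(), duration = 1.2, seed = 6)
  f <- logmel(u, preset = "clf")
  y1 <- resynthesize(f, n_iter = 25)
  y2 <- resynthesize(f, n_iter = 25)
  expect_identical(y1, y2)  # bit-stable
  f2 <- logmel(y1, preset = "clf")
  nr <- min(nrow(f), nrow(f2))
  mae_natlog <- mean(abs(unclass(f)[1:nr, ] - unclass(f2)[1:nr, ])) *
    log(10) / 20
  expect_lt(mae_natlog, 1.0)

  silent <- resynthesize(logmel(numeric(16000), preset = "clf"), n_iter = 5)
  expect_lt(sqrt(mean(silent^2)), 1e-3)
  expect_error(resynthesize(logmel(u, preset = "asv")), "clf")
})
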