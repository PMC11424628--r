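test_that("make_population apportions groups, gender and errors correctly", {
  pop <- make_population(4, c(control = 0.5, dysphonia = 0.5), seed = 1)
  tab <- table(population_table(pop)$group)
  expect_equal(as.integer(tab[c("control", "dysphonia")]), c(2L, 2L))

  pop100 <- make_population(100, gender_mix = 0.47, seed = 7)
  expect_equal(sum(population_table(pop100)$gender == "female"), 47L)

  expect_error(make_population(10, c(control = 0.6, clp = 0.5), seed = 1), "sum")
  expect_error(make_population(1, seed = 1), ">= 2")
})

test_that("population generation is deterministic and seed-sensitive", {
  a <- make_population(30, seed = 7)
  b <- make_population(30, seed = 7)
  c <- make_population(30, seed = 8)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(serialize(a, NULL), serialize(c, NULL)))
})

test_that("speaker_profile enforces invariants", {
  fmts <- cbind(center = c(500, 1500, 2500, 3500),
                bandwidth = c(70, 100, 140, 180))
  mk <- function(...) speaker_profile(...)
  base <- list(speaker_id = "s", gender = "male", age_group = "adult",
               f0_base = 120, formants = fmts, disorder = "control",
               marker_intensity = c(jitter = 0, shimmer = 0,
                                    formant_blur = 0, nasality = 0))
  expect_s3_class(do.call(mk, base), "speaker_profile")
  bad <- base; bad$f0_base <- 300
  expect_error(do.call(mk, bad), "band")
  bad <- base; bad$formants <- fmts[c(2, 1, 3, 4), ]
  expect_error(do.call(mk, bad), "increasing")
  bad <- base; bad$formants[4, 1] <- 9000
  expect_error(do.call(mk, bad), "Nyquist")
})

test_that("synthesized utterance has the requested F0 (autocorrelation oracle)", {
  u <- synthesize_utterance(test_profile(120), duration = 2, seed = 3)
  periods <- oracle_periods(u$samples[1:round(0.4 * length(u$samples))],
                            f0_nominal = 120)
  lag <- stats::median(periods)
  expect_lt(abs(lag - 16000 / 120) / (16000 / 120), 0.05)
  expect_true(all(abs(u$samples) <= 1))
  expect_equal(u$sampling_rate, 16000L)
})

test_that("synthesis is deterministic and contains a silent gap >= 100 ms", {
  u1 <- synthesize_utterance(test_profile(), duration = 1.5, seed = 9)
  u2 <- synthesize_utterance(test_profile(), duration = 1.5, seed = 9)
  expect_identical(u1$samples, u2$samples)
  r <- rle(u1$samples == 0)
  expect_gte(max(r$lengths[r$values]), 0.1 * 16000)
  expect_error(synthesize_utterance(test_profile(), duration = 0.3), "duration")
})

test_that("jitter intensity maps monotonically to measured period variability", {
  mk <- function(j, dis) test_profile(120, dis, c(jitter = j, shimmer = 0.05,
                                                  formant_blur = 0.05,
                                                  nasality = 0.05))
  sds <- vapply(c(0.05, 0.4, 0.8), function(j) {
    u <- synthesize_utterance(mk(j, if (j > 0.1) "dysphonia" else "control"),
                              duration = 3, seed = 5)
    per <- oracle_periods(u$samples[1:20000], f0_nominal = 120)
    expect_gte(length(per), 100)
    stats::sd(per)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("shimmer and nasality markers map monotonically to their acoustics", {
  # shimmer -> cycle-amplitude std (peak amplitudes via the period oracle)
  amp_sd <- vapply(c(0.05, 0.8), function(s) {
    p <- test_profile(120, if (s > 0.1) "dysphonia" else "control",
                      c(jitter = 0.02, shimmer = s, formant_blur = 0.02,
                        nasality = 0.02))
    u <- synthesize_utterance(p, duration = 3, seed = 6)
    x <- u$samples[1:20000]
    peaks <- oracle_pulse_peaks(x, f0_nominal = 120)
    stats::sd(abs(x[peaks])) / mean(abs(x[peaks]))
  }, numeric(1))
  expect_gt(amp_sd[2], amp_sd[1])

  # nasality -> low-frequency spectral prominence (band power 200-500 Hz
  # relative to 500-3000 Hz)
  low_ratio <- vapply(c(0.1, 0.9), function(nas) {
    p <- test_profile(120, "clp", c(jitter = 0.02, shimmer = 0.02,
                                    formant_blur = 0.1, nasality = nas))
    u <- synthesize_utterance(p, duration = 2, seed = 6)
    n <- 2^14
    s <- Mod(stats::fft(u$samples[1:n] * hann_window_test(n)))^2
    fr <- (seq_len(n) - 1) * 16000 / n
    sum(s[fr >= 200 & fr < 500]) / sum(s[fr >= 500 & fr < 3000])
  }, numeric(1))
  expect_gt(low_ratio[2], low_ratio[1])
})

test_that("generate_corpus yields the right shape and survives WAV round trip", {
  pop <- make_population(10, c(control = 1), seed = 3)
  corp <- generate_corpus(pop, utterances_per_speaker = 8,
                          duration_range = c(0.8, 1.0), seed = 3)
  expect_equal(nrow(corp$metadata), 80L)
  expect_length(corp$utterances, 80L)
  expect_setequal(colnames(corp$metadata),
                  c("utterance_id", "speaker_id", "group", "gender",
                    "age_group", "duration_s", "path"))

  dir <- withr::local_tempdir()
  small <- corp
  keep <- corp$metadata$utterance_id[1:4]
  small$utterances <- corp$utterances[keep]
  small$metadata <- corp$metadata[corp$metadata$utterance_id %in% keep, ]
  write_corpus(small, dir)
  back <- read_corpus(dir)
  for (id in keep) {
    expect_lte(max(abs(back$utterances[[id]]$samples -
                         small$utterances[[id]]$samples)), 1 / 32767)
  }
})

test_that("distinct corpus seeds give distinct audio", {
  pop <- make_population(2, c(control = 1), seed = 3)
  a <- generate_corpus(pop, 1, c(0.8, 0.9), seed = 1)
  b <- generate_corpus(pop, 1, c(0.8, 0.9), seed = 2)
  expect_false(identical(a$utterances[[1]]$samples, b$utterances[[1]]$samples))
})
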