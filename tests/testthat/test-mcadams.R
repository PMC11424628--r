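test_that("mcadams_config validates its invariants", {
  expect_s3_class(mcadams_config(), "mcadams_config")
  expect_error(mcadams_config(random_low = 0.95, random_high = 0.9), "random_low")
  expect_error(mcadams_config(mode = "fixed", fixed_value = 1.5), "fixed_value")
  expect_error(mcadams_config(lpc_order = 4), "lpc_order")
  expect_error(mcadams_config(overlap = 0.95), "overlap")
  legacy <- mcadams_config(mode = "random_per_speaker")
  expect_equal(legacy$mode, "random")
  expect_equal(legacy$grain, "per_speaker")
})

test_that("sample_coefficient draws stay in range and are reproducible", {
  cfg <- mcadams_config(seed = 3)
  draws <- vapply(sprintf("id%04d", 1:2000), function(id)
    sample_coefficient(cfg, id), numeric(1))
  expect_true(all(draws >= 0.75 & draws <= 0.90))
  expect_gt(length(unique(round(draws, 6))), 1900)
  expect_identical(sample_coefficient(cfg, "abc"), sample_coefficient(cfg, "abc"))
  fixed <- mcadams_config(mode = "fixed", fixed_value = 0.8)
  expect_identical(sample_coefficient(fixed, "anyone"), 0.8)
})

test_that("transform_poles implements phi^alpha with radius preserved", {
  p <- complex(modulus = 0.95, argument = 0.5)
  out <- transform_poles(c(p, Conj(p)), 0.8)
  expect_equal(Arg(out[1]), 0.5^0.8, tolerance = 1e-12)
  expect_equal(Mod(out[1]), 0.95, tolerance = 1e-12)
  expect_equal(out[2], Conj(out[1]))

  expect_equal(transform_poles(complex(real = 0.9), 0.8), complex(real = 0.9))
  id <- complex(modulus = c(0.9, 0.8), argument = c(0.3, 1.2))
  expect_equal(transform_poles(id, 1), id, tolerance = 1e-12)
  expect_warning(transform_poles(complex(modulus = 1.05, argument = 0.4), 0.8),
                 "clipped")
})

test_that("pole-angle move direction matches the phi^alpha geometry", {
  for (phi in c(0.1, 0.3, 0.7, 0.99, 1.01, 1.5, 2.5)) {
    for (alpha in c(0.6, 0.8, 0.95)) {
      new_phi <- Arg(transform_poles(complex(modulus = 0.9, argument = phi),
                                     alpha))
      if (phi < 1) expect_gt(new_phi, phi) else expect_lt(new_phi, phi)
    }
  }
})

test_that("alpha = 1 anonymization is a near-identity (log-spectral distance)", {
  u <- synthesize_utterance(test_profile(), duration = 1.5, seed = 8)
  ua <- anonymize_mcadams(u, mcadams_config(mode = "fixed", fixed_value = 1),
                          alpha = 1)
  expect_length(ua$samples, length(u$samples))
  f1 <- unclass(logmel(u, preset = "asv"))
  f2 <- unclass(logmel(ua, preset = "asv"))
  interior <- 5:(nrow(f1) - 5)  # overlap-add edges taper by construction
  lsd <- mean(vapply(interior, function(k)
    sqrt(mean((f1[k, ] - f2[k, ])^2)), numeric(1)))
  expect_lt(lsd, 1)
})

test_that("a single formant moves to the phi^alpha-predicted frequency", {
  ex <- withr::with_seed(1, rnorm(48000))
  x <- as.numeric(stats::filter(ex, c(2 * exp(-pi * 80 / 16000) * cos(2 * pi * 1000 / 16000),
                                      -exp(-pi * 80 / 16000)^2),
                                method = "recursive"))
  x <- x / max(abs(x)) * 0.9
  ut <- utterance("t", "t", x)
  ua <- anonymize_mcadams(ut, mcadams_config(mode = "fixed", fixed_value = 0.8,
                                             lpc_order = 8), alpha = 0.8)
  predicted <- (2 * pi * 1000 / 16000)^0.8 * 16000 / (2 * pi)  # ~1206 Hz
  measured <- oracle_peak_hz(ua$samples[2000:18000])
  expect_lt(abs(measured - predicted), 50)
})

test_that("anonymization is deterministic, finite, energy-sane", {
  u <- synthesize_utterance(test_profile(), duration = 1.2, seed = 2)
  cfg <- mcadams_config(seed = 4)
  a1 <- anonymize_mcadams(u, cfg)
  a2 <- anonymize_mcadams(u, cfg)
  expect_identical(a1$samples, a2$samples)
  expect_true(all(is.finite(a1$samples)))
  rms_ratio_db <- 20 * log10(sqrt(mean(a1$samples^2)) / sqrt(mean(u$samples^2)))
  expect_lt(abs(rms_ratio_db), 6)
})

test_that("corpus anonymization respects the randomization grain", {
  pop <- make_population(3, c(control = 1), seed = 2)
  corp <- generate_corpus(pop, utterances_per_speaker = 2,
                          duration_range = c(0.8, 0.9), seed = 2)
  per_utt <- anonymize_corpus_mcadams(corp, mcadams_config(seed = 9))
  expect_length(attr(per_utt, "alphas"), 6L)
  per_spk <- anonymize_corpus_mcadams(
    corp, mcadams_config(grain = "per_speaker", seed = 9))
  expect_length(attr(per_spk, "alphas"), 3L)
})
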