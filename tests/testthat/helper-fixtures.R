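# Shared fixtures (memoized: built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 20 control-only speakers: the default privacy corpus.
eer_corpus <- function() {
  fixture("eer_corpus", function() {
    pop <- make_population(20, c(control = 1), seed = 11)
    generate_corpus(pop, utterances_per_speaker = 4,
                    duration_range = c(1.6, 2.2), seed = 11)
  })
}

mcadams_eer_corpus <- function() {
  fixture("mcadams_eer_corpus", function() {
    anonymize_corpus_mcadams(eer_corpus(), mcadams_config(seed = 5))
  })
}

pitch_eer_corpus <- function() {
  fixture("pitch_eer_corpus", function() {
    anonymize_corpus_pitch(eer_corpus(), pitch_shift_config(seed = 5))
  })
}

# 30 speakers, control vs dysphonia: the default utility corpus.
clf_corpus <- function() {
  fixture("clf_corpus", function() {
    pop <- make_population(30, c(control = 0.5, dysphonia = 0.5), seed = 21)
    generate_corpus(pop, utterances_per_speaker = 6,
                    duration_range = c(2.0, 2.4), seed = 21)
  })
}

# A deterministic control profile for signal-level tests.
test_profile <- function(f0 = 120, disorder = "control",
                         marker = c(jitter = 0.05, shimmer = 0.05,
                                    formant_blur = 0.05, nasality = 0.05)) {
  speaker_profile("spkT", "male", "adult", f0,
                  cbind(center = c(500, 1500, 2500, 3500),
                        bandwidth = c(70, 100, 140, 180)),
                  disorder, marker)
}

# --- independent oracles -----------------------------------------------------

# Cycle extraction by waveform peak picking (independent of the package's
# autocorrelation F0 estimator): one peak per glottal cycle.
oracle_pulse_peaks <- function(x, sr = 16000, f0_nominal = 120) {
  period0 <- sr / f0_nominal
  thr <- 0.3 * max(abs(x))
  peaks <- integer(0)
  i <- 2
  while (i < length(x) - 1) {
    w_end <- min(i + floor(0.7 * period0), length(x))
    seg <- abs(x[i:w_end])
    if (max(seg) > thr) {
      p <- i + which.max(seg) - 1L
      peaks <- c(peaks, p)
      i <- p + floor(0.6 * period0)
    } else {
      i <- w_end
    }
  }
  peaks
}

oracle_periods <- function(x, sr = 16000, f0_nominal = 120) {
  diff(oracle_pulse_peaks(x, sr, f0_nominal))
}

# Brute-force EER: evaluate FAR/FRR at every midpoint between consecutive
# sorted scores (plus outer points) and take the crossing value.
oracle_eer <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- sort(unique(scores))
  mids <- c(min(s) - 1, (s[-1] + s[-length(s)]) / 2, max(s) + 1, s)
  far <- vapply(mids, function(t) mean(neg >= t), numeric(1))
  frr <- vapply(mids, function(t) mean(pos < t), numeric(1))
  o <- order(mids)
  far <- far[o]; frr <- frr[o]; mids <- mids[o]
  d <- far - frr
  k <- which(d[-length(d)] >= 0 & d[-1] <= 0)[1]
  if (is.na(k)) return(far[which.min(abs(d))])
  if (d[k] == 0) return(far[k])
  u <- d[k] / (d[k] - d[k + 1])
  far[k] + u * (far[k + 1] - far[k])
}

# Brute-force AUROC: explicit concordance count over all (pos, neg) pairs.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Dominant spectral pole angle via LPC on the signal (order 8), restricted to
# complex poles: the resonance peak locator used by the McAdams shift test.
oracle_peak_hz <- function(x, sr = 16000, order = 8) {
  an <- lpc_analyze(x * hann_window_test(length(x)), order)
  p <- an$poles
  p <- p[Im(p) > 1e-6]
  ang <- Arg(p[which.max(Mod(p))])
  ang * sr / (2 * pi)
}

hann_window_test <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
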