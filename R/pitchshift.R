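# Randomized per-speaker pitch-shift anonymization. The shift magnitude is
# drawn uniformly per speaker; the sign is random but constrained so the
# shifted fundamental frequency stays inside the speaker's gender/age F0 band
# (gender preservation). Pitch is scaled with a phase-vocoder time-scale
# modification followed by resampling, which preserves duration. A
# deterministic Griffin-Lim spectrogram inversion stands in for the neural
# vocoder behind the same resynthesis interface.

#' Pitch-shift anonymizer configuration
#'
#' @param min_abs_semitones,max_abs_semitones bounds on the shift magnitude
#'   (defaults 1 and 4 semitones; `0 < min <= max <= 12`).
#' @param gender_bands named list of F0 bands (Hz), keys `male`, `female`,
#'   `child`; see [default_f0_bands()].
#' @param noise_snr_db SNR of the optional noise-addition/denoising step;
#'   `Inf` disables the step (default).
#' @param seed integer seed for the per-speaker draws.
#' @return object of class `pitch_shift_config`.
#' @export
pitch_shift_config <- function(min_abs_semitones = 1, max_abs_semitones = 4,
                               gender_bands = default_f0_bands(),
                               noise_snr_db = Inf, seed = 1L) {
  if (!(min_abs_semitones > 0 && min_abs_semitones <= max_abs_semitones &&
        max_abs_semitones <= 12) && !(min_abs_semitones == 0 && max_abs_semitones == 0)) {
    stop("need 0 < min_abs <= max_abs <= 12 (or both zero)")
  }
  if (any(vapply(gender_bands, function(b) diff(b) <= 0, logical(1)))) {
    stop("gender bands must be non-degenerate")
  }
  structure(list(min_abs_semitones = min_abs_semitones,
                 max_abs_semitones = max_abs_semitones,
                 gender_bands = gender_bands, noise_snr_db = noise_snr_db,
                 seed = as.integer(seed)),
            class = "pitch_shift_config")
}

#' Draw a signed per-speaker pitch shift respecting the F0 band
#'
#' The magnitude is uniform on `[min_abs, max_abs]` semitones and the sign
#' uniform, flipped if the shifted F0 would leave the band. If both signs
#' would exit, the magnitude is reduced to the largest feasible value; if no
#' shift is feasible the result is 0 with a warning.
#'
#' @param f0 the speaker's measured or declared fundamental frequency in Hz.
#' @param gender `"male"`, `"female"`; with `age_group = "child"` the child
#'   band is used.
#' @param config a [pitch_shift_config()].
#' @param speaker_id id used to derive the per-speaker random substream.
#' @param age_group `"adult"` or `"child"`.
#' @return signed shift in semitones.
#' @export
sample_pitch_shift <- function(f0, gender, config = pitch_shift_config(),
                               speaker_id = "spk", age_group = "adult") {
  band <- f0_band_for(gender, age_group, config$gender_bands)
  with_seed(derive_seed(config$seed, "pitch", speaker_id), {
    mag <- stats::runif(1, config$min_abs_semitones, config$max_abs_semitones)
    sgn <- if (stats::runif(1) < 0.5) 1 else -1
    # signed shifts that land inside the band form the interval [s_lo, s_hi]
    s_lo <- 12 * log2(band[1] / f0)
    s_hi <- 12 * log2(band[2] / f0)
    fits <- function(s) s >= s_lo && s <= s_hi
    if (fits(sgn * mag)) return(sgn * mag)
    if (fits(-sgn * mag)) return(-sgn * mag)
    # both signs exit: largest |s| with s in [s_lo, s_hi] and |s| <= mag
    lo <- max(s_lo, -mag)
    hi <- min(s_hi, mag)
    if (lo > hi) {
      warning("no feasible pitch shift for F0 ", round(f0, 1),
              " Hz within band [", band[1], ", ", band[2], "]; shift = 0")
      return(0)
    }
    if (abs(lo) >= abs(hi)) lo else hi
  })
}

# Phase-vocoder time-scale modification: stretches the signal by `stretch`
# (output duration = input * stretch) with pitch preserved.
phase_vocoder_stretch <- function(x, stretch, n_fft = 1024L, hop = 256L) {
  X <- stft(x, n_fft, hop, n_fft)
  n_bins <- nrow(X)
  n_frames <- ncol(X)
  if (n_frames < 2) return(x)
  phi_adv <- 2 * pi * (seq_len(n_bins) - 1L) / n_fft * hop
  steps <- seq(0, n_frames - 2, by = 1 / stretch)
  out <- matrix(0i, n_bins, length(steps))
  phase <- Arg(X[, 1])
  for (j in seq_along(steps)) {
    t0 <- floor(steps[j])
    frac <- steps[j] - t0
    c1 <- X[, t0 + 1L]
    c2 <- X[, min(t0 + 2L, n_frames)]
    mag <- (1 - frac) * Mod(c1) + frac * Mod(c2)
    out[, j] <- mag * exp(1i * phase)
    dphi <- Arg(c2) - Arg(c1) - phi_adv
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + phi_adv + dphi
  }
  istft(out, n_fft, hop, n_fft)
}

# Linear-interpolation resampling at a fixed rate ratio.
resample_linear <- function(x, rate, length_out) {
  pos <- 1 + (seq_len(length_out) - 1) * rate
  pos <- pmin(pos, length(x))
  lo <- floor(pos)
  hi <- pmin(lo + 1, length(x))
  frac <- pos - lo
  x[lo] * (1 - frac) + x[hi] * frac
}

#' Shift the pitch of an utterance by a number of semitones
#'
#' Pitch is scaled by `2^(semitones/12)` with duration preserved: phase-vocoder
#' time-scale modification followed by resampling.
#'
#' @param utt an [utterance()] or numeric waveform at 16 kHz.
#' @param semitones signed shift, `|semitones| <= 12`.
#' @return same type as input, identical length.
#' @export
shift_pitch <- function(utt, semitones) {
  if (abs(semitones) > 12) stop("|semitones| must be <= 12")
  x <- if (inherits(utt, "utterance")) utt$samples else as.numeric(utt)
  if (abs(semitones) < 1e-9) {
    return(utt)
  }
  rho <- 2^(semitones / 12)
  stretched <- phase_vocoder_stretch(x, rho)
  y <- resample_linear(stretched, rho, length(x))
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak * max(abs(x))
  if (inherits(utt, "utterance")) replace_samples(utt, y) else y
}

#' Add white noise then denoise by spectral subtraction
#'
#' Noise is added at `config$noise_snr_db` (relative to the signal RMS),
#' followed by magnitude spectral subtraction with a per-bin noise-floor
#' estimate (10th percentile across frames) and a spectral floor of 5% of the
#' noisy magnitude. `noise_snr_db = Inf` disables the step (identity).
#'
#' @param utt an [utterance()].
#' @param config a [pitch_shift_config()].
#' @return an [utterance()].
#' @export
add_noise_then_denoise <- function(utt, config = pitch_shift_config()) {
  snr <- config$noise_snr_db
  if (!is.finite(snr)) return(utt)
  x <- utt$samples
  sigma <- rms(x) / db_to_amp(snr)
  noisy <- x + with_seed(derive_seed(config$seed, "noise", utt$utterance_id),
                         stats::rnorm(length(x), 0, sigma))
  n_fft <- 512L; hop <- 160L
  if (length(noisy) < n_fft) return(replace_samples(utt, noisy))
  X <- stft(noisy, n_fft, hop, n_fft)
  mag <- Mod(X)
  # the added-noise level is known, so the expected per-bin noise magnitude
  # is closed form: E|N_k| = sigma * sqrt(sum w^2) * sqrt(pi)/2 for windowed
  # white Gaussian noise
  noise_est <- sigma * sqrt(sum(hann_window(n_fft)^2)) * sqrt(pi) / 2
  clean_mag <- pmax(mag - 1.5 * noise_est, 0.05 * mag)
  Y <- clean_mag * exp(1i * Arg(X))
  y <- istft(Y, n_fft, hop, n_fft, length_out = length(x))
  replace_samples(utt, y)
}

#' Resynthesize a waveform from clf-preset log-Mel features
#'
#' Deterministic stand-in for a neural vocoder: the mel magnitudes are
#' inverted through the Moore-Penrose pseudo-inverse of the mel filterbank
#' (clipped at zero) and the waveform is reconstructed by fixed-iteration
#' Griffin-Lim phase estimation. Bit-stable across runs.
#'
#' @param feats a `logmel` matrix produced with the `"clf"` preset.
#' @param n_iter Griffin-Lim iterations (default 40).
#' @return numeric waveform.
#' @export
resynthesize <- function(feats, n_iter = 40L) {
  if (!inherits(feats, "logmel")) stop("feats must be a logmel object")
  p <- logmel_preset("clf")
  if (attr(feats, "n_mels") != p$n_mels || attr(feats, "n_fft") != p$n_fft) {
    stop("resynthesize expects clf-preset features (80 mels, n_fft 1024)")
  }
  sr <- attr(feats, "sampling_rate")
  wl <- round(attr(feats, "window_s") * sr)
  hop <- round(attr(feats, "hop_s") * sr)
  n_fft <- attr(feats, "n_fft")
  mel_mag <- t(10^(unclass(feats) / 20))          # n_mels x frames
  fb <- mel_filterbank(p$n_mels, n_fft, sr)
  S <- pmax(MASS::ginv(fb) %*% mel_mag, 0)        # n_bins x frames
  L <- wl + (ncol(S) - 1L) * hop
  y <- istft(S * exp(0i), wl, hop, n_fft, length_out = L)
  for (it in seq_len(n_iter)) {
    X <- stft(y, wl, hop, n_fft)
    nc <- min(ncol(X), ncol(S))
    Y <- S[, seq_len(nc), drop = FALSE] * exp(1i * Arg(X[, seq_len(nc), drop = FALSE]))
    y <- istft(Y, wl, hop, n_fft, length_out = L)
  }
  y
}

#' Measure the fundamental frequency of a voiced signal by autocorrelation
#' @param utt an [utterance()] or numeric waveform.
#' @param f0_range search range in Hz.
#' @return estimated F0 in Hz.
#' @export
measure_f0 <- function(utt, f0_range = c(60, 400)) {
  x <- if (inherits(utt, "utterance")) utt$samples else as.numeric(utt)
  sr <- if (inherits(utt, "utterance")) utt$sampling_rate else 16000L
  x <- remove_drift(x - mean(x), cutoff_hz = 50)
  lags <- seq(floor(sr / f0_range[2]), ceiling(sr / f0_range[1]))
  ac <- stats::acf(x, lag.max = max(lags) + 1L, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  v <- ac[lags + 1L]
  # prefer true local maxima over the range edge of a decaying envelope
  inner <- seq(2, length(v) - 1L)
  locmax <- inner[v[inner] > v[inner - 1L] & v[inner] >= v[inner + 1L]]
  lag_best <- if (length(locmax)) lags[locmax[which.max(v[locmax])]] else
    lags[which.max(v)]
  sr / lag_best
}

#' Pitch-shift anonymize a whole corpus
#'
#' One shift draw per speaker (F0 measured from the speaker's first
#' utterance), applied to all of the speaker's utterances; optional
#' noise-addition/denoising; optional mel-domain resynthesis through
#' [resynthesize()] (`resynth = TRUE`), mirroring a vocoder-based pipeline.
#'
#' @param corpus a `speech_corpus`.
#' @param config a [pitch_shift_config()].
#' @param resynth route the shifted audio through log-Mel analysis and
#'   Griffin-Lim resynthesis (slower; default FALSE).
#' @return anonymized corpus; per-speaker shifts in attribute `shifts`.
#' @export
anonymize_corpus_pitch <- function(corpus, config = pitch_shift_config(),
                                   resynth = FALSE) {
  md <- corpus$metadata
  speakers <- unique(md$speaker_id)
  shifts <- numeric(length(speakers))
  names(shifts) <- speakers
  for (s in speakers) {
    first_utt <- corpus$utterances[[md$utterance_id[md$speaker_id == s][1]]]
    f0 <- measure_f0(first_utt)
    row <- md[md$speaker_id == s, ][1, ]
    shifts[s] <- sample_pitch_shift(f0, row$gender, config, speaker_id = s,
                                    age_group = row$age_group)
  }
  out <- transform_corpus(corpus, function(u) {
    v <- shift_pitch(u, shifts[[u$speaker_id]])
    v <- add_noise_then_denoise(v, config)
    if (resynth) {
      y <- resynthesize(logmel(v, preset = "clf"))
      v <- replace_samples(v, y)
    }
    v
  })
  attr(out, "shifts") <- shifts
  out
}

#' Resynthesis-only corpus transform (vocoder ablation)
#'
#' Converts each utterance to clf-preset log-Mel features and back through
#' [resynthesize()] with no other modification.
#'
#' @param corpus a `speech_corpus`.
#' @param n_iter Griffin-Lim iterations.
#' @return resynthesized corpus.
#' @export
resynth_only_corpus <- function(corpus, n_iter = 40L) {
  transform_corpus(corpus, function(u) {
    y <- resynthesize(logmel(u, preset = "clf"), n_iter = n_iter)
    peak <- max(abs(y))
    if (peak > 0) y <- y / peak * max(abs(u$samples))
    replace_samples(u, y)
  })
}
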