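# Shared preprocessing and feature extraction. Two named log-Mel presets are
# used downstream: "asv" (40 bands, 25 ms window, 10 ms hop, 512-point STFT)
# for speaker verification and "clf" (80 bands, 25 ms, 10 ms, 1024-point STFT)
# for disorder classification. All STFT analyses use a periodic Hann window;
# the mel filterbank uses triangular filters with HTK-style spacing over
# 0-8000 Hz. Frames are 0-based half-open sample intervals.

#' Log-Mel feature presets
#' @param name `"asv"` or `"clf"`.
#' @return list with `n_mels`, `window_s`, `hop_s`, `n_fft`.
#' @export
logmel_preset <- function(name = c("asv", "clf")) {
  name <- match.arg(name)
  switch(name,
         asv = list(n_mels = 40L, window_s = 0.025, hop_s = 0.010, n_fft = 512L),
         clf = list(n_mels = 80L, window_s = 0.025, hop_s = 0.010, n_fft = 1024L))
}

# Magnitude STFT: returns (n_fft/2 + 1) x n_frames matrix of complex values.
stft <- function(x, window_len, hop, n_fft) {
  if (n_fft < window_len) stop("n_fft must be >= window length")
  frames <- frame_signal(x, window_len, hop)
  frames <- frames * hann_window(window_len)
  if (n_fft > window_len) {
    frames <- rbind(frames, matrix(0, n_fft - window_len, ncol(frames)))
  }
  spec <- stats::mvfft(frames)
  spec[seq_len(n_fft %/% 2 + 1L), , drop = FALSE]
}

# Inverse STFT by windowed overlap-add with window-sum normalization.
istft <- function(spec, window_len, hop, n_fft, length_out = NULL) {
  full <- rbind(spec, Conj(spec[rev(seq(2, nrow(spec) - 1L)), , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  frames <- frames[seq_len(window_len), , drop = FALSE]
  w <- hann_window(window_len)
  frames <- frames * w
  n_frames <- ncol(frames)
  L <- window_len + (n_frames - 1L) * hop
  y <- numeric(L)
  wsum <- numeric(L)
  for (k in seq_len(n_frames)) {
    idx <- (k - 1L) * hop + seq_len(window_len)
    y[idx] <- y[idx] + frames[, k]
    wsum[idx] <- wsum[idx] + w^2
  }
  # cap the normalization gain so near-zero window sums at the signal edges
  # cannot blow up into spikes
  y <- y / pmax(wsum, 0.25 * max(wsum))
  if (!is.null(length_out)) {
    if (length(y) >= length_out) y <- y[seq_len(length_out)]
    else y <- c(y, numeric(length_out - length(y)))
  }
  y
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank (HTK-style spacing)
#' @param n_mels number of bands.
#' @param n_fft FFT size.
#' @param sr sampling rate in Hz.
#' @param fmin,fmax frequency range in Hz.
#' @return `n_mels x (n_fft/2 + 1)` matrix of filter weights.
#' @export
mel_filterbank <- function(n_mels, n_fft, sr = 16000, fmin = 0, fmax = sr / 2) {
  n_bins <- n_fft %/% 2 + 1L
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (seq_len(n_bins) - 1L) * sr / n_fft
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bin_freqs - lo) / max(ce - lo, 1e-9)
    down <- (hi - bin_freqs) / max(hi - ce, 1e-9)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel spectrogram
#'
#' Magnitude STFT, triangular mel filterbank over 0-8000 Hz, then a dB-scale
#' log with an epsilon floor: `20 * log10(max(mel, floor_eps))`. Scaling the
#' waveform by `g` therefore shifts every (un-floored) cell by `20*log10(g)`.
#'
#' @param utt an [utterance()] or numeric waveform.
#' @param preset `"asv"`, `"clf"`, or `NULL` to pass explicit parameters.
#' @param n_mels,window_s,hop_s,n_fft explicit parameters when `preset` is NULL.
#' @param floor_eps magnitude floor before the log.
#' @return object of class `logmel` (frames x n_mels matrix with parameter
#'   attributes).
#' @export
logmel <- function(utt, preset = "asv", n_mels = NULL, window_s = NULL,
                   hop_s = NULL, n_fft = NULL, floor_eps = 1e-6) {
  x <- if (inherits(utt, "utterance")) utt$samples else as.numeric(utt)
  sr <- if (inherits(utt, "utterance")) utt$sampling_rate else 16000L
  if (!is.null(preset)) {
    p <- logmel_preset(preset)
    n_mels <- p$n_mels; window_s <- p$window_s; hop_s <- p$hop_s; n_fft <- p$n_fft
  }
  wl <- round(window_s * sr)
  hop <- round(hop_s * sr)
  if (length(x) < wl) stop("signal shorter than one analysis window")
  spec <- Mod(stft(x, wl, hop, n_fft))
  fb <- mel_filterbank(n_mels, n_fft, sr)
  mel <- fb %*% spec                       # n_mels x frames
  vals <- t(20 * log10(pmax(mel, floor_eps)))
  structure(vals, class = c("logmel", "matrix"),
            n_mels = n_mels, window_s = window_s, hop_s = hop_s,
            n_fft = as.integer(n_fft), sampling_rate = sr,
            floor_db = 20 * log10(floor_eps))
}

# Frame-level dB energies on a fixed non-overlapping grid, shared by the
# level gate.
frame_energy_db <- function(x, frame_len) {
  n_frames <- max(1L, length(x) %/% frame_len)
  e <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    idx <- (k - 1L) * frame_len + seq_len(frame_len)
    e[k] <- mean(x[idx]^2)
  }
  10 * log10(pmax(e, 1e-20))
}

#' Excise low-level frames from an utterance
#'
#' Frames (10 ms, non-overlapping) whose level falls `threshold_db` dB or more
#' below the reference are removed and the remainder concatenated. Digital
#' recordings carry no sound-pressure calibration, so by default the reference
#' is the utterance's noise-floor estimate (5th percentile frame energy); a
#' frame is kept when it sits at least `threshold_db` dB above that floor.
#' When the utterance's dynamic range is smaller than the threshold (no silence
#' present) the signal is returned unchanged. With `reference = "dbfs"` the
#' level is measured as dB relative to full scale plus `dbfs_offset`.
#'
#' @param utt an [utterance()].
#' @param threshold_db gate threshold in dB (default 30).
#' @param reference `"noise_floor"` (default) or `"dbfs"`.
#' @param frame_s gating frame length in seconds.
#' @param dbfs_offset offset added to dBFS levels in `"dbfs"` mode (default 90,
#'   mapping full scale to 90 dB).
#' @return an [utterance()]; if every frame is below threshold an empty
#'   utterance with attribute `empty = TRUE` is returned (not an error).
#' @export
remove_low_level <- function(utt, threshold_db = 30,
                             reference = c("noise_floor", "dbfs"),
                             frame_s = 0.010, dbfs_offset = 90) {
  stopifnot(threshold_db >= 0)
  reference <- match.arg(reference)
  x <- utt$samples
  fl <- round(frame_s * utt$sampling_rate)
  if (length(x) < fl) return(utt)
  db <- frame_energy_db(x, fl)
  if (reference == "noise_floor") {
    floor_db <- stats::quantile(db, 0.05, names = FALSE)
    if (max(db) - floor_db < threshold_db) return(utt)  # no silence present
    keep <- db - floor_db >= threshold_db
  } else {
    keep <- db + dbfs_offset >= threshold_db
  }
  n_frames <- length(keep)
  mask <- rep(keep, each = fl)
  tail_idx <- if (n_frames * fl < length(x)) seq(n_frames * fl + 1L, length(x)) else integer(0)
  kept <- c(x[seq_len(n_frames * fl)][mask], x[tail_idx])
  out <- replace_samples(utt, kept)
  if (length(kept) == 0) attr(out, "empty") <- TRUE
  out
}

#' Energy-based voice activity detection
#'
#' Short-time energy over `window_s`, smoothed by a moving average of
#' `ma_window_s`; samples below threshold form silence runs, and runs longer
#' than `max_silence_s` are excluded from speech (shorter dips are retained
#' inside a segment). Thresholding is relative: 40 dB below the envelope peak,
#' floored at an absolute minimum for all-silent input.
#'
#' @param utt an [utterance()].
#' @param window_s energy window length in seconds (default 0.030).
#' @param max_silence_s longest below-threshold run kept inside a speech
#'   segment, in seconds (default 0.006).
#' @param ma_window_s moving-average smoothing window in seconds (default 0.008).
#' @return object of class `speech_segments`: matrix of half-open
#'   `(start, end)` sample intervals (0-based), sorted and disjoint.
#' @export
detect_voice_activity <- function(utt, window_s = 0.030, max_silence_s = 0.006,
                                  ma_window_s = 0.008) {
  stopifnot(window_s > ma_window_s, ma_window_s > 0)
  x <- utt$samples
  sr <- utt$sampling_rate
  wl <- round(window_s * sr)
  empty <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (length(x) == 0) return(structure(empty, class = "speech_segments"))
  env <- moving_average(x^2, wl)
  env <- moving_average(env, round(ma_window_s * sr))
  thr <- max(max(env) * 1e-4, 1e-10)  # 40 dB below peak, absolute floor
  if (length(x) < wl) {               # single decision for the whole signal
    seg <- if (mean(x^2) > 1e-10) cbind(start = 0, end = length(x)) else empty
    return(structure(seg, class = "speech_segments"))
  }
  speech <- env >= thr
  # silence runs no longer than max_silence_s are absorbed into speech
  max_sil <- round(max_silence_s * sr)
  r <- rle(speech)
  short_sil <- !r$values & r$lengths <= max_sil
  r$values[short_sil] <- TRUE
  speech <- inverse.rle(r)
  iv <- runs_to_intervals(speech)
  structure(iv, class = "speech_segments")
}

#' Keep only the detected speech segments of an utterance
#' @param utt an [utterance()].
#' @param segments a `speech_segments` matrix from [detect_voice_activity()].
#' @return an [utterance()] with silent intervals excised.
#' @export
apply_segments <- function(utt, segments) {
  if (nrow(segments) == 0) {
    out <- replace_samples(utt, numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  idx <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    seq(segments[i, "start"] + 1L, segments[i, "end"])
  }))
  replace_samples(utt, utt$samples[idx])
}

#' Remove drifting (near-DC) noise with a zero-phase high-pass filter
#'
#' A first-order Butterworth high-pass is applied forward and backward
#' (zero phase by construction; the effective attenuation is squared).
#'
#' @param utt an [utterance()] or numeric waveform.
#' @param cutoff_hz cutoff frequency in Hz (default 40).
#' @return same type as the input with the drift component removed.
#' @export
remove_drift <- function(utt, cutoff_hz = 40) {
  x <- if (inherits(utt, "utterance")) utt$samples else as.numeric(utt)
  sr <- if (inherits(utt, "utterance")) utt$sampling_rate else 16000L
  if (length(x) > 1) {
    k <- tan(pi * cutoff_hz / sr)
    p <- (1 - k) / (1 + k)
    b0 <- (1 + p) / 2
    hp1 <- function(v) {
      z <- b0 * (v - c(0, v[-length(v)]))
      as.numeric(stats::filter(z, p, method = "recursive"))
    }
    x <- rev(hp1(rev(hp1(x))))
  }
  if (inherits(utt, "utterance")) replace_samples(utt, x) else x
}

#' ASV preprocessing chain: level gate, then voice activity detection
#' @param utt an [utterance()].
#' @param threshold_db level-gate threshold in dB.
#' @return a trimmed [utterance()].
#' @export
preprocess_asv <- function(utt, threshold_db = 30) {
  g <- remove_low_level(utt, threshold_db)
  if (isTRUE(attr(g, "empty"))) return(g)
  apply_segments(g, detect_voice_activity(g))
}
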