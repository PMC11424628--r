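# Source-filter synthesis of pathological-voice stand-ins. Excitation is a
# jittered/shimmered glottal impulse train plus aspiration noise; the vocal
# tract is a cascade of second-order resonators at the speaker's formants.
# Disorder labels switch on additional transforms: dysphonia raises jitter,
# shimmer and aspiration; dysarthria adds slow F0/energy drift and widens
# formant bandwidths; dysglossia perturbs formant centers (articulatory
# imprecision); CLP mixes in a low nasal resonance and widens oral bandwidths.

#' Construct an utterance object
#'
#' @param utterance_id,speaker_id character ids.
#' @param samples numeric waveform in `[-1, 1]`.
#' @param sampling_rate sampling rate in Hz (must be 16000).
#' @param labels named list carrying at least `group`, `gender`, `age_group`.
#' @return object of class `utterance`.
#' @export
utterance <- function(utterance_id, speaker_id, samples, sampling_rate = 16000L,
                      labels = list()) {
  if (sampling_rate != 16000L) stop("sampling_rate must be 16000 Hz")
  if (length(samples) && !all(is.finite(samples))) stop("samples must be finite")
  structure(list(utterance_id = as.character(utterance_id),
                 speaker_id = as.character(speaker_id),
                 samples = as.numeric(samples),
                 sampling_rate = as.integer(sampling_rate),
                 duration = length(samples) / sampling_rate,
                 labels = labels),
            class = "utterance")
}

#' @export
print.utterance <- function(x, ...) {
  cat(sprintf("<utterance %s (%s): %.2f s @ %d Hz>\n", x$utterance_id,
              x$speaker_id, x$duration, x$sampling_rate))
  invisible(x)
}

# Replace the waveform of an utterance, keeping ids and labels.
replace_samples <- function(utt, samples) {
  utterance(utt$utterance_id, utt$speaker_id, samples, utt$sampling_rate,
            utt$labels)
}

# Second-order resonator (two conjugate poles at frequency f, bandwidth bw).
resonate <- function(x, f, bw, sr) {
  r <- exp(-pi * bw / sr)
  theta <- 2 * pi * f / sr
  y <- stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive")
  as.numeric(y) * (1 - r)  # tame the per-stage gain; final level is normalized
}

#' Synthesize one utterance for a speaker profile
#'
#' Deterministic for a fixed `(profile, duration, seed)` triple. The waveform
#' contains at least one silent gap of `gap_s` seconds inserted at
#' mid-utterance so that voice-activity detection is exercised.
#'
#' @param profile a [speaker_profile()].
#' @param duration duration in seconds, in `[0.5, 30]`.
#' @param seed integer seed.
#' @param gap_s silent-gap duration in seconds (default 0.14, >= 0.1).
#' @return an [utterance()].
#' @export
synthesize_utterance <- function(profile, duration = 2, seed = 1, gap_s = 0.14) {
  if (duration < 0.5 || duration > 30) stop("duration must be in [0.5, 30] s")
  sr <- 16000L
  n <- round(duration * sr)
  mi <- profile$marker_intensity
  lab <- profile$disorder

  with_seed(derive_seed(seed, profile$speaker_id, round(duration * 1000)), {
    jitter_sd <- 0.004 + 0.045 * mi[["jitter"]]
    shimmer_sd <- 0.02 + 0.35 * mi[["shimmer"]]
    asp_level <- 0.02 + if (lab == "dysphonia") 0.30 * mean(mi[c("jitter", "shimmer")]) else 0

    # F0 contour: per-utterance session variability (~2%) and a mild,
    # zero-mean declination; dysarthria adds slow drift
    tt <- seq_len(n) / sr
    f0_utt <- profile$f0_base * exp(stats::rnorm(1, 0, 0.02))
    f0c <- f0_utt * (1 + 0.015 - 0.03 * tt / duration)
    drift_gain <- rep(1, n)
    if (lab == "dysarthria") {
      ph <- stats::runif(2, 0, 2 * pi)
      f0c <- f0c * (1 + 0.06 * mi[["formant_blur"]] * sin(2 * pi * 0.4 * tt + ph[1]))
      drift_gain <- 1 + 0.45 * mi[["formant_blur"]] * sin(2 * pi * 0.3 * tt + ph[2])
    }

    # glottal impulse train with cycle-length (jitter) and cycle-amplitude
    # (shimmer) perturbations
    excitation <- numeric(n)
    pos <- 1 + stats::runif(1, 0, sr / f0_utt)
    while (pos < n) {
      i <- round(pos)
      excitation[i] <- (1 + shimmer_sd * stats::rnorm(1)) * drift_gain[i]
      period <- sr / f0c[i] * (1 + jitter_sd * stats::rnorm(1))
      pos <- pos + max(period, sr / 500)
    }
    excitation <- excitation + asp_level * stats::rnorm(n)

    # vocal tract: per-utterance articulatory session variability (~2%),
    # per-label formant adjustments, then resonator cascade
    fmt <- profile$formants
    centers <- sort(fmt[, "center"] * exp(stats::rnorm(nrow(fmt), 0, 0.02)))
    bws <- fmt[, "bandwidth"]
    if (lab == "dysglossia") {
      centers <- centers * exp(stats::rnorm(length(centers), 0, 0.10 * mi[["formant_blur"]]))
      centers <- pmin(sort(centers), 7500)
    }
    if (lab %in% c("dysarthria", "clp")) {
      bws <- bws * (1 + 2.5 * mi[["formant_blur"]])
    }
    oral <- excitation
    for (k in seq_along(centers)) {
      oral <- resonate(oral, centers[k], bws[k], sr)
    }
    y <- oral / max(rms(oral), 1e-12)
    if (lab == "clp" && mi[["nasality"]] > 0) {
      nf <- stats::runif(1, 250, 450)
      nasal <- resonate(excitation, nf, 60, sr)
      w <- 0.6 * mi[["nasality"]]
      y <- (1 - w) * y + w * nasal / max(rms(nasal), 1e-12)
    }

    # remove the DC/rumble the all-positive pulse train pushes through the
    # resonators, then add a broadband noise floor ~ -50 dB re signal RMS
    y <- remove_drift(y, cutoff_hz = 60)
    y <- y + db_to_amp(-50) * rms(y) * stats::rnorm(n)

    # deterministic mid-utterance silent gap (>= 100 ms)
    gap_len <- round(max(gap_s, 0.1) * sr)
    g0 <- round(0.45 * n)
    y[g0:min(n, g0 + gap_len - 1)] <- 0

    y <- y / max(abs(y)) * 0.9
    y
  }) -> samples

  utterance(utterance_id = paste0(profile$speaker_id, "_u", seed),
            speaker_id = profile$speaker_id, samples = samples,
            labels = list(group = profile$disorder, gender = profile$gender,
                          age_group = profile$age_group))
}

#' Generate a synthetic corpus for a population
#'
#' @param population list of [speaker_profile()] objects.
#' @param utterances_per_speaker utterances per speaker (default 8, matching
#'   the per-speaker batch sampling used by the classifier).
#' @param duration_range `c(min, max)` utterance duration in seconds.
#' @param seed integer seed.
#' @return object of class `speech_corpus`: list with `utterances` (named list
#'   of [utterance()]) and `metadata` (one data.frame row per utterance).
#' @export
generate_corpus <- function(population, utterances_per_speaker = 8,
                            duration_range = c(2.0, 2.6), seed = 1) {
  if (utterances_per_speaker < 1) stop("utterances_per_speaker must be >= 1")
  utts <- list()
  meta <- list()
  for (p in population) {
    durs <- with_seed(derive_seed(seed, p$speaker_id, "durations"),
                      stats::runif(utterances_per_speaker, duration_range[1],
                                   duration_range[2]))
    for (j in seq_len(utterances_per_speaker)) {
      u <- synthesize_utterance(p, duration = durs[j],
                                seed = derive_seed(seed, j))
      u$utterance_id <- sprintf("%s_utt%02d", p$speaker_id, j)
      utts[[u$utterance_id]] <- u
      meta[[u$utterance_id]] <- data.frame(
        utterance_id = u$utterance_id, speaker_id = p$speaker_id,
        group = p$disorder, gender = p$gender, age_group = p$age_group,
        duration_s = u$duration, path = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(utterances = utts,
                 metadata = do.call(rbind, c(meta, list(make.row.names = FALSE)))),
            class = "speech_corpus")
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat(sprintf("<speech_corpus: %d utterances, %d speakers>\n",
              length(x$utterances), length(unique(x$metadata$speaker_id))))
  invisible(x)
}

#' Write a corpus to WAV files plus a metadata CSV
#' @param corpus a `speech_corpus`.
#' @param out_dir output directory (created if missing).
#' @return path of the metadata file, invisibly.
#' @export
write_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- corpus$metadata
  for (i in seq_len(nrow(md))) {
    u <- corpus$utterances[[md$utterance_id[i]]]
    p <- file.path(out_dir, paste0(u$utterance_id, ".wav"))
    write_wav(u$samples, p, u$sampling_rate)
    md$path[i] <- p
  }
  mp <- file.path(out_dir, "metadata.csv")
  utils::write.csv(md, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a corpus previously written by [write_corpus()]
#' @param dir directory containing `metadata.csv` and WAV files.
#' @return a `speech_corpus`.
#' @export
read_corpus <- function(dir) {
  md <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  utts <- list()
  for (i in seq_len(nrow(md))) {
    w <- read_wav(md$path[i])
    utts[[md$utterance_id[i]]] <- utterance(
      md$utterance_id[i], md$speaker_id[i], w$samples, w$sampling_rate,
      labels = list(group = md$group[i], gender = md$gender[i],
                    age_group = md$age_group[i]))
  }
  structure(list(utterances = utts, metadata = md), class = "speech_corpus")
}

# Apply a per-utterance transform to every utterance of a corpus.
transform_corpus <- function(corpus, fn) {
  out <- corpus
  out$utterances <- lapply(corpus$utterances, fn)
  out
}
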