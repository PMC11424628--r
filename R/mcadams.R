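# Signal-level anonymization via the McAdams transformation: frame-wise LPC
# analysis, exponentiation of the complex pole angles (phi -> phi^alpha, upper
# half-plane representative, radius preserved), and resynthesis of the
# residual through the transformed all-pole filter with overlap-add. Real
# poles are left untouched; alpha = 1 is the identity up to numerical error.

#' McAdams anonymizer configuration
#'
#' @param mode `"random"` (uniform coefficient draw, one per randomization
#'   unit, see `grain`) or `"fixed"`. `"random_per_speaker"` is accepted as an
#'   alias for `mode = "random", grain = "per_speaker"`.
#' @param random_low,random_high bounds of the uniform draw (defaults 0.75 and
#'   0.90).
#' @param fixed_value coefficient used in `"fixed"` mode.
#' @param grain randomization unit for corpus-level anonymization:
#'   `"per_utterance"` (default; each utterance draws its own coefficient, the
#'   grain of the published randomized-coefficient baseline) or
#'   `"per_speaker"` (all utterances of a speaker share one draw).
#' @param lpc_order LPC prediction order (default 20 at 16 kHz).
#' @param frame_s analysis frame length in seconds (default 0.020).
#' @param overlap frame overlap fraction in `[0, 0.9]` (default 0.5).
#' @param seed integer seed for the coefficient draws.
#' @return object of class `mcadams_config`.
#' @export
mcadams_config <- function(mode = c("random", "fixed", "random_per_speaker"),
                           random_low = 0.75, random_high = 0.90,
                           fixed_value = 0.8,
                           grain = c("per_utterance", "per_speaker"),
                           lpc_order = 20L,
                           frame_s = 0.020, overlap = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  grain <- match.arg(grain)
  if (mode == "random_per_speaker") {
    mode <- "random"
    grain <- "per_speaker"
  }
  if (!(random_low > 0 && random_low <= random_high && random_high <= 1)) {
    stop("need 0 < random_low <= random_high <= 1")
  }
  if (fixed_value <= 0 || fixed_value > 1.2) stop("fixed_value must be in (0, 1.2]")
  if (lpc_order < 8) stop("lpc_order must be >= 8")
  if (overlap < 0 || overlap > 0.9) stop("overlap must be in [0, 0.9]")
  structure(list(mode = mode, random_low = random_low,
                 random_high = random_high, fixed_value = fixed_value,
                 grain = grain, lpc_order = as.integer(lpc_order),
                 frame_s = frame_s, overlap = overlap,
                 seed = as.integer(seed)),
            class = "mcadams_config")
}

#' Draw the McAdams coefficient for a randomization unit
#'
#' In `random` mode the draw is uniform on `[random_low, random_high]` and is
#' a deterministic function of `(config$seed, id)`, so the same unit (speaker
#' or utterance, per `config$grain`) always receives the same coefficient
#' within a run. In `fixed` mode `fixed_value` is returned.
#'
#' @param config an [mcadams_config()].
#' @param speaker_id identifier of the randomization unit (a speaker id under
#'   `per_speaker` grain, an utterance id under `per_utterance`).
#' @return the coefficient (scalar).
#' @export
sample_coefficient <- function(config, speaker_id) {
  if (config$mode == "fixed") return(config$fixed_value)
  with_seed(derive_seed(config$seed, "mcadams", speaker_id),
            stats::runif(1, config$random_low, config$random_high))
}

# Levinson-Durbin recursion on an autocorrelation sequence; returns the
# prediction polynomial A = c(1, a_1, ..., a_p) of "1 - sum a_k z^-k" form
# arranged so that the residual is obtained by FIR filtering with A.
levinson <- function(r, p) {
  a <- numeric(p)
  e <- r[1]
  if (e <= 0) return(c(1, numeric(p)))
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[seq(i, 2)])
    k <- acc / e
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[seq(i - 1, 1)]
    a <- new_a
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  c(1, -a)
}

#' LPC analysis of a frame
#' @param frame numeric frame (windowing is the caller's responsibility).
#' @param order prediction order.
#' @return list with `a` (polynomial `c(1, a1, ..., ap)`), `poles` (complex
#'   roots of the prediction polynomial) and `residual`.
#' @export
lpc_analyze <- function(frame, order) {
  n <- length(frame)
  r <- vapply(0:order, function(k) sum(frame[seq_len(n - k)] * frame[seq_len(n - k) + k]),
              numeric(1))
  a <- levinson(r, order)
  poles <- tryCatch(polyroot(rev(a)), error = function(e) complex(0))
  # FIR inverse filtering with zero initial conditions, so that recursive
  # filtering of the residual through 1/A reconstructs the frame exactly
  pad <- c(numeric(order), frame)
  res <- as.numeric(stats::filter(pad, a, method = "convolution", sides = 1))
  residual <- res[order + seq_len(n)]
  list(a = a, poles = poles, residual = residual)
}

# Rebuild the real-coefficient prediction polynomial from its roots.
poly_from_roots <- function(roots) {
  coefs <- 1 + 0i
  for (r in roots) coefs <- c(coefs, 0) - c(0, coefs * r)
  Re(coefs)
}

#' Apply the McAdams pole-angle transformation
#'
#' For each complex pole, the upper-half-plane representative's angle `phi`
#' (radians in `(0, pi)`) is replaced by `phi^alpha` with the radius
#' preserved; the conjugate is mirrored. Real poles are returned unchanged.
#' Radii are clipped to `1 - 0.002` for stability (input radii above 1 are
#' clipped with a warning).
#'
#' @param poles complex vector of poles.
#' @param alpha McAdams coefficient (> 0).
#' @param imag_eps threshold on `|Im|` below which a pole counts as real.
#' @return complex vector of transformed poles.
#' @export
transform_poles <- function(poles, alpha, imag_eps = 1e-8) {
  stopifnot(alpha > 0)
  radius_max <- 0.998
  if (any(Mod(poles) > 1 + 1e-9)) {
    warning("input pole(s) with radius > 1 clipped to stability bound")
  }
  out <- poles
  for (i in seq_along(poles)) {
    z <- poles[i]
    if (abs(Im(z)) <= imag_eps) {
      if (Mod(z) > 1) out[i] <- sign(Re(z)) * radius_max
      next
    }
    r <- min(Mod(z), radius_max)
    phi <- abs(Arg(z))            # upper-half-plane representative
    phi_new <- phi^alpha
    out[i] <- complex(modulus = r, argument = sign(Arg(z)) * phi_new)
  }
  out
}

#' Anonymize an utterance with the McAdams method
#'
#' Frame-wise: Hann-window, LPC analysis at `lpc_order`, residual by inverse
#' filtering with the original coefficients, pole transformation with the
#' speaker's coefficient, resynthesis through the transformed all-pole filter,
#' and overlap-add. Output length equals input length and the peak level is
#' normalized to the input peak. Frames whose resynthesis is non-finite even
#' after radius clipping are passed through unmodified and counted in the
#' `n_passthrough` attribute.
#'
#' @param utt an [utterance()] at 16 kHz.
#' @param config an [mcadams_config()].
#' @param alpha optional explicit coefficient overriding the config draw.
#' @return anonymized [utterance()] with attributes `alpha` and
#'   `n_passthrough`.
#' @export
anonymize_mcadams <- function(utt, config = mcadams_config(), alpha = NULL) {
  stopifnot(inherits(utt, "utterance"), utt$sampling_rate == 16000L)
  if (is.null(alpha)) {
    id <- if (config$grain == "per_speaker") utt$speaker_id else utt$utterance_id
    alpha <- sample_coefficient(config, id)
  }
  x <- utt$samples
  sr <- utt$sampling_rate
  wl <- round(config$frame_s * sr)
  hop <- max(1L, round(wl * (1 - config$overlap)))
  if (length(x) < wl) return(structure(utt, alpha = alpha, n_passthrough = 0L))
  n_frames <- 1L + (length(x) - wl) %/% hop
  w <- hann_window(wl)
  y <- numeric(length(x))
  n_pass <- 0L
  for (k in seq_len(n_frames)) {
    idx <- (k - 1L) * hop + seq_len(wl)
    fr <- x[idx] * w
    if (sum(fr^2) < 1e-12) next
    an <- lpc_analyze(fr, config$lpc_order)
    new_a <- poly_from_roots(transform_poles(an$poles, alpha))
    synth <- as.numeric(stats::filter(an$residual, -new_a[-1],
                                      method = "recursive"))
    if (!all(is.finite(synth))) {
      synth <- fr
      n_pass <- n_pass + 1L
    }
    y[idx] <- y[idx] + synth
  }
  # tail not covered by a full frame: pass through
  covered <- (n_frames - 1L) * hop + wl
  if (covered < length(x)) y[(covered + 1L):length(x)] <- x[(covered + 1L):length(x)]
  peak <- max(abs(y))
  if (peak > 0) y <- y / peak * max(abs(x))
  structure(replace_samples(utt, y), alpha = alpha, n_passthrough = n_pass)
}

#' Anonymize every utterance of a corpus
#'
#' Coefficients are drawn per utterance or per speaker according to
#' `config$grain`.
#' @param corpus a `speech_corpus`.
#' @param config an [mcadams_config()].
#' @return the anonymized corpus; coefficients (named by randomization unit)
#'   in attribute `alphas`.
#' @export
anonymize_corpus_mcadams <- function(corpus, config = mcadams_config()) {
  units <- if (config$grain == "per_speaker") {
    unique(corpus$metadata$speaker_id)
  } else {
    corpus$metadata$utterance_id
  }
  alphas <- vapply(units, function(id) sample_coefficient(config, id), numeric(1))
  names(alphas) <- units
  out <- transform_corpus(corpus, function(u) {
    id <- if (config$grain == "per_speaker") u$speaker_id else u$utterance_id
    anonymize_mcadams(u, config, alpha = alphas[[id]])
  })
  attr(out, "alphas") <- alphas
  out
}
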