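#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit string hash (FNV-1a style), used to derive per-speaker
# substreams from a single run seed without consuming the global RNG.
hash_string <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647L)
}

# Combine a base seed with extra integer/string keys into a reproducible
# 32-bit seed (kept below 2^31 - 1).
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    kv <- if (is.character(k)) hash_string(k) else as.numeric(k)
    h <- (h * 69069 + kv + 1) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a local RNG seed, leaving the caller's RNG state untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Periodic Hann window: satisfies the constant-overlap-add property at 50%
# overlap, which the analysis/resynthesis paths rely on.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Frame a signal into a (frame_len x n_frames) matrix; n_frames follows the
# 1 + floor((L - frame_len)/hop) convention used throughout.
frame_signal <- function(x, frame_len, hop) {
  L <- length(x)
  if (L < frame_len) stop("signal shorter than one frame (", L, " < ", frame_len, ")")
  n_frames <- 1L + (L - frame_len) %/% hop
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  matrix(x[idx], nrow = frame_len)
}

# Centered moving average with edge shrinkage (partial windows at the ends).
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  cs <- cumsum(c(0, x))
  L <- length(x)
  half <- n %/% 2
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + (n - half - 1L), L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Run-length extraction of TRUE stretches as half-open [start, end) sample
# intervals (0-based starts are not used; R 1-based, end exclusive).
runs_to_intervals <- function(mask) {
  if (!any(mask)) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep] + 1L) - c(1L, 1L)
}

db_to_amp <- function(db) 10^(db / 20)
amp_to_db <- function(a, eps = 1e-12) 20 * log10(pmax(a, eps))

rms <- function(x) sqrt(mean(x^2))

# Half-up rounding (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
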