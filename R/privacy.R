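# Privacy evaluation: speaker embeddings, cosine-scored verification trials,
# and equal error rate at the FAR = FRR operating point. The default embedder
# is a deterministic statistics map over asv-preset log-Mel features (per-band
# temporal mean, standard deviation and mean absolute delta, each block
# centered, concatenated and length-normalized: 120 dimensions for 40 bands).
# A trainable embedder satisfying the same signature can be registered; the
# inversion-attack protocol fits one on pooled original + anonymized data.

#' Embed asv-preset log-Mel features into a fixed-length speaker vector
#'
#' @param feats a `logmel` matrix (asv preset: 40 bands) with at least 10
#'   frames.
#' @param utterance_id,speaker_id optional ids carried on the result.
#' @return object of class `speaker_embedding` (numeric vector with unit
#'   L2 norm and id attributes).
#' @export
embed <- function(feats, utterance_id = NA_character_, speaker_id = NA_character_) {
  v <- unclass(feats)
  if (nrow(v) < 10) stop("need at least 10 feature frames to embed")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  dmu <- colMeans(abs(diff(v)))
  # smooth across bands to emphasize the spectral envelope (vocal-tract
  # shape) over harmonic ripple, then center each block so cosine scoring
  # compares spectral shape rather than overall level
  blocks <- lapply(list(mu, sdv, dmu),
                   function(b) { s <- moving_average(b, 5); s - mean(s) })
  e <- unlist(blocks, use.names = FALSE)
  n <- sqrt(sum(e^2))
  if (n == 0) stop("degenerate (constant) features cannot be embedded")
  structure(e / n, class = "speaker_embedding",
            utterance_id = utterance_id, speaker_id = speaker_id)
}

#' Cosine similarity between two embeddings
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine_score <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("embedding dimensionality mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector has no cosine score")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Build a speaker-verification trial set
#'
#' Samples `n_pos` same-speaker and `n_neg` different-speaker utterance pairs
#' without replacement from a corpus metadata table. No utterance is paired
#' with itself.
#'
#' @param metadata data.frame with columns `utterance_id`, `speaker_id`.
#' @param n_pos,n_neg numbers of positive/negative trials.
#' @param seed integer seed.
#' @return data.frame of class `trial_set` with columns `enroll_id`,
#'   `test_id`, `same_speaker`.
#' @export
build_trials <- function(metadata, n_pos = 1000, n_neg = 1000, seed = 1) {
  sp <- split(metadata$utterance_id, metadata$speaker_id)
  if (n_pos > 0 && any(lengths(sp) < 2)) {
    short <- names(sp)[lengths(sp) < 2]
    stop("speakers with < 2 utterances cannot yield positive trials: ",
         paste(short, collapse = ", "))
  }
  pos <- do.call(rbind, lapply(sp, function(u) {
    if (length(u) < 2) return(NULL)
    t(utils::combn(u, 2))
  }))
  ids <- metadata$utterance_id
  spk <- metadata$speaker_id
  all_pairs <- utils::combn(seq_along(ids), 2)
  neg_mask <- spk[all_pairs[1, ]] != spk[all_pairs[2, ]]
  neg <- cbind(ids[all_pairs[1, neg_mask]], ids[all_pairs[2, neg_mask]])
  if (n_pos > nrow(pos)) stop("requested ", n_pos, " positive trials but only ",
                              nrow(pos), " distinct same-speaker pairs exist")
  if (n_neg > nrow(neg)) stop("requested ", n_neg, " negative trials but only ",
                              nrow(neg), " distinct cross-speaker pairs exist")
  with_seed(derive_seed(seed, "trials"), {
    pi <- sample.int(nrow(pos), n_pos)
    ni <- sample.int(nrow(neg), n_neg)
    out <- data.frame(enroll_id = c(pos[pi, 1], neg[ni, 1]),
                      test_id = c(pos[pi, 2], neg[ni, 2]),
                      same_speaker = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
                      stringsAsFactors = FALSE)
    class(out) <- c("trial_set", "data.frame")
    out
  })
}

#' Equal error rate of scored verification trials
#'
#' Sweeps thresholds over the sorted score set: `FAR(t)` is the fraction of
#' negative trials with score `>= t`, `FRR(t)` the fraction of positives with
#' score `< t`. The EER is the value at the FAR = FRR crossing, linearly
#' interpolated between the bracketing thresholds. If all scores are
#' identical the EER is defined as 0.5 with a warning.
#'
#' @param scores numeric trial scores.
#' @param same_speaker logical labels (TRUE = same speaker).
#' @return list of class `eer_result` with `eer`, `threshold`, `n_pos`,
#'   `n_neg`.
#' @export
compute_eer <- function(scores, same_speaker) {
  stopifnot(length(scores) == length(same_speaker))
  pos <- scores[same_speaker]
  neg <- scores[!same_speaker]
  if (length(pos) < 1 || length(neg) < 1) {
    stop("need at least one positive and one negative trial")
  }
  if (length(unique(scores)) == 1) {
    warning("all trial scores identical; EER defined as 0.5")
    return(structure(list(eer = 0.5, threshold = scores[1],
                          n_pos = length(pos), n_neg = length(neg)),
                     class = "eer_result"))
  }
  thr <- sort(unique(scores))
  thr <- c(thr, max(thr) + 1)  # threshold above all scores: FAR 0, FRR 1
  far <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  frr <- vapply(thr, function(t) mean(pos < t), numeric(1))
  d <- far - frr
  k <- which(d[-length(d)] >= 0 & d[-1] <= 0)[1]
  if (is.na(k)) k <- which.min(abs(d))
  if (d[k] == 0) {
    eer <- far[k]; t_eer <- thr[k]
  } else {
    # linear interpolation of both curves between bracketing thresholds
    u <- d[k] / (d[k] - d[k + 1])
    eer <- far[k] + u * (far[k + 1] - far[k])
    t_eer <- thr[k] + u * (thr[k + 1] - thr[k])
  }
  structure(list(eer = eer, threshold = t_eer,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "eer_result")
}

#' @export
print.eer_result <- function(x, ...) {
  cat(sprintf("<eer_result: EER %.2f%% at threshold %.4f (%d pos / %d neg)>\n",
              100 * x$eer, x$threshold, x$n_pos, x$n_neg))
  invisible(x)
}

# Compute embeddings for every utterance of a corpus (after the ASV
# preprocessing chain), with an optional custom embedder.
corpus_embeddings <- function(corpus, embedder = NULL, preprocess = TRUE) {
  lapply(corpus$utterances, function(u) {
    v <- if (preprocess) preprocess_asv(u) else u
    # preprocessing emptied (or nearly emptied) the utterance: fall back to
    # the raw audio so the embedding stays defined (>= 10 frames needed)
    if (length(v$samples) < 2000) v <- u
    f <- logmel(v, preset = "asv")
    if (is.null(embedder)) {
      embed(f, utterance_id = u$utterance_id, speaker_id = u$speaker_id)
    } else {
      embedder(f, utterance_id = u$utterance_id, speaker_id = u$speaker_id)
    }
  })
}

#' Score trials and compute the EER for a corpus
#'
#' @param corpus a `speech_corpus`.
#' @param trials a `trial_set` from [build_trials()]; built with defaults when
#'   NULL.
#' @param embedder optional embedder function `(feats, utterance_id,
#'   speaker_id) -> vector`; the deterministic default is used when NULL.
#' @param n_pos,n_neg,seed trial-set parameters when `trials` is NULL.
#' @return an `eer_result` with the scored trials in attribute `trials`.
#' @export
corpus_eer <- function(corpus, trials = NULL, embedder = NULL,
                       n_pos = 200, n_neg = 400, seed = 1) {
  if (is.null(trials)) {
    trials <- build_trials(corpus$metadata, n_pos, n_neg, seed)
  }
  embs <- corpus_embeddings(corpus, embedder)
  sc <- vapply(seq_len(nrow(trials)), function(i) {
    cosine_score(embs[[trials$enroll_id[i]]], embs[[trials$test_id[i]]])
  }, numeric(1))
  res <- compute_eer(sc, trials$same_speaker)
  trials$score <- sc
  attr(res, "trials") <- trials
  res
}

#' Fit an inverse-attack embedder on pooled original and anonymized audio
#'
#' Implements the inversion-attack protocol: anonymized utterances are treated
#' as authentic utterances of their true speakers, and a speaker-conditional
#' linear transform (regularized linear discriminant projection) is fitted on
#' the pooled base embeddings. The returned embedder projects base embeddings
#' into the discriminant space, which partially undoes the anonymization when
#' used for verification scoring.
#'
#' @param original_corpus,anonymized_corpus `speech_corpus` objects over the
#'   same speaker set (the anonymized corpus derived from the same utterances).
#' @param n_components dimensionality of the projection (default
#'   `min(n_speakers - 1, 40)`).
#' @param lambda ridge regularization added to the within-class scatter.
#' @return an embedder function usable with [corpus_eer()].
#' @export
train_inverse_asv <- function(original_corpus, anonymized_corpus,
                              n_components = NULL, lambda = 1e-3) {
  so <- sort(unique(original_corpus$metadata$speaker_id))
  sa <- sort(unique(anonymized_corpus$metadata$speaker_id))
  if (!identical(so, sa)) stop("speaker sets of the two corpora differ")
  pool <- c(corpus_embeddings(original_corpus),
            corpus_embeddings(anonymized_corpus))
  X <- do.call(rbind, lapply(pool, as.numeric))
  y <- vapply(pool, function(e) attr(e, "speaker_id"), character(1))
  mu <- colMeans(X)
  d <- ncol(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (s in unique(y)) {
    Xi <- X[y == s, , drop = FALSE]
    mi <- colMeans(Xi)
    Xi_c <- sweep(Xi, 2, mi)
    Sw <- Sw + crossprod(Xi_c)
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  Sw <- Sw / nrow(X) + lambda * diag(d)
  M <- solve(Sw, Sb)
  ev <- eigen(M)
  k <- n_components %||% min(length(unique(y)) - 1L, 40L)
  W <- Re(ev$vectors[, seq_len(k), drop = FALSE])
  function(feats, utterance_id = NA_character_, speaker_id = NA_character_) {
    base <- as.numeric(embed(feats))
    v <- drop(crossprod(W, base - mu))
    n <- sqrt(sum(v^2))
    structure(v / max(n, 1e-12), class = "speaker_embedding",
              utterance_id = utterance_id, speaker_id = speaker_id)
  }
}

#' Write / read trial lists as delimited text
#'
#' Columns `enroll_id`, `test_id`, `label` (`target`/`nontarget`) and
#' optionally `score`, compatible with common ASV scoring conventions.
#' @param trials a `trial_set` (with optional `score` column).
#' @param path file path.
#' @return `path` (write) or a `trial_set` (read).
#' @export
write_trials <- function(trials, path) {
  out <- data.frame(enroll_id = trials$enroll_id, test_id = trials$test_id,
                    label = ifelse(trials$same_speaker, "target", "nontarget"))
  if (!is.null(trials$score)) out$score <- trials$score
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(enroll_id = x$enroll_id, test_id = x$test_id,
                    same_speaker = x$label == "target",
                    stringsAsFactors = FALSE)
  if (!is.null(x$score)) out$score <- x$score
  class(out) <- c("trial_set", "data.frame")
  out
}
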