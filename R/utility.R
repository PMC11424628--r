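# Disorder-detection utility evaluation. The classification front end crops
# 180 frames (~3 s) of clf-preset log-Mel features per draw, summarizes each
# crop by per-band mean and standard deviation, and scores it with a small
# trainable regularized logistic model (binomial or multinomial). The
# training-loop conventions of the emulated pipeline are retained where they
# matter for evaluation: 8 utterances per speaker per draw, 50 paired test
# repetitions, speaker-level aggregation by mean utterance probability, and a
# 0.5 operating threshold for accuracy/sensitivity/specificity.

#' Classifier specification
#'
#' @param crop_frames frames per crop (default 180, about 3 s at a 10 ms hop).
#' @param utterances_per_speaker utterances drawn per speaker per evaluation
#'   repeat (default 8, with replacement).
#' @param n_crops_train training crops per utterance.
#' @param lambda ridge penalty of the logistic model.
#' @param seed integer seed.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(crop_frames = 180L, utterances_per_speaker = 8L,
                            n_crops_train = 2L, lambda = 1e-2, seed = 1L) {
  structure(list(crop_frames = as.integer(crop_frames),
                 utterances_per_speaker = as.integer(utterances_per_speaker),
                 n_crops_train = as.integer(n_crops_train),
                 lambda = lambda, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' clf-preset features for every utterance of a corpus
#'
#' Applies drift removal then the `"clf"` log-Mel preset.
#' @param corpus a `speech_corpus`.
#' @return named list of `logmel` matrices.
#' @export
corpus_features <- function(corpus) {
  lapply(corpus$utterances, function(u) logmel(remove_drift(u), preset = "clf"))
}

# Crop `len` frames starting at `start` (tiling short inputs), then summarize
# by per-band mean and standard deviation.
crop_summary <- function(feats, start, len) {
  v <- unclass(feats)
  if (nrow(v) < len) {
    reps <- ceiling(len / nrow(v))
    v <- do.call(rbind, rep(list(v), reps))
  }
  start <- min(max(1L, start), nrow(v) - len + 1L)
  v <- v[start + seq_len(len) - 1L, , drop = FALSE]
  c(colMeans(v), apply(v, 2, stats::sd))
}

crop_start_from_frac <- function(feats, frac, len) {
  n <- nrow(unclass(feats))
  span <- max(1L, n - len + 1L)
  1L + floor(frac * (span - 1e-9))
}

#' Fit the default disorder classifier
#'
#' Trains a class-weighted ridge logistic model (binomial for two classes,
#' multinomial otherwise) on seeded random crops of the training features.
#' Deterministic under `spec$seed`.
#'
#' @param features named list of `logmel` matrices (see [corpus_features()]).
#' @param labels factor of class labels, one per feature entry (same order).
#' @param spec a [classifier_spec()].
#' @return object of class `speech_classifier`; call it on features via
#'   [predict_proba()].
#' @export
fit_classifier <- function(features, labels, spec = classifier_spec()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("training set contains a single class")
  rows <- list()
  ys <- character(0)
  with_seed(derive_seed(spec$seed, "fit"), {
    for (i in seq_along(features)) {
      for (j in seq_len(spec$n_crops_train)) {
        frac <- stats::runif(1)
        st <- crop_start_from_frac(features[[i]], frac, spec$crop_frames)
        rows[[length(rows) + 1L]] <- crop_summary(features[[i]], st, spec$crop_frames)
        ys <- c(ys, as.character(labels[i]))
      }
    }
  })
  X <- do.call(rbind, rows)
  y <- factor(ys, levels = levels(labels))
  w <- 1 / table(y)[y]          # class-weighted loss
  w <- as.numeric(w) * length(y) / sum(as.numeric(w))
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- glmnet::glmnet(X, y, family = fam, alpha = 0,
                        lambda = spec$lambda, weights = w,
                        standardize = TRUE)
  structure(list(fit = fit, classes = levels(y), spec = spec,
                 family = fam), class = "speech_classifier")
}

#' Class probabilities for one crop-summary vector or feature matrix
#' @param clf a `speech_classifier`.
#' @param x a crop-summary vector or a matrix of them (rows = crops).
#' @return matrix of class probabilities (rows sum to 1).
#' @export
predict_proba <- function(clf, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (clf$family == "binomial") {
    p1 <- drop(stats::predict(clf$fit, x, type = "response"))
    out <- cbind(1 - p1, p1)
  } else {
    out <- stats::predict(clf$fit, x, type = "response")[, , 1]
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  }
  colnames(out) <- clf$classes
  out
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Equals the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted 0.5.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive) or two-level factor whose second
#'   level is positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (!is.logical(labels)) labels <- as.factor(labels) == levels(as.factor(labels))[2]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Two-tailed unpaired t-test (Welch by default)
#' @param sample_a,sample_b numeric samples, each of length >= 2.
#' @param var_equal use the pooled-variance (Student) form instead of Welch.
#' @return list with `t`, `p`, `significant` (at 0.05).
#' @export
ttest_unpaired <- function(sample_a, sample_b, var_equal = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) stop("each sample needs n >= 2")
  if (stats::var(c(sample_a, sample_b)) == 0) stop("degenerate: zero variance")
  ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value, significant = ht$p.value < 0.05)
}

#' Pearson correlation between privacy (EER) and utility (AUROC) vectors
#' @param eer_values,auroc_values equal-length numeric vectors (n >= 3).
#' @return list with `r` and two-tailed `p`.
#' @export
pearson_tradeoff <- function(eer_values, auroc_values) {
  if (length(eer_values) != length(auroc_values) || length(eer_values) < 3) {
    stop("need equal lengths >= 3")
  }
  if (stats::var(eer_values) == 0 || stats::var(auroc_values) == 0) {
    stop("zero variance in one input")
  }
  ct <- stats::cor.test(eer_values, auroc_values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

binary_metrics <- function(scores, truth, threshold = 0.5) {
  pred <- scores >= threshold
  c(auroc = auroc(scores, truth),
    accuracy = mean(pred == truth),
    sensitivity = if (any(truth)) mean(pred[truth]) else NA_real_,
    specificity = if (any(!truth)) mean(!pred[!truth]) else NA_real_)
}

#' Repeated paired evaluation of a classifier on a test corpus
#'
#' Per repeat: draw `utterances_per_speaker` utterances per speaker (with
#' replacement) and one crop per utterance, score the crops, aggregate to
#' speaker level by mean positive-class probability, and compute AUROC,
#' accuracy, sensitivity and specificity at threshold 0.5. The draw sequence
#' depends only on `(seed, speaker ids, utterance counts)` via crop fractions,
#' so running the same seed on an anonymized version of the corpus consumes
#' identical draws (paired evaluation); draws are logged in the report.
#'
#' @param clf a `speech_classifier` (binary).
#' @param features named list of clf-preset `logmel` matrices for the test
#'   utterances.
#' @param metadata metadata rows for the same utterances.
#' @param positive_class label counted as positive; by default every
#'   non-`"control"` group.
#' @param n_repeats number of repeats (default 50).
#' @param seed integer seed.
#' @return object of class `eval_report`: per-repeat metric matrix, summary
#'   mean and sd, speaker scores of the last repeat, and the pairing log.
#' @export
evaluate_repeated <- function(clf, features, metadata, positive_class = NULL,
                              n_repeats = 50, seed = 1) {
  stopifnot(nrow(metadata) == length(features))
  truth_utt <- if (is.null(positive_class)) {
    metadata$group != "control"
  } else {
    metadata$group %in% positive_class
  }
  speakers <- sort(unique(metadata$speaker_id))
  truth_spk <- vapply(speakers, function(s) truth_utt[metadata$speaker_id == s][1],
                      logical(1))
  if (all(truth_spk) || !any(truth_spk)) stop("test set misses one class; AUROC undefined")
  spec <- clf$spec
  utt_by_spk <- split(seq_len(nrow(metadata)), metadata$speaker_id)[speakers]
  metrics <- matrix(NA_real_, n_repeats, 4,
                    dimnames = list(NULL, c("auroc", "accuracy", "sensitivity",
                                            "specificity")))
  draw_log <- vector("list", n_repeats)
  spk_scores <- NULL
  for (r in seq_len(n_repeats)) {
    draws <- with_seed(derive_seed(seed, "repeat", r), {
      lapply(speakers, function(s) {
        idx <- utt_by_spk[[s]]
        # index draws via uniform fractions so the sequence pairs across
        # conditions with equal utterance counts
        u_frac <- stats::runif(spec$utterances_per_speaker)
        c_frac <- stats::runif(spec$utterances_per_speaker)
        list(utt = idx[1L + floor(u_frac * length(idx))], crop_frac = c_frac)
      })
    })
    names(draws) <- speakers
    scores <- vapply(speakers, function(s) {
      d <- draws[[s]]
      probs <- vapply(seq_along(d$utt), function(j) {
        f <- features[[d$utt[j]]]
        st <- crop_start_from_frac(f, d$crop_frac[j], spec$crop_frames)
        predict_proba(clf, crop_summary(f, st, spec$crop_frames))[1, 2]
      }, numeric(1))
      mean(probs)
    }, numeric(1))
    metrics[r, ] <- binary_metrics(scores, truth_spk)
    draw_log[[r]] <- draws
    spk_scores <- scores
  }
  structure(list(metrics = metrics,
                 summary = rbind(mean = colMeans(metrics),
                                 sd = apply(metrics, 2, stats::sd)),
                 speakers = speakers, truth = truth_spk,
                 last_scores = spk_scores, draws = draw_log,
                 n_repeats = n_repeats, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<eval_report over %d repeats: AUROC %.3f+-%.3f, acc %.3f+-%.3f>\n",
              x$n_repeats, s["mean", "auroc"], s["sd", "auroc"],
              s["mean", "accuracy"], s["sd", "accuracy"]))
  invisible(x)
}

#' Demographic fairness report with statistical parity difference
#'
#' PtD = accuracy(minority) - accuracy(majority), where the minority is the
#' smaller test subgroup (ties broken alphabetically). Positive values favor
#' the minority subgroup.
#'
#' @param predictions data.frame with columns `speaker_id`, `score` (positive
#'   class probability) and `truth` (logical).
#' @param metadata data.frame mapping `speaker_id` to `gender` and
#'   `age_group`.
#' @param attribute `"gender"` or `"age_group"`.
#' @param threshold decision threshold (default 0.5).
#' @return object of class `fairness_report` with per-subgroup metrics and
#'   `ptd`.
#' @export
fairness_report <- function(predictions, metadata, attribute = c("gender", "age_group"),
                            threshold = 0.5) {
  attribute <- match.arg(attribute)
  md <- metadata[!duplicated(metadata$speaker_id), ]
  sub <- md[[attribute]][match(predictions$speaker_id, md$speaker_id)]
  levs <- sort(unique(sub))
  if (length(levs) < 2) stop("both subgroup levels must be present")
  acc <- vapply(levs, function(l) {
    i <- sub == l
    mean((predictions$score[i] >= threshold) == predictions$truth[i])
  }, numeric(1))
  n <- vapply(levs, function(l) sum(sub == l), numeric(1))
  minority <- levs[order(n, levs)][1]
  majority <- setdiff(levs, minority)[1]
  structure(list(attribute = attribute, subgroup_n = stats::setNames(n, levs),
                 subgroup_accuracy = stats::setNames(acc, levs),
                 minority = minority, majority = majority,
                 ptd = unname(acc[minority] - acc[majority])),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("<fairness_report (%s): PtD %+0.3f (minority %s)>\n",
              x$attribute, x$ptd, x$minority))
  invisible(x)
}
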