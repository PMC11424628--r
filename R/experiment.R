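# End-to-end experiment orchestration: speaker-disjoint 70/30 splits with
# patient:control ratio caps, anonymization conditions applied to both train
# and test audio, paired repeated utility evaluation, privacy trials on the
# test split, coefficient sweeps, pooled patient-vs-control and multiclass
# tasks, and the inversion attack. All randomness flows from the config seed.

#' Experiment configuration
#'
#' @param train_fraction speaker fraction allocated to training (default 0.70).
#' @param patient_cap patients capped at `patient_cap` x controls for adult
#'   tasks (default 2).
#' @param control_cap controls capped at `control_cap` x patients for child
#'   tasks (default 1.5).
#' @param sweep_alphas fixed-coefficient sweep grid (default 0.5-1.0 step 0.1).
#' @param multiclass_alphas multiclass sweep grid (default 0.7-1.0 step 0.05).
#' @param n_repeats paired evaluation repeats (default 50).
#' @param n_pos,n_neg verification trial counts.
#' @param seed master seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(train_fraction = 0.70, patient_cap = 2,
                              control_cap = 1.5,
                              sweep_alphas = seq(0.5, 1.0, by = 0.1),
                              multiclass_alphas = seq(0.7, 1.0, by = 0.05),
                              n_repeats = 50, n_pos = 200, n_neg = 400,
                              seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0, 1)")
  if (any(sweep_alphas <= 0 | sweep_alphas > 1.2)) stop("sweep alphas must be in (0, 1.2]")
  structure(list(train_fraction = train_fraction, patient_cap = patient_cap,
                 control_cap = control_cap, sweep_alphas = sweep_alphas,
                 multiclass_alphas = multiclass_alphas,
                 n_repeats = n_repeats, n_pos = n_pos, n_neg = n_neg,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Speaker-disjoint train/test split with ratio caps
#'
#' Ratio caps are applied by seeded subsampling before the split: patients are
#' capped at `patient_cap` x controls (adult-style tasks) and controls at
#' `control_cap` x patients (child-style tasks). The split is stratified by
#' group and deterministic under the seed.
#'
#' @param metadata utterance- or speaker-level metadata with `speaker_id` and
#'   `group`.
#' @param config an [experiment_config()].
#' @param seed split seed (defaults to the config seed so the same split is
#'   reused across conditions).
#' @return list with `train` and `test` speaker-id vectors.
#' @export
split_speakers <- function(metadata, config = experiment_config(),
                           seed = config$seed) {
  spk <- metadata[!duplicated(metadata$speaker_id), c("speaker_id", "group")]
  with_seed(derive_seed(seed, "split"), {
    controls <- spk$speaker_id[spk$group == "control"]
    patients <- spk$speaker_id[spk$group != "control"]
    if (length(patients) > config$patient_cap * length(controls) &&
        length(controls) > 0) {
      patients <- sample(patients, floor(config$patient_cap * length(controls)))
    }
    if (length(controls) > config$control_cap * length(patients) &&
        length(patients) > 0) {
      controls <- sample(controls, floor(config$control_cap * length(patients)))
    }
    kept <- spk[spk$speaker_id %in% c(controls, patients), ]
    train <- character(0); test <- character(0)
    for (g in unique(kept$group)) {
      ids <- sort(kept$speaker_id[kept$group == g])
      if (length(ids) < 2) stop("group ", g, " too small to split")
      n_train <- round(config$train_fraction * length(ids))
      n_train <- min(max(n_train, 1L), length(ids) - 1L)
      tr <- sample(ids, n_train)
      train <- c(train, tr)
      test <- c(test, setdiff(ids, tr))
    }
    list(train = sort(train), test = sort(test))
  })
}

# Cap requested trial counts at what the metadata can supply.
trial_caps <- function(metadata, n_pos, n_neg) {
  cnt <- table(metadata$speaker_id)
  tot <- sum(cnt)
  list(n_pos = min(n_pos, sum(choose(cnt, 2))),
       n_neg = min(n_neg, (tot * (tot - 1)) %/% 2 - sum(choose(cnt, 2))))
}

#' Restrict a corpus to a set of speakers
#' @param corpus a `speech_corpus`.
#' @param speaker_ids speaker ids to keep.
#' @return the restricted `speech_corpus`.
#' @export
subset_corpus <- function(corpus, speaker_ids) {
  keep <- corpus$metadata$speaker_id %in% speaker_ids
  structure(list(utterances = corpus$utterances[corpus$metadata$utterance_id[keep]],
                 metadata = corpus$metadata[keep, , drop = FALSE]),
            class = "speech_corpus")
}

#' Apply a named anonymization condition to a corpus
#'
#' Conditions: `original` (identity), `mcadams_random` (uniform coefficient
#' in `[0.75, 0.90]`, drawn at the config grain, per utterance by default),
#' `mcadams_fixed` (fixed `alpha`),
#' `pitch_shift` (randomized per-speaker shift), `resynth_only` (mel-domain
#' analysis/resynthesis with zero shift).
#'
#' @param corpus a `speech_corpus`.
#' @param condition condition name.
#' @param config an [experiment_config()].
#' @param alpha fixed McAdams coefficient for `mcadams_fixed`.
#' @return transformed corpus.
#' @export
apply_condition <- function(corpus,
                            condition = c("original", "mcadams_random",
                                          "mcadams_fixed", "pitch_shift",
                                          "resynth_only"),
                            config = experiment_config(), alpha = NULL) {
  condition <- match.arg(condition)
  switch(condition,
         original = corpus,
         mcadams_random = anonymize_corpus_mcadams(
           corpus, mcadams_config(mode = "random", seed = config$seed)),
         mcadams_fixed = {
           if (is.null(alpha)) stop("mcadams_fixed requires alpha")
           anonymize_corpus_mcadams(
             corpus, mcadams_config(mode = "fixed", fixed_value = alpha,
                                    seed = config$seed))
         },
         pitch_shift = anonymize_corpus_pitch(
           corpus, pitch_shift_config(seed = config$seed)),
         resynth_only = resynth_only_corpus(corpus))
}

#' Run one anonymization condition end to end
#'
#' Splits the speakers (same split for every condition under one config),
#' applies the condition's transform to both train and test audio, fits the
#' disorder classifier, runs the paired repeated utility evaluation, and
#' computes the verification EER on the test split.
#'
#' @param corpus a `speech_corpus`.
#' @param condition see [apply_condition()].
#' @param config an [experiment_config()].
#' @param alpha fixed coefficient for `mcadams_fixed`.
#' @param split optional precomputed split (from [split_speakers()]).
#' @param embedder optional embedder for the privacy trials (e.g. an
#'   inverse-attack embedder).
#' @return list of class `condition_result` with `condition`, `report`
#'   (an `eval_report`), `eer` (an `eer_result`), and `split`.
#' @export
run_condition <- function(corpus, condition, config = experiment_config(),
                          alpha = NULL, split = NULL, embedder = NULL) {
  if (is.null(split)) split <- split_speakers(corpus$metadata, config)
  anon <- apply_condition(corpus, condition, config, alpha)
  train_c <- subset_corpus(anon, split$train)
  test_c <- subset_corpus(anon, split$test)
  feats_tr <- corpus_features(train_c)
  labels_tr <- factor(ifelse(train_c$metadata$group == "control", "control", "patient"),
                      levels = c("control", "patient"))
  clf <- fit_classifier(feats_tr, labels_tr,
                        classifier_spec(seed = derive_seed(config$seed, condition)))
  feats_te <- corpus_features(test_c)
  report <- evaluate_repeated(clf, feats_te, test_c$metadata,
                              n_repeats = config$n_repeats, seed = config$seed)
  caps <- trial_caps(test_c$metadata, config$n_pos, config$n_neg)
  eer <- corpus_eer(test_c, embedder = embedder, n_pos = caps$n_pos,
                    n_neg = caps$n_neg, seed = config$seed)
  structure(list(condition = condition, alpha = alpha, report = report,
                 eer = eer, split = split),
            class = "condition_result")
}

#' Fixed-coefficient sweep with privacy-utility correlation
#'
#' Runs `mcadams_fixed` for each coefficient in `config$sweep_alphas` on a
#' shared split and reports the tradeoff curve plus the Pearson correlation
#' between EER and AUROC across the grid.
#'
#' @param corpus a `speech_corpus`.
#' @param config an [experiment_config()].
#' @return list with `table` (alpha, eer, auroc, accuracy, sensitivity,
#'   specificity) and `pearson` (list `r`, `p`).
#' @export
run_sweep <- function(corpus, config = experiment_config()) {
  if (length(config$sweep_alphas) < 3) stop("need >= 3 sweep values")
  split <- split_speakers(corpus$metadata, config)
  rows <- lapply(config$sweep_alphas, function(a) {
    res <- run_condition(corpus, "mcadams_fixed", config, alpha = a,
                         split = split)
    s <- res$report$summary["mean", ]
    data.frame(alpha = a, eer = res$eer$eer, auroc = s[["auroc"]],
               accuracy = s[["accuracy"]], sensitivity = s[["sensitivity"]],
               specificity = s[["specificity"]])
  })
  tab <- do.call(rbind, rows)
  list(table = tab, pearson = pearson_tradeoff(tab$eer, tab$auroc))
}

#' Pooled patient-vs-control run with subgroup EERs
#'
#' Consolidates all disorder groups into one patient set, runs the given
#' condition, and reports EERs separately for the patient subset, the control
#' subset, and all test speakers.
#'
#' @param corpus a `speech_corpus` containing >= 2 disorder classes.
#' @param config an [experiment_config()].
#' @param condition condition name (default `mcadams_random`).
#' @return list with `report`, `eer_patients`, `eer_controls`, `eer_all`.
#' @export
run_pooled <- function(corpus, config = experiment_config(),
                       condition = "mcadams_random") {
  groups <- unique(corpus$metadata$group)
  if (length(setdiff(groups, "control")) < 1 || !"control" %in% groups) {
    stop("pooled task needs controls and at least one disorder group")
  }
  res <- run_condition(corpus, condition, config)
  anon <- apply_condition(corpus, condition, config)
  test_c <- subset_corpus(anon, res$split$test)
  md <- test_c$metadata
  eer_for <- function(ids) {
    sub <- subset_corpus(test_c, ids)
    caps <- trial_caps(sub$metadata, config$n_pos, config$n_neg)
    corpus_eer(sub, n_pos = caps$n_pos, n_neg = caps$n_neg, seed = config$seed)
  }
  list(report = res$report,
       eer_patients = eer_for(unique(md$speaker_id[md$group != "control"])),
       eer_controls = eer_for(unique(md$speaker_id[md$group == "control"])),
       eer_all = res$eer)
}

# One-vs-rest multiclass evaluation at speaker level.
evaluate_multiclass <- function(clf, features, metadata, n_repeats = 10, seed = 1) {
  speakers <- sort(unique(metadata$speaker_id))
  truth <- vapply(speakers, function(s) metadata$group[metadata$speaker_id == s][1],
                  character(1))
  spec <- clf$spec
  utt_by_spk <- split(seq_len(nrow(metadata)), metadata$speaker_id)[speakers]
  per_class <- matrix(NA_real_, n_repeats, length(clf$classes),
                      dimnames = list(NULL, clf$classes))
  for (r in seq_len(n_repeats)) {
    draws <- with_seed(derive_seed(seed, "mc", r), {
      lapply(speakers, function(s) {
        idx <- utt_by_spk[[s]]
        u_frac <- stats::runif(spec$utterances_per_speaker)
        c_frac <- stats::runif(spec$utterances_per_speaker)
        list(utt = idx[1L + floor(u_frac * length(idx))], crop_frac = c_frac)
      })
    })
    prob <- t(vapply(seq_along(speakers), function(si) {
      d <- draws[[si]]
      p <- vapply(seq_along(d$utt), function(j) {
        f <- features[[d$utt[j]]]
        st <- crop_start_from_frac(f, d$crop_frac[j], spec$crop_frames)
        predict_proba(clf, crop_summary(f, st, spec$crop_frames))[1, ]
      }, numeric(length(clf$classes)))
      rowMeans(p)
    }, numeric(length(clf$classes))))
    for (cl in clf$classes) {
      per_class[r, cl] <- auroc(prob[, cl], truth == cl)
    }
  }
  per_class
}

#' Multiclass (5-group) task with equal-n subsampling and coefficient sweep
#'
#' Speaker counts are equalized to the smallest class by seeded subsampling,
#' the equalized corpus is split once, and for each coefficient in
#' `config$multiclass_alphas` a multinomial classifier is trained and
#' evaluated one-vs-rest per class.
#'
#' @param corpus a `speech_corpus` containing all five groups.
#' @param config an [experiment_config()].
#' @param alphas coefficient grid (defaults to `config$multiclass_alphas`).
#' @param n_repeats evaluation repeats per coefficient.
#' @return list with `class_counts`, `results` (one per coefficient: alpha,
#'   per-class AUROC means) and the `split`.
#' @export
run_multiclass <- function(corpus, config = experiment_config(),
                           alphas = config$multiclass_alphas, n_repeats = 5) {
  md <- corpus$metadata
  groups <- sort(unique(md$group))
  if (!setequal(groups, DISORDER_LEVELS)) {
    stop("multiclass task needs all five groups; missing: ",
         paste(setdiff(DISORDER_LEVELS, groups), collapse = ", "))
  }
  spk <- md[!duplicated(md$speaker_id), ]
  n_min <- min(table(spk$group))
  keep <- with_seed(derive_seed(config$seed, "equalize"), {
    unlist(lapply(groups, function(g) {
      ids <- sort(spk$speaker_id[spk$group == g])
      sample(ids, n_min)
    }))
  })
  eq <- subset_corpus(corpus, keep)
  # classes are already equalized: ratio caps must not resubsample
  cfg_nocap <- config
  cfg_nocap$patient_cap <- Inf
  cfg_nocap$control_cap <- Inf
  split <- split_speakers(eq$metadata, cfg_nocap)
  results <- lapply(alphas, function(a) {
    anon <- if (a >= 1) eq else {
      anonymize_corpus_mcadams(eq, mcadams_config(mode = "fixed",
                                                  fixed_value = a,
                                                  seed = config$seed))
    }
    train_c <- subset_corpus(anon, split$train)
    test_c <- subset_corpus(anon, split$test)
    clf <- fit_classifier(corpus_features(train_c),
                          factor(train_c$metadata$group, levels = groups),
                          classifier_spec(seed = derive_seed(config$seed, "mc", round(100 * a))))
    pc <- evaluate_multiclass(clf, corpus_features(test_c), test_c$metadata,
                              n_repeats = n_repeats, seed = config$seed)
    list(alpha = a, auroc_per_class = colMeans(pc))
  })
  list(class_counts = table(factor(spk$group[spk$speaker_id %in% keep],
                                   levels = groups)),
       results = results, split = split)
}

#' Inversion-attack evaluation
#'
#' Fits the inverse embedder on pooled original + anonymized audio
#' ([train_inverse_asv()]) and reports naive and inverse EERs on both
#' versions of the test split.
#'
#' @param corpus a `speech_corpus`.
#' @param config an [experiment_config()].
#' @param condition anonymization condition attacked (default
#'   `mcadams_random`).
#' @return list with `eer_naive_original`, `eer_naive_anonymized`,
#'   `eer_inverse_original`, `eer_inverse_anonymized`.
#' @export
run_inversion_attack <- function(corpus, config = experiment_config(),
                                 condition = "mcadams_random") {
  split <- split_speakers(corpus$metadata, config)
  anon <- apply_condition(corpus, condition, config)
  test_o <- subset_corpus(corpus, split$test)
  test_a <- subset_corpus(anon, split$test)
  caps <- trial_caps(test_o$metadata, config$n_pos, config$n_neg)
  inv <- train_inverse_asv(subset_corpus(corpus, split$train),
                           subset_corpus(anon, split$train))
  eer_of <- function(corp, emb = NULL) {
    corpus_eer(corp, embedder = emb, n_pos = caps$n_pos, n_neg = caps$n_neg,
               seed = config$seed)
  }
  list(
    eer_naive_original = eer_of(test_o),
    eer_naive_anonymized = eer_of(test_a),
    eer_inverse_original = eer_of(test_o, inv),
    eer_inverse_anonymized = eer_of(test_a, inv))
}
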