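test_that("auroc matches closed forms and the concordance oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auroc(c(0.9, 0.4, 0.7, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)), "both classes")
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(4:25, 1)
      sc <- round(runif(n), 2)  # induce ties
      lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      expect_equal(auroc(sc, lab), oracle_auroc(sc, lab), tolerance = 1e-12)
    }
  })
})

test_that("ttest_unpaired matches the textbook formula and symmetry", {
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- ttest_unpaired(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$p, 1e-6)
  expect_true(far$significant)
  a <- c(1.2, 3.1, 2.0, 4.4); b <- c(2.5, 2.9, 3.8)
  # Welch statistic, explicit formula
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  res <- ttest_unpaired(a, b)
  expect_equal(res$t, tw, tolerance = 1e-12)
  swapped <- ttest_unpaired(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_error(ttest_unpaired(rep(1, 3), rep(1, 4)), "variance")
})

test_that("pearson_tradeoff matches closed-form cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_tradeoff(x, x)$r, 1)
  expect_equal(pearson_tradeoff(x, -x)$r, -1)
  expect_equal(pearson_tradeoff(x, c(2, 1, 4, 3))$r, 0.6, tolerance = 1e-12)
  expect_error(pearson_tradeoff(x, rep(1, 4)), "variance")
  expect_error(pearson_tradeoff(1:2, 1:2), "lengths")
})

test_that("classifier produces proper probabilities and is seed-deterministic", {
  corp <- clf_corpus()
  feats <- corpus_features(corp)
  labels <- factor(corp$metadata$group)
  clf <- fit_classifier(feats, labels, classifier_spec(seed = 3))
  withr::with_seed(1, {
    x <- matrix(rnorm(5 * 160, mean = -40, sd = 10), 5)
    p <- predict_proba(clf, x)
    expect_true(all(abs(rowSums(p) - 1) < 1e-6))
    expect_true(all(p >= 0 & p <= 1))
  })
  clf2 <- fit_classifier(feats, labels, classifier_spec(seed = 3))
  expect_identical(as.numeric(stats::coef(clf$fit)),
                   as.numeric(stats::coef(clf2$fit)))
  expect_error(fit_classifier(feats[1:5], factor(rep("a", 5))), "single class")
})

test_that("repeated evaluation is shaped, paired, and discriminates", {
  corp <- clf_corpus()
  split <- split_speakers(corp$metadata, experiment_config(seed = 7))
  tr_idx <- corp$metadata$speaker_id %in% split$train
  feats <- corpus_features(corp)
  clf <- fit_classifier(feats[tr_idx], factor(corp$metadata$group[tr_idx]),
                        classifier_spec(seed = 7))
  te_feats <- feats[!tr_idx]
  te_md <- corp$metadata[!tr_idx, ]
  rep1 <- evaluate_repeated(clf, te_feats, te_md, n_repeats = 8, seed = 7)
  expect_equal(nrow(rep1$metrics), 8L)
  expect_true(all(rep1$metrics >= 0 & rep1$metrics <= 1))
  expect_gt(rep1$summary["mean", "auroc"], 0.8)

  # pairing: identical draw log for a re-run with the same seed
  rep2 <- evaluate_repeated(clf, te_feats, te_md, n_repeats = 8, seed = 7)
  expect_identical(rep1$draws, rep2$draws)
  expect_error(evaluate_repeated(clf, te_feats[te_md$group != "control"],
                                 te_md[te_md$group != "control", ],
                                 n_repeats = 2, seed = 1),
               "misses one class")
})

test_that("fairness_report implements the PtD sign convention", {
  preds <- data.frame(speaker_id = sprintf("s%02d", 1:10),
                      score = c(rep(0.9, 5), rep(0.1, 5)),
                      truth = c(rep(TRUE, 5), rep(FALSE, 5)))
  md <- data.frame(speaker_id = sprintf("s%02d", 1:10),
                   gender = rep(c("female", "male"), c(4, 6)),
                   age_group = "adult")
  fr <- fairness_report(preds, md, "gender")
  expect_equal(fr$ptd, 0)          # equal (perfect) accuracy in both subgroups
  expect_equal(fr$minority, "female")

  # minority 0.92 vs majority 0.90 -> PtD = +0.02 (constructed scores)
  preds2 <- data.frame(
    speaker_id = sprintf("s%03d", 1:150),
    score = c(ifelse(seq_len(50) <= 46, 0.9, 0.1),    # minority: 92% correct
              ifelse(seq_len(100) <= 90, 0.9, 0.1)),  # majority: 90% correct
    truth = TRUE)
  md2 <- data.frame(speaker_id = sprintf("s%03d", 1:150),
                    gender = rep(c("female", "male"), c(50, 100)),
                    age_group = "adult")
  fr2 <- fairness_report(preds2, md2, "gender")
  expect_equal(fr2$ptd, 0.02, tolerance = 1e-12)

  # swapping subgroup sizes (same per-gender accuracies: female 92%, male
  # 90%) flips the minority identity, hence the sign
  md3 <- md2
  md3$gender <- rep(c("female", "male"), c(100, 50))
  preds3 <- preds2
  preds3$score <- c(ifelse(seq_len(100) <= 92, 0.9, 0.1),
                    ifelse(seq_len(50) <= 45, 0.9, 0.1))
  fr3 <- fairness_report(preds3, md3, "gender")
  expect_equal(fr3$ptd, -0.02, tolerance = 1e-12)
  expect_error(fairness_report(preds, md[md$gender == "male", ], "gender"),
               "subgroup")
})
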