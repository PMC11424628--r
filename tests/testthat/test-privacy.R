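test_that("embeddings are unit-norm, deterministic, and guard short input", {
  u <- synthesize_utterance(test_profile(), duration = 1, seed = 1)
  f <- logmel(u, preset = "asv")
  e1 <- embed(f)
  e2 <- embed(f)
  expect_identical(as.numeric(e1), as.numeric(e2))
  expect_equal(sqrt(sum(as.numeric(e1)^2)), 1, tolerance = 1e-9)
  expect_equal(cosine_score(e1, e2), 1, tolerance = 1e-12)
  short <- unclass(f)[1:5, ]
  class(short) <- class(f)
  expect_error(embed(short), "10")
})

test_that("same-speaker cosine exceeds mean different-speaker cosine", {
  corp <- eer_corpus()
  e <- corpus_eer(corp, n_pos = 60, n_neg = 200, seed = 5)
  tr <- attr(e, "trials")
  expect_gt(min(tapply(tr$score, tr$same_speaker, mean)["TRUE"]),
            mean(tr$score[!tr$same_speaker]))
})

test_that("cosine_score matches closed forms and rejects bad input", {
  expect_equal(cosine_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_score(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_score(c(1, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-9)
  expect_error(cosine_score(c(1, 0), c(1, 0, 0)), "mismatch")
  expect_error(cosine_score(c(0, 0), c(1, 0)), "zero")
})

test_that("build_trials samples valid pairs and errors on infeasible requests", {
  md <- data.frame(utterance_id = c("a1", "a2", "b1", "b2"),
                   speaker_id = c("a", "a", "b", "b"))
  tr <- build_trials(md, n_pos = 2, n_neg = 4, seed = 1)
  expect_setequal(paste(tr$enroll_id[tr$same_speaker], tr$test_id[tr$same_speaker]),
                  c("a1 a2", "b1 b2"))
  expect_true(all(tr$enroll_id != tr$test_id))
  expect_identical(build_trials(md, 2, 4, seed = 9),
                   build_trials(md, 2, 4, seed = 9))
  expect_error(build_trials(md, n_pos = 3, n_neg = 1, seed = 1), "positive")
  solo <- rbind(md, data.frame(utterance_id = "c1", speaker_id = "c"))
  expect_error(build_trials(solo, n_pos = 1, n_neg = 1, seed = 1),
               "< 2 utterances")
})

test_that("compute_eer handles the canonical cases", {
  perfect <- compute_eer(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$eer, 0)
  mid <- compute_eer(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2),
                     c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(mid$eer, 1 / 3, tolerance = 1e-9)
  swapped <- compute_eer(c(0.9, 0.8, 0.3, 0.2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(swapped$eer, 1)
  expect_warning(res <- compute_eer(rep(0.5, 6), rep(c(TRUE, FALSE), 3)),
                 "identical")
  expect_equal(res$eer, 0.5)
  expect_error(compute_eer(c(1, 2), c(TRUE, TRUE)), "negative")
})

test_that("EER is invariant under strictly increasing score transforms", {
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(4:30, 1)
      sc <- runif(n)
      lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
      e1 <- compute_eer(sc, lab)$eer
      e2 <- compute_eer(exp(3 * sc) - 1, lab)$eer
      expect_equal(e1, e2, tolerance = 1e-9)
    }
  })
})

test_that("trial list I/O round-trips", {
  md <- data.frame(utterance_id = c("a1", "a2", "b1", "b2"),
                   speaker_id = c("a", "a", "b", "b"))
  tr <- build_trials(md, 2, 4, seed = 1)
  tr$score <- seq_len(nrow(tr)) / 10
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trials(tr, p)
  back <- read_trials(p)
  expect_equal(back$same_speaker, tr$same_speaker)
  expect_equal(back$score, tr$score)
})

test_that("inverse-attack embedder recovers speaker identity on anonymized audio", {
  corp <- eer_corpus()
  anon <- mcadams_eer_corpus()
  naive_orig <- corpus_eer(corp, n_pos = 120, n_neg = 300, seed = 5)
  naive_anon <- corpus_eer(anon, n_pos = 120, n_neg = 300, seed = 5)
  inv <- train_inverse_asv(corp, anon)
  inv_anon <- corpus_eer(anon, embedder = inv, n_pos = 120, n_neg = 300, seed = 5)
  inv_orig <- corpus_eer(corp, embedder = inv, n_pos = 120, n_neg = 300, seed = 5)
  expect_lt(inv_anon$eer, naive_anon$eer)     # attack compromises anonymization
  expect_lt(inv_orig$eer, 0.25)               # baseline verification survives
  expect_gt(naive_anon$eer, naive_orig$eer)
  # speaker-set mismatch is rejected
  half <- corp
  keep <- corp$metadata$speaker_id %in% unique(corp$metadata$speaker_id)[1:10]
  half$utterances <- corp$utterances[corp$metadata$utterance_id[keep]]
  half$metadata <- corp$metadata[keep, ]
  expect_error(train_inverse_asv(half, anon), "speaker sets")
})
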