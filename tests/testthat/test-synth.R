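test_that("scream clips have the specified length, bounds, and determinism", {
  sp <- scream_spec(duration_s = 0.8, rate_hz = 16000)
  c1 <- make_scream_clip(sp, seed = 7)
  expect_length(c1$samples, 12800)            # duration x rate
  expect_true(all(abs(c1$samples) <= 1))
  c2 <- make_scream_clip(sp, seed = 7)
  expect_identical(c1$samples, c2$samples)
  c3 <- make_scream_clip(sp, seed = 8)
  expect_false(identical(c1$samples, c3$samples))
})

test_that("invalid scream specs fail naming the offending field", {
  expect_error(scream_spec(duration_s = 0), "duration_s")
  expect_error(scream_spec(am_depth = 1.5), "am_depth")
  expect_error(scream_spec(am_band = c(70, 50)), "am_band")
  expect_error(scream_spec(f0_hz = 9000, rate_hz = 16000), "rate_hz")
  expect_error(scream_spec(scream_type = "growl"), "scream_type")
})

test_that("corpus designs yield the reference stimulus counts", {
  # full recording design: 12 speakers x 7 types x 5 instances
  co <- make_corpus(corpus_design(12, instances_per_type = 5, seed = 1),
                    duration_s = 0.05, rate_hz = 4000)
  expect_length(co$clips, 420)
  expect_equal(nrow(co$metadata), 420)
  # affect-burst corpus: 16 x 7 x 4
  cb <- make_corpus(corpus_design(16, instances_per_type = 4, seed = 1),
                    duration_s = 0.05, rate_hz = 4000)
  expect_length(cb$clips, 448)
  # behavioral selection: 6 x 7 x 2
  cs <- make_corpus(corpus_design(6, instances_per_type = 2, seed = 1),
                    duration_s = 0.05, rate_hz = 4000)
  expect_length(cs$clips, 84)
  # metadata completeness and alternating speaker sex
  expect_setequal(unique(cs$metadata$scream_type), scream_types())
  sexes <- unique(cs$metadata[c("speaker_id", "sex")])
  expect_equal(sum(sexes$sex == "female"), 3)
  expect_equal(sum(sexes$sex == "male"), 3)
  expect_error(corpus_design(0), "n_speakers")
  expect_error(corpus_design(2, types = c("fear", "fear")), "types")
})

test_that("feature tables have planted geometry and are deterministic", {
  tab <- make_feature_table(7, 60, 88, separation = 3, seed = 4)
  expect_equal(dim(tab$values), c(420, 88))
  expect_equal(length(unique(tab$class_labels)), 7)
  tab2 <- make_feature_table(7, 60, 88, separation = 3, seed = 4)
  expect_identical(tab$values, tab2$values)
  # class-mean geometry: pairwise distances ~ sqrt(2) * separation
  mu <- do.call(rbind, lapply(split(seq_len(420), tab$class_labels),
                              function(i) colMeans(tab$values[i, ])))
  d <- as.numeric(dist(mu))
  expect_true(all(abs(d - 3 * sqrt(2)) < 0.8))
})

test_that("zero separation yields chance-level classification", {
  tab <- make_feature_table(7, 60, 88, separation = 0, seed = 9)
  acc <- crossval_classify(tab, seed = 9)$overall_accuracy
  half <- 1.96 * sqrt((1 / 7) * (6 / 7) / 420)
  expect_gt(acc, 1 / 7 - 2 * half)
  expect_lt(acc, 1 / 7 + 2 * half)
})

test_that("7AFC logs honor the confusion spec, miss rate, and RT window", {
  cats <- scream_types()
  ident <- confusion_spec(cats, diag(7), miss_rate = 0)
  log0 <- make_afc_log(ident, rt_spec(), n_participants = 2,
                       trials_per_type = 5, seed = 2)
  cm <- confusion_from_log(log0)$pooled
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(unname(diag(cm)), rep(10, 7))
  # miss-rate binomial check on a large log
  lg <- make_afc_log(confusion_spec(miss_rate = 0.065), rt_spec(),
                     n_participants = 5, trials_per_type = 300, seed = 3)
  n <- nrow(lg)
  expect_gte(n, 10000)
  half <- 1.96 * sqrt(0.065 * 0.935 / n)
  expect_lt(abs(mean(lg$missed) - 0.065), half * 1.5)
  ok <- !lg$missed
  expect_true(all(lg$rt_ms[ok] > 0 & lg$rt_ms[ok] <= 3000))
  expect_true(all(is.na(lg$rt_ms[!ok])))
  # determinism
  expect_identical(lg, make_afc_log(confusion_spec(miss_rate = 0.065),
                                    rt_spec(), 5, 300, seed = 3))
})

test_that("alarm-biased misclassification raises alarm false-alarm rates", {
  cats <- scream_types()
  P <- matrix(0, 7, 7, dimnames = list(cats, cats))
  for (i in 1:7) {
    w <- ifelse(cats %in% alarm_types(), 4, 1); w[i] <- 0
    P[i, ] <- 0.3 * w / sum(w); P[i, i] <- 0.7
  }
  lg <- make_afc_log(confusion_spec(cats, P, miss_rate = 0), rt_spec(),
                     n_participants = 4, trials_per_type = 100, seed = 5)
  fa <- false_alarm_rates(confusion_from_log(lg))
  expect_gt(min(fa[alarm_types()]), max(fa[nonalarm_types()]))
})

test_that("generated logs satisfy the trial-log invariants on random specs", {
  withr::with_seed(21, {
    for (i in 1:300) {
      k <- sample(2:4, 1)
      cats <- scream_types()[seq_len(k)]
      P <- matrix(runif(k * k), k, k)
      P <- P / rowSums(P)
      miss <- runif(1, 0, 0.3)
      rt <- rt_spec(meanlog_ms = setNames(runif(k, 5.5, 7), cats),
                    sdlog = runif(1, 0.1, 0.6),
                    response_window_ms = sample(1000:4000, 1))
      # trial_log() itself asserts the invariants; construction must succeed
      lg <- make_afc_log(confusion_spec(cats, P, miss), rt,
                         n_participants = 1, trials_per_type = 3,
                         seed = 1000 + i)
      expect_s3_class(lg, "trial_log")
      expect_equal(nrow(lg), 3 * k)
      expect_true(all(is.na(lg$response_type[lg$missed])))
      expect_true(all(lg$response_type[!lg$missed] %in% cats))
    }
  })
})

test_that("2AFC logs cover all 21 pairs with block-local responses", {
  lg <- make_2afc_log(accuracy = 0.9, n_participants = 2,
                      trials_per_type_per_block = 4, seed = 6)
  expect_equal(length(unique(lg$block)), 21)
  for (bk in unique(lg$block)) {
    pr <- strsplit(bk, "|", fixed = TRUE)[[1]]
    d <- lg[lg$block == bk, ]
    expect_setequal(unique(d$true_type), pr)
    expect_true(all(d$response_type[!d$missed] %in% pr))
  }
})

test_that("rating tables are bounded, deterministic, and planted", {
  rt <- make_rating_table(n_raters = 5, n_per_type = 4, seed = 3)
  expect_true(all(rt$ratings >= 0 & rt$ratings <= 1))
  expect_identical(rt$ratings,
                   make_rating_table(n_raters = 5, n_per_type = 4, seed = 3)$ratings)
  # equal means, zero noise: every split scores F = 0
  flat <- make_rating_table(alarm_mean = 0.5, nonalarm_mean = 0.5,
                            neutral_mean = 0.5, noise_sd = 0, n_raters = 4,
                            n_per_type = 3, seed = 1)
  Fs <- vapply(best_split(flat), function(s) s$anova$F, numeric(1))
  expect_true(all(Fs == 0))
  # planted split recovered by the downstream search
  planted <- make_rating_table(n_raters = 23, n_per_type = 20, seed = 8)
  expect_setequal(attr(best_split(planted), "best")$alarm_types, alarm_types())
})
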