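test_that("confusion matrices count non-missed trials by true and chosen type", {
  lg <- fixture_correct_log()
  cs <- confusion_from_log(lg)
  expect_true(all(cs$pooled[upper.tri(cs$pooled) | lower.tri(cs$pooled)] == 0))
  expect_equal(unname(diag(cs$pooled)), rep(4, 7))
  # row sums equal non-missed presentations per type, pooled and per participant
  lg2 <- make_afc_log(confusion_spec(miss_rate = 0.1), rt_spec(),
                      n_participants = 3, trials_per_type = 30, seed = 2)
  cs2 <- confusion_from_log(lg2)
  ok <- !lg2$missed
  expect_equal(unname(rowSums(cs2$pooled)),
               as.vector(table(factor(lg2$true_type[ok], scream_types()))))
  expect_length(cs2$per_participant, 3)
  expect_equal(Reduce(`+`, cs2$per_participant), cs2$pooled)
})

test_that("empirical confusion converges to the generating spec", {
  cats <- scream_types()
  P <- matrix(0.03, 7, 7, dimnames = list(cats, cats))
  diag(P) <- 1 - 0.03 * 6
  lg <- make_afc_log(confusion_spec(cats, P, miss_rate = 0), rt_spec(),
                     n_participants = 1, trials_per_type = 2000, seed = 4)
  emp <- confusion_from_log(lg)$pooled
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - P)), 0.03)
})

test_that("false-alarm rates partition the misclassification mass", {
  conf <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  diag(conf) <- 10
  conf[1, 2] <- 5                              # all errors land on b
  fa <- false_alarm_rates(conf)
  expect_equal(unname(fa), c(0, 1, 0))
  uni <- matrix(2, 4, 4); diag(uni) <- 10
  expect_equal(unname(false_alarm_rates(uni)), rep(0.25, 4))
  expect_equal(sum(false_alarm_rates(uni)), 1, tolerance = 1e-9)
  perfect <- diag(c(5, 5, 5))
  expect_warning(fa0 <- false_alarm_rates(perfect), "undefined")
  expect_true(all(is.na(fa0)))
})

test_that("d-prime matches the inverse-normal oracle and is antisymmetric", {
  conf <- matrix(c(84, 16, 16, 84), 2, byrow = TRUE,
                 dimnames = rep(list(c("x", "y")), 2))
  dp <- dprime_table(conf)
  # hit 0.84, FA 0.16: d' = Z(0.84) - Z(0.16) via numeric CDF inversion
  z84 <- uniroot(function(z) pnorm(z) - 0.84, c(0, 3), tol = 1e-9)$root
  expect_equal(dp$d_prime[1], 2 * z84, tolerance = 1e-6)
  expect_equal(dp$hit_rate[1], 0.84)
  expect_equal(dp$false_alarm_rate[1], 0.16)
  # swapping hits and false alarms negates d'
  swapped <- dprime_table(conf[2:1, ])
  expect_equal(swapped$d_prime[2], -dp$d_prime[2], tolerance = 1e-9)
  # hit rate equal to false-alarm rate: d' = 0
  flat <- matrix(c(5, 5, 5, 5), 2, dimnames = rep(list(c("x", "y")), 2))
  expect_equal(dprime_table(flat)$d_prime, c(0, 0), tolerance = 1e-12)
  # extreme rates stay finite under the 1/(2N) correction
  perfect <- diag(c(20, 20)); dimnames(perfect) <- rep(list(c("x", "y")), 2)
  expect_true(all(is.finite(dprime_table(perfect)$d_prime)))
})

test_that("d-prime from a generated log matches the closed form of its spec", {
  cats <- scream_types()
  P <- matrix(0.02, 7, 7, dimnames = list(cats, cats))
  diag(P) <- 1 - 0.02 * 6
  lg <- make_afc_log(confusion_spec(cats, P, miss_rate = 0), rt_spec(),
                     n_participants = 1, trials_per_type = 5000, seed = 16)
  dp <- dprime_table(confusion_from_log(lg))
  closed <- qnorm(diag(P)) - qnorm(0.02 * 6 / 6)  # uniform FA mass per column
  # per-category sampling SD of d-prime is ~0.023 at this design size
  expect_lt(mean(abs(dp$d_prime - closed)), 0.05)
  expect_lt(max(abs(dp$d_prime - closed)), 0.1)
})

test_that("RT/accuracy summaries exclude the right trials", {
  lg <- fixture_correct_log(n_per_type = 4, rt = 500)
  s7 <- rt_accuracy_summary(lg)
  expect_equal(nrow(s7), 7)
  expect_true(all(s7$mean_rt_ms == 500))
  expect_true(all(s7$accuracy == 1))
  # add missed and incorrect trials: RT mean and accuracy numerator untouched
  extra <- as.data.frame(lg)[1:2, ]
  extra$stimulus_id <- c("m1", "m2")
  extra$missed <- c(TRUE, FALSE)
  extra$response_type <- c(NA, "anger")        # one miss, one error (neutral)
  extra$rt_ms <- c(NA, 900)
  lg2 <- trial_log(rbind(as.data.frame(lg), extra), task_kind = "7AFC",
                   response_window_ms = 3000, categories = scream_types())
  s7b <- rt_accuracy_summary(lg2)
  neu <- s7b[s7b$level == "neutral", ]
  expect_equal(neu$mean_rt_ms, 500)            # incorrect RT not averaged in
  expect_equal(neu$accuracy, 4 / 5)            # miss out of denominator
  expect_equal(neu$n_missed, 1)
})

test_that("3-level aggregation pools member-type trials per participant", {
  lg <- make_afc_log(confusion_spec(miss_rate = 0.05), rt_spec(),
                     n_participants = 3, trials_per_type = 40, seed = 7)
  s3 <- rt_accuracy_summary(lg, alarm_grouping())
  expect_setequal(unique(s3$level), c("neutral", "nonalarm", "alarm"))
  # direct trial-level recomputation for one participant and level
  d <- lg[lg$participant == "p02" & lg$true_type %in% alarm_types(), ]
  correct <- !d$missed & d$response_type == d$true_type
  row <- s3[s3$participant == "p02" & s3$level == "alarm", ]
  expect_equal(row$mean_rt_ms, mean(d$rt_ms[correct]))
  expect_equal(row$accuracy, sum(correct) / sum(!d$missed))
})

test_that("trial bookkeeping: missed + correct + incorrect = total per participant", {
  withr::with_seed(8, {
    for (i in 1:20) {
      k <- sample(3:7, 1)
      cats <- scream_types()[seq_len(k)]
      P <- matrix(runif(k * k), k, k); P <- P / rowSums(P)
      lg <- make_afc_log(confusion_spec(cats, P, runif(1, 0, 0.2)), rt_spec(),
                         n_participants = 2, trials_per_type = 10,
                         seed = 300 + i)
      for (p in unique(lg$participant)) {
        d <- lg[lg$participant == p, ]
        n_missed <- sum(d$missed)
        n_correct <- sum(!d$missed & d$response_type == d$true_type)
        n_incorrect <- sum(!d$missed & d$response_type != d$true_type)
        expect_equal(n_missed + n_correct + n_incorrect, nrow(d))
      }
    }
  })
})

test_that("2AFC pairwise analysis covers 21 pairs and is calibrated", {
  # symmetric generator: no pair should show systematic differences
  lg <- make_2afc_log(accuracy = 0.85, n_participants = 20,
                      trials_per_type_per_block = 20, seed = 9)
  pw <- afc2_pairwise(lg)
  expect_equal(nrow(pw), 21)
  expect_lt(max(abs(pw$norm_rt_diff)), 0.1)
  expect_lte(sum(pw$p_rt_adj < 0.05), 1)
  expect_lte(sum(pw$p_acc_adj < 0.05), 1)
  expect_true(all(pw$p_rt_adj >= pw$p_rt))
  # missing pair is named
  broken <- lg[lg$block != "fear|anger", ]
  attr(broken, "task_kind") <- "2AFC"
  class(broken) <- c("trial_log", "data.frame")
  attr(broken, "categories") <- scream_types()
  expect_error(afc2_pairwise(broken), "fear|anger")
})

test_that("a planted RT gap is detected in its pair and only there", {
  ml <- setNames(rep(log(800), 7), scream_types())
  ml["fear"] <- log(1300)                      # fear markedly slower
  lg <- make_2afc_log(accuracy = 0.9, rt = rt_spec(meanlog_ms = ml, sdlog = 0.2),
                      n_participants = 25, trials_per_type_per_block = 20,
                      seed = 10)
  pw <- afc2_pairwise(lg)
  fear_rows <- pw$type_a == "fear" | pw$type_b == "fear"
  expect_true(all(pw$p_rt_adj[fear_rows] < 0.05))
  expect_true(all(pw$p_rt_adj[!fear_rows] >= 0.05))
})

test_that("combination categories partition the 21 pairs as 6/3/9/3", {
  lg <- make_2afc_log(accuracy = 0.9, n_participants = 4,
                      trials_per_type_per_block = 6, seed = 11)
  combo <- afc2_combo_categories(lg)
  counts <- table(combo$class_of_pair$combo)
  expect_equal(as.vector(counts[c("neutral_vs_scream", "nonalarm_vs_nonalarm",
                                  "alarm_vs_nonalarm", "alarm_vs_alarm")]),
               c(6L, 3L, 9L, 3L))
  expect_equal(sum(counts), 21)
  fa_pair <- combo$class_of_pair$combo[combo$class_of_pair$block == "fear|anger"]
  expect_equal(fa_pair, "alarm_vs_alarm")
})

test_that("planted ordering of combination-class RTs is recovered", {
  ml <- setNames(log(c(600, 800, 800, 800, 1100, 1100, 1100)), scream_types())
  lg <- make_2afc_log(accuracy = 0.95, rt = rt_spec(meanlog_ms = ml, sdlog = 0.2),
                      n_participants = 15, trials_per_type_per_block = 15,
                      seed = 12)
  combo <- afc2_combo_categories(lg)
  m <- combo$class_means$rt
  expect_lt(m["neutral_vs_scream"], m["nonalarm_vs_nonalarm"])
  expect_lt(m["nonalarm_vs_nonalarm"], m["alarm_vs_nonalarm"])
  expect_lt(m["alarm_vs_nonalarm"], m["alarm_vs_alarm"])
  expect_lt(combo$rt_anova$p, 0.001)
})

test_that("trial logs round-trip through delimited text", {
  lg <- make_2afc_log(accuracy = 0.8, n_participants = 2,
                      trials_per_type_per_block = 3, miss_rate = 0.2, seed = 13)
  f <- tempfile(fileext = ".tsv")
  write_trial_log(lg, f)
  back <- read_trial_log(f)
  expect_equal(attr(back, "task_kind"), "2AFC")
  expect_equal(attr(back, "response_window_ms"), 3000)
  expect_equal(back$rt_ms, lg$rt_ms, tolerance = 1e-9)
  expect_identical(back$response_type, lg$response_type)
  expect_identical(back$missed, lg$missed)
  unlink(f)
})
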