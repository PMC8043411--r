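#' Confusion matrices from a 7AFC trial log
#'
#' Counts of (true type, chosen type), excluding missed trials; computed per
#' participant and pooled.
#'
#' @param log a `trial_log` with `task_kind = "7AFC"`.
#' @return A list of class `confusion_set`: `pooled` (K x K count matrix,
#'   rows = true) and `per_participant` (named list of such matrices).
#' @export
confusion_from_log <- function(log) {
  stopifnot(inherits(log, "trial_log"))
  if (attr(log, "task_kind") != "7AFC") stop("confusion_from_log needs a 7AFC log")
  if (nrow(log) == 0) stop("empty trial log")
  cats <- attr(log, "categories")
  ok <- !log$missed
  tab <- function(d) {
    unclass(table(factor(d$true_type, levels = cats),
                  factor(d$response_type, levels = cats)))
  }
  pooled <- tab(log[ok, ])
  per <- lapply(split(log[ok, ], log$participant[ok]), tab)
  structure(list(pooled = pooled, per_participant = per, categories = cats),
            class = "confusion_set")
}

#' False-alarm rates over misclassification choices
#'
#' For each category, the probability that it was the one chosen when a
#' stimulus was misclassified: off-diagonal choices of the category divided
#' by all off-diagonal choices. The rates sum to 1 across categories.
#'
#' @param conf a K x K confusion count matrix (rows = true), or a
#'   `confusion_set` (its pooled matrix is used).
#' @return Named numeric vector of rates; all `NA` with a warning if the
#'   matrix contains no misclassifications.
#' @export
false_alarm_rates <- function(conf) {
  if (inherits(conf, "confusion_set")) conf <- conf$pooled
  conf <- as.matrix(conf)
  off <- conf
  diag(off) <- 0
  total <- sum(off)
  if (total == 0) {
    warning("no misclassifications: false-alarm rates undefined")
    return(stats::setNames(rep(NA_real_, ncol(conf)), colnames(conf)))
  }
  colSums(off) / total
}

#' Per-category sensitivity (d-prime) from a confusion matrix
#'
#' One-vs-rest signal detection per category: the hit rate is the category's
#' diagonal proportion of its own presentations; the false-alarm rate is the
#' proportion of all other categories' presentations on which this category
#' was chosen (trial-weighted pooling over the other rows). Sensitivity is
#' `d' = Z(hit rate) - Z(false-alarm rate)` with `Z` the inverse
#' standard-normal CDF. Extreme rates are adjusted by the 1/(2N) rule
#' (0 -> 1/(2N), 1 -> 1 - 1/(2N), N = the rate's trial denominator) before
#' the transform.
#'
#' @param conf a K x K confusion count matrix or `confusion_set`.
#' @return A data.frame of class `dprime_result`: category, hit_rate,
#'   false_alarm_rate, d_prime, with `attr(, "correction") = "1/(2N)"`.
#' @export
dprime_table <- function(conf) {
  if (inherits(conf, "confusion_set")) conf <- conf$pooled
  conf <- as.matrix(conf)
  cats <- colnames(conf)
  row_tot <- rowSums(conf)
  total <- sum(conf)
  out <- lapply(seq_along(cats), function(i) {
    hit <- rate_correct(conf[i, i], row_tot[i])
    fa_num <- sum(conf[-i, i])
    fa_den <- total - row_tot[i]
    fa <- rate_correct(fa_num, fa_den)
    data.frame(category = cats[i], hit_rate = hit, false_alarm_rate = fa,
               d_prime = z_quantile(hit) - z_quantile(fa),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "correction") <- "1/(2N)"
  class(res) <- c("dprime_result", "data.frame")
  res
}

rate_correct <- function(count, n) {
  if (n <= 0) stop("rate denominator must be positive")
  r <- count / n
  if (r <= 0) r <- 1 / (2 * n)
  if (r >= 1) r <- 1 - 1 / (2 * n)
  r
}

#' Per-participant RT and accuracy summaries under a type grouping
#'
#' Mean RT is computed over correct trials only; accuracy excludes missed
#' trials from its denominator. The grouping maps each type to a level:
#' identity for the 7-level analysis, or [alarm_grouping()] for the 3-level
#' neutral / non-alarm / alarm analysis (level means pool the member types'
#' trials per participant). A participant-level cell with no correct trials
#' gets `NA` RT.
#'
#' @param log a `trial_log`.
#' @param grouping named character vector mapping every type to a level.
#' @return A data.frame: participant, level, mean_rt_ms, accuracy,
#'   n_correct, n_responded, n_missed.
#' @export
rt_accuracy_summary <- function(log, grouping = NULL) {
  stopifnot(inherits(log, "trial_log"))
  cats <- attr(log, "categories")
  if (is.null(grouping)) grouping <- stats::setNames(cats, cats)
  if (!all(cats %in% names(grouping))) {
    stop("grouping must cover all types: missing ",
         paste(setdiff(cats, names(grouping)), collapse = ", "))
  }
  lvl <- unname(grouping[log$true_type])
  correct <- !log$missed & !is.na(log$response_type) &
    log$response_type == log$true_type
  responded <- !log$missed
  cells <- split(seq_len(nrow(log)), list(log$participant, lvl), drop = TRUE)
  rows <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ci <- correct[idx]
    data.frame(participant = parts[1], level = parts[2],
               mean_rt_ms = if (any(ci)) mean(log$rt_ms[idx][ci]) else NA_real_,
               accuracy = sum(ci) / sum(responded[idx]),
               n_correct = sum(ci), n_responded = sum(responded[idx]),
               n_missed = sum(log$missed[idx]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$participant, out$level), ]
}

#' Three-level grouping of the 7 types
#'
#' @param split a [category_split] (defaults to the conventional
#'   \{pain, fear, anger\} alarm partition).
#' @return Named vector mapping each of the 7 types to
#'   neutral/nonalarm/alarm.
#' @export
alarm_grouping <- function(split = category_split(alarm_types())) {
  g <- ifelse(scream_types() == "neutral", "neutral",
              ifelse(scream_types() %in% split$alarm_types, "alarm", "nonalarm"))
  stats::setNames(g, scream_types())
}

#' Pairwise discrimination analysis of a 2AFC log
#'
#' For each of the 21 type pairs: per-participant mean RT (correct trials)
#' and accuracy for each member type; a paired t test across participants on
#' the within-pair difference; and normalized differences, the within-pair
#' difference divided by the participant's mean over the two types
#' (equivalently scaled by 1/mean RT or by the mean accuracy). P-values are
#' Benjamini-Hochberg adjusted across the 21 tests, separately for the RT
#' and accuracy families.
#'
#' @param log a `trial_log` with `task_kind = "2AFC"` containing all pairs.
#' @return A data.frame of class `pair_results`: type_a, type_b, mean RT and
#'   accuracy per member, normalized differences, t statistics, raw and
#'   FDR-adjusted p-values.
#' @export
afc2_pairwise <- function(log) {
  stopifnot(inherits(log, "trial_log"))
  if (attr(log, "task_kind") != "2AFC") stop("afc2_pairwise needs a 2AFC log")
  cats <- attr(log, "categories")
  expected <- apply(utils::combn(cats, 2), 2, paste, collapse = "|")
  have <- unique(log$block)
  missing <- setdiff(expected, have)
  if (length(missing)) stop("missing pair blocks: ", paste(missing, collapse = ", "))

  rows <- lapply(expected, function(bk) {
    pr <- strsplit(bk, "|", fixed = TRUE)[[1]]
    d <- log[log$block == bk, ]
    per <- per_participant_type_stats(d)
    # participants with both types measured
    wide_rt <- stats::reshape(per[c("participant", "true_type", "mean_rt_ms")],
                              idvar = "participant", timevar = "true_type",
                              direction = "wide")
    wide_ac <- stats::reshape(per[c("participant", "true_type", "accuracy")],
                              idvar = "participant", timevar = "true_type",
                              direction = "wide")
    rt1 <- wide_rt[[paste0("mean_rt_ms.", pr[1])]]
    rt2 <- wide_rt[[paste0("mean_rt_ms.", pr[2])]]
    ac1 <- wide_ac[[paste0("accuracy.", pr[1])]]
    ac2 <- wide_ac[[paste0("accuracy.", pr[2])]]
    ok <- is.finite(rt1) & is.finite(rt2)
    t_rt <- paired_t(rt1[ok], rt2[ok])
    t_ac <- tryCatch(paired_t(ac1, ac2),
                     error = function(e) list(t = 0, df = length(ac1) - 1, p = 1))
    data.frame(type_a = pr[1], type_b = pr[2],
               mean_rt_a = mean(rt1, na.rm = TRUE), mean_rt_b = mean(rt2, na.rm = TRUE),
               accuracy_a = mean(ac1), accuracy_b = mean(ac2),
               norm_rt_diff = mean(2 * (rt1[ok] - rt2[ok]) / (rt1[ok] + rt2[ok])),
               norm_acc_diff = mean(ifelse(ac1 + ac2 > 0,
                                           2 * (ac1 - ac2) / (ac1 + ac2), 0)),
               t_rt = t_rt$t, p_rt = t_rt$p,
               t_acc = t_ac$t, p_acc = t_ac$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_rt_adj <- fdr_adjust(out$p_rt)
  out$p_acc_adj <- fdr_adjust(out$p_acc)
  class(out) <- c("pair_results", "data.frame")
  out
}

per_participant_type_stats <- function(d) {
  correct <- !d$missed & !is.na(d$response_type) & d$response_type == d$true_type
  cells <- split(seq_len(nrow(d)), list(d$participant, d$true_type), drop = TRUE)
  rows <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ci <- correct[idx]
    data.frame(participant = parts[1], true_type = parts[2],
               mean_rt_ms = if (any(ci)) mean(d$rt_ms[idx][ci]) else NA_real_,
               accuracy = sum(ci) / sum(!d$missed[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combination-category contrast for the 2AFC pairs
#'
#' Maps each of the 21 pairs to one of four combination classes — neutral vs
#' scream (6 pairs), non-alarm vs non-alarm (3), alarm vs non-alarm (9),
#' alarm vs alarm (3) — computes per-participant mean RT and accuracy per
#' class, and scores each measure with a 4-level repeated-measures ANOVA.
#'
#' @param log a `trial_log` with `task_kind = "2AFC"`.
#' @param split the alarm partition used for the taxonomy (default
#'   \{pain, fear, anger\}).
#' @return A list of class `combo_result`: `class_of_pair` (data.frame),
#'   `summary` (per participant per class), `class_means`, `rt_anova`,
#'   `accuracy_anova`.
#' @export
afc2_combo_categories <- function(log, split = category_split(alarm_types())) {
  stopifnot(inherits(log, "trial_log"))
  if (attr(log, "task_kind") != "2AFC") stop("afc2_combo_categories needs a 2AFC log")
  grouping <- alarm_grouping(split)
  pair_of <- function(bk) sort(strsplit(bk, "|", fixed = TRUE)[[1]])
  combo_class <- function(pr) {
    g <- sort(unname(grouping[pr]))
    if ("neutral" %in% g) "neutral_vs_scream"
    else if (all(g == "nonalarm")) "nonalarm_vs_nonalarm"
    else if (all(g == "alarm")) "alarm_vs_alarm"
    else "alarm_vs_nonalarm"
  }
  blocks <- unique(log$block)
  cls <- vapply(blocks, function(b) combo_class(pair_of(b)), character(1))
  class_of_pair <- data.frame(block = blocks, combo = unname(cls),
                              stringsAsFactors = FALSE)

  correct <- !log$missed & !is.na(log$response_type) &
    log$response_type == log$true_type
  combo <- cls[match(log$block, blocks)]
  cells <- split(seq_len(nrow(log)), list(log$participant, combo), drop = TRUE)
  rows <- lapply(names(cells), function(nm) {
    idx <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    ci <- correct[idx]
    data.frame(participant = parts[1], combo = parts[2],
               mean_rt_ms = if (any(ci)) mean(log$rt_ms[idx][ci]) else NA_real_,
               accuracy = sum(ci) / sum(!log$missed[idx]),
               stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, rows)
  lv <- c("neutral_vs_scream", "nonalarm_vs_nonalarm", "alarm_vs_nonalarm",
          "alarm_vs_alarm")
  to_matrix <- function(col) {
    m <- stats::reshape(summ[c("participant", "combo", col)],
                        idvar = "participant", timevar = "combo",
                        direction = "wide")
    mm <- as.matrix(m[, paste0(col, ".", lv)])
    colnames(mm) <- lv
    mm
  }
  rt_m <- to_matrix("mean_rt_ms")
  ac_m <- to_matrix("accuracy")
  structure(list(class_of_pair = class_of_pair, summary = summ,
                 class_means = list(rt = colMeans(rt_m, na.rm = TRUE),
                                    accuracy = colMeans(ac_m)),
                 rt_anova = rm_anova(rt_m[stats::complete.cases(rt_m), ]),
                 accuracy_anova = rm_anova(ac_m)),
            class = "combo_result")
}

#' Read/write trial logs as delimited text
#'
#' Tab-separated with the task attributes in `#`-prefixed header lines.
#'
#' @param log a `trial_log`.
#' @param path file path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   a `trial_log`.
#' @export
write_trial_log <- function(log, path) {
  stopifnot(inherits(log, "trial_log"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# task_kind: ", attr(log, "task_kind")),
               paste0("# response_window_ms: ", attr(log, "response_window_ms")),
               paste0("# categories: ", paste(attr(log, "categories"), collapse = ","))),
             con)
  utils::write.table(as.data.frame(log), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  hdr <- readLines(path, n = 3)
  get <- function(key) sub(paste0("# ", key, ": "), "", hdr[grepl(key, hdr)])
  df <- utils::read.delim(path, skip = 3, stringsAsFactors = FALSE)
  df$response_type[df$response_type == ""] <- NA_character_
  trial_log(df, task_kind = get("task_kind"),
            response_window_ms = as.numeric(get("response_window_ms")),
            categories = strsplit(get("categories"), ",")[[1]])
}
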