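#' Enumerate all admissible alarm/non-alarm categorizations
#'
#' All unordered partitions of the six non-neutral scream types into two
#' categories of 2-4 types each. Sizes 2 vs 4 contribute 15 unordered
#' partitions twice-counted as 30 ordered ones, and 3 vs 3 contribute 10;
#' the total is 25. Returned in a deterministic canonical order (by the
#' sorted member-set key).
#'
#' @return A list of 25 [category_split] objects.
#' @export
enumerate_splits <- function() {
  types <- nonneutral_types()
  seen <- character(0)
  out <- list()
  for (size in 2:4) {
    sets <- utils::combn(types, size, simplify = FALSE)
    for (s in sets) {
      sp <- category_split(s)
      key <- split_key(sp)
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- sp
      }
    }
  }
  out[order(vapply(out, split_key, character(1)))]
}

#' Score one categorization by repeated-measures ANOVA
#'
#' For a candidate split, each rater's ratings are averaged within three
#' levels — neutral screams, the split's non-alarm types, and its alarm
#' types — and the rater x 3 matrix is scored by [rm_anova()] (with
#' Mauchly-gated Greenhouse-Geisser correction). A larger F means the split
#' separates the alarm dimension more sharply.
#'
#' @param ratings a [rating_table] containing neutral screams and all six
#'   scream types.
#' @param split a [category_split].
#' @return A list of class `split_score` with `split`, `anova`
#'   (an `anova_result`), and `level_means`.
#' @export
split_anova <- function(ratings, split) {
  stopifnot(inherits(ratings, "rating_table"), inherits(split, "category_split"))
  lvl <- ifelse(ratings$scream_types == "neutral", "neutral",
                ifelse(ratings$scream_types %in% split$alarm_types,
                       "alarm", "nonalarm"))
  if (!all(c("neutral", "alarm", "nonalarm") %in% lvl)) {
    stop("rating table must contain screams at all three levels")
  }
  if (nrow(ratings$ratings) < 2) stop("need >= 2 raters")
  per_level <- vapply(c("neutral", "nonalarm", "alarm"), function(l) {
    rowMeans(ratings$ratings[, lvl == l, drop = FALSE])
  }, numeric(nrow(ratings$ratings)))
  means <- colMeans(per_level)
  # the ANOVA is label-symmetric; orient the split so the higher-rated
  # category carries the "alarm" label
  oriented <- if (means["nonalarm"] > means["alarm"]) {
    category_split(split$nonalarm_types)
  } else split
  structure(list(split = oriented, anova = rm_anova(per_level),
                 level_means = means),
            class = "split_score")
}

#' @export
print.split_score <- function(x, ...) {
  cat(sprintf("split alarm={%s}: F(%.3g, %.3g) = %.3f, p = %.3g\n",
              paste(x$split$alarm_types, collapse = ","),
              x$anova$df_num, x$anova$df_den, x$anova$F, x$anova$p))
  invisible(x)
}

#' Exhaustive alarm-categorization search
#'
#' Scores every one of the 25 admissible splits with [split_anova()] and
#' returns them sorted by F statistic, largest first (ties broken by the
#' canonical split order). The first element is the winning, maximally
#' separating categorization.
#'
#' @param ratings a [rating_table].
#' @return A list of class `split_ranking`: 25 `split_score` objects in
#'   decreasing-F order, with the winner flagged via `attr(, "best")`.
#' @export
best_split <- function(ratings) {
  splits <- enumerate_splits()
  scores <- lapply(splits, function(s) split_anova(ratings, s))
  Fs <- vapply(scores, function(s) s$anova$F, numeric(1))
  ord <- order(-Fs, vapply(scores, function(s) split_key(s$split), character(1)))
  out <- scores[ord]
  attr(out, "best") <- out[[1]]$split
  class(out) <- "split_ranking"
  out
}

#' @export
print.split_ranking <- function(x, ...) {
  cat("<split_ranking> top categorizations by rm-ANOVA F:\n")
  for (i in seq_len(min(3, length(x)))) {
    cat(sprintf("  %d. alarm={%s}  F = %.3f\n", i,
                paste(x[[i]]$split$alarm_types, collapse = ","), x[[i]]$anova$F))
  }
  invisible(x)
}

#' Serialize a split ranking to JSON
#'
#' @param ranking a `split_ranking` from [best_split()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_ranking <- function(ranking, path) {
  rows <- lapply(ranking, function(s) {
    list(alarm_types = s$split$alarm_types,
         nonalarm_types = s$split$nonalarm_types,
         F = s$anova$F, df_num = s$anova$df_num, df_den = s$anova$df_den,
         p = s$anova$p, eta_sq = s$anova$eta_sq,
         epsilon = s$anova$epsilon, mauchly_p = s$anova$mauchly_p,
         corrected = s$anova$corrected)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read/write rating tables as delimited text
#'
#' Tab-separated: first column `rater_id`, remaining columns one per scream;
#' a companion header line (`# type:`) records each scream's type.
#'
#' @param ratings a [rating_table].
#' @param path file path.
#' @return `write_rating_table` returns `path` invisibly;
#'   `read_rating_table` a [rating_table].
#' @export
write_rating_table <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# type:\t", paste(ratings$scream_types, collapse = "\t")), con)
  df <- data.frame(rater_id = ratings$rater_ids, ratings$ratings,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rating_table
#' @export
read_rating_table <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# type:")) stop("missing '# type:' header line")
  types <- strsplit(first, "\t")[[1]][-1]
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rating_table(as.matrix(df[, -1, drop = FALSE]), scream_types = types,
               scream_ids = colnames(df)[-1], rater_ids = df$rater_id)
}
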