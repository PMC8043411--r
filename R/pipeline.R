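#' Default pipeline configuration
#'
#' The full default configuration used by [validate_config()]; any key
#' omitted from a user config file is filled from here. Band definitions
#' default to the two roughness bands, 50-70 Hz and 140-180 Hz.
#'
#' @return A nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    output_dir = NULL,                     # required, no default
    seed = 1L,
    stages = c("synth", "prep", "mps", "classify", "alarmsplit", "behavior"),
    bands = list(low = c(50, 70), high = c(140, 180)),
    corpus = list(n_speakers = 4L, instances_per_type = 2L,
                  duration_s = 0.8, rate_hz = 16000),
    prep = list(target_level_db = 70, ramp_s = 0.015),
    mps = list(window_sd_s = 0.0015, hop_s = 0.002, n_freq_bins = 96,
               fmin_hz = 100, floor_db = 80, n_perm = 200L),
    classify = list(n_per_class = 60L, n_features = 88L, separation = 3,
                    n_folds = 5L, kernel_degree = 3L,
                    cross_n_per_class = 64L, cross_separation = 3),
    alarmsplit = list(n_raters = 23L, n_per_type = 60L, alarm_mean = 0.8,
                      nonalarm_mean = 0.4, neutral_mean = 0.6, noise_sd = 0.1,
                      planted_alarm = c("pain", "fear", "anger")),
    behavior = list(n_participants_7afc = 12L, trials_per_type = 24L,
                    miss_rate = 0.0653,
                    n_participants_2afc = 12L, trials_per_type_per_block = 12L,
                    miss_rate_2afc = 0.0155, response_window_ms = 3000)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration file, checks required keys and types, and
#' fills every omitted key from [default_config()]. Unknown top-level keys
#' are an error; so is a missing `output_dir`. The returned normal form
#' re-serializes to itself.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated configuration list of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path: must be a file path or list")
  if (is.null(cfg)) cfg <- list()
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("missing required config key: output_dir")
  merged <- merge_config(defaults, cfg)
  merged$seed <- as.integer(merged$seed)
  if (is.na(merged$seed)) stop("config key seed: must be an integer")
  bad <- setdiff(merged$stages, defaults$stages)
  if (length(bad)) stop("config key stages: unknown stage(s) ", paste(bad, collapse = ", "))
  for (b in c("low", "high")) {
    bd <- merged$bands[[b]]
    if (length(bd) != 2 || !is.numeric(bd) || bd[1] >= bd[2]) {
      stop(sprintf("config key bands$%s: must be (lo, hi) with lo < hi", b))
    }
  }
  if (!all(merged$alarmsplit$planted_alarm %in% nonneutral_types())) {
    stop("config key alarmsplit$planted_alarm: unknown scream type")
  }
  structure(merged, class = "run_config")
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      unknown <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(unknown)) {
        stop(sprintf("unknown config key(s) under %s: %s", k,
                     paste(unknown, collapse = ", ")))
      }
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the selected stages in dependency order — synth, prep, mps,
#' classify, alarmsplit, behavior — writing each stage's outputs under
#' `output_dir` and recording every file with its MD5 checksum in a run
#' manifest. All randomness flows from `config$seed`, so a repeated run
#' with the same configuration produces byte-identical outputs.
#'
#' @param config a `run_config` from [validate_config()].
#' @param verbose print per-stage progress.
#' @return A list of class `run_manifest`: `config`, `files` (named MD5
#'   checksums), `stages_run`, `results` (key stage summaries), `versions`,
#'   `started`, `elapsed_s`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character(0)
  results <- list()
  state <- new.env(parent = emptyenv())
  stages <- intersect(default_config()$stages, config$stages)  # dep order

  for (st in stages) {
    say("stage %s ...", st)
    res <- tryCatch(
      switch(st,
        synth = stage_synth(config, out_dir, state),
        prep = stage_prep(config, out_dir, state),
        mps = stage_mps(config, out_dir, state),
        classify = stage_classify(config, out_dir, state),
        alarmsplit = stage_alarmsplit(config, out_dir, state),
        behavior = stage_behavior(config, out_dir, state)),
      error = function(e) stop(sprintf("stage '%s' failed: %s", st,
                                       conditionMessage(e)), call. = FALSE))
    files <- c(files, res$files)
    results[[st]] <- res$summary
  }

  checks <- tools::md5sum(files)
  names(checks) <- sub(paste0("^", out_dir, "/?"), "", names(checks))
  manifest <- structure(list(
    config = unclass(config), files = as.list(checks),
    stages_run = stages, results = results,
    versions = list(package = as.character(utils::packageVersion("vocalarm")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_manifest")
  jsonlite::write_json(manifest[setdiff(names(manifest), "started")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> stages: %s; %d files; %.1f s\n",
              paste(x$stages_run, collapse = ", "), length(x$files),
              x$elapsed_s))
  invisible(x)
}

stage_synth <- function(config, out_dir, state) {
  cc <- config$corpus
  design <- corpus_design(n_speakers = cc$n_speakers,
                          instances_per_type = cc$instances_per_type,
                          seed = config$seed)
  corpus <- make_corpus(design, duration_s = cc$duration_s,
                        rate_hz = cc$rate_hz)
  wav_dir <- file.path(out_dir, "wav")
  dir.create(wav_dir, showWarnings = FALSE)
  paths <- vapply(corpus$clips, function(cl) {
    p <- file.path(wav_dir, paste0(cl$clip_id, ".wav"))
    write_wav(cl, p, format = "pcm16")
    p
  }, character(1))
  meta_path <- file.path(out_dir, "corpus_metadata.tsv")
  utils::write.table(corpus$metadata, meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  state$corpus <- corpus
  list(files = c(paths, meta_path),
       summary = list(n_clips = length(corpus$clips)))
}

stage_prep <- function(config, out_dir, state) {
  if (is.null(state$corpus)) stop("prep requires the synth stage")
  deltas <- vector("list", length(state$corpus$clips))
  prepped <- vector("list", length(state$corpus$clips))
  for (i in seq_along(state$corpus$clips)) {
    cl <- state$corpus$clips[[i]]
    norm <- suppressWarnings(
      normalize_rms(cl, target_level_db = config$prep$target_level_db))
    norm <- crop_fade(norm, duration_s = config$corpus$duration_s,
                      ramp_s = config$prep$ramp_s)
    prepped[[i]] <- norm
    deltas[[i]] <- as.data.frame(loudness_delta(cl, norm))
  }
  state$prepped <- prepped
  delta_df <- do.call(rbind, deltas)
  p <- file.path(out_dir, "loudness_deltas.tsv")
  utils::write.table(delta_df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  list(files = p, summary = list(mean_delta_db = mean(delta_df$delta_db)))
}

stage_mps <- function(config, out_dir, state) {
  if (is.null(state$prepped)) stop("mps requires the prep stage")
  mc <- config$mps
  grids <- lapply(state$prepped, function(cl) {
    compute_mps(spectrogram_log(cl, window_sd_s = mc$window_sd_s,
                                hop_s = mc$hop_s, n_freq_bins = mc$n_freq_bins,
                                fmin_hz = mc$fmin_hz, floor_db = mc$floor_db))
  })
  types <- vapply(state$prepped, function(cl) cl$metadata$scream_type, character(1))
  ids <- vapply(state$prepped, function(cl) cl$clip_id, character(1))
  lo <- config$bands$low; hi <- config$bands$high
  bp <- data.frame(clip_id = ids, scream_type = types,
                   low = vapply(grids, band_power, numeric(1), lo[1], lo[2]),
                   high = vapply(grids, band_power, numeric(1), hi[1], hi[2]),
                   stringsAsFactors = FALSE)
  bp_path <- file.path(out_dir, "band_powers.tsv")
  utils::write.table(bp, bp_path, sep = "\t", row.names = FALSE, quote = FALSE)

  files <- bp_path
  pmap_summaries <- list()
  neutral <- grids[types == "neutral"]
  if (length(neutral) >= 2) {
    for (ty in setdiff(unique(types), "neutral")) {
      pm <- mps_permutation_pmap(grids[types == ty], neutral,
                                 n_perm = mc$n_perm, seed = config$seed)
      pp <- file.path(out_dir, sprintf("pmap_%s_vs_neutral.tsv", ty))
      utils::write.table(round(pm$p_values, 6), pp, sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, pp)
      pmap_summaries[[ty]] <- mean(pm$p_values < 0.05)
    }
  }
  state$band_powers <- bp
  state$grids <- grids
  list(files = files,
       summary = list(band_powers = bp_path,
                      frac_sig_bins_vs_neutral = pmap_summaries))
}

stage_classify <- function(config, out_dir, state) {
  cc <- config$classify
  tab <- make_feature_table(n_classes = 7, n_per_class = cc$n_per_class,
                            n_features = cc$n_features,
                            separation = cc$separation, seed = config$seed)
  cv <- crossval_classify(tab, n_folds = cc$n_folds,
                          kernel_degree = cc$kernel_degree,
                          seed = config$seed)
  burst <- make_feature_table(n_classes = 7, n_per_class = cc$cross_n_per_class,
                              n_features = cc$n_features,
                              separation = cc$cross_separation,
                              seed = config$seed + 1L)
  ab <- cross_classify(tab, burst, kernel_degree = cc$kernel_degree)
  ba <- cross_classify(burst, tab, kernel_degree = cc$kernel_degree)
  res <- list(
    crossval = list(overall_accuracy = cv$overall_accuracy,
                    per_class_accuracy = as.list(cv$per_class_accuracy),
                    chance_level = cv$chance_level,
                    confusion = cv$confusion),
    cross_classification = list(
      train_screams_test_bursts = ab$overall_accuracy,
      train_bursts_test_screams = ba$overall_accuracy))
  p <- file.path(out_dir, "classification.json")
  jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  list(files = p, summary = list(crossval_accuracy = cv$overall_accuracy))
}

stage_alarmsplit <- function(config, out_dir, state) {
  ac <- config$alarmsplit
  ratings <- make_rating_table(split = category_split(ac$planted_alarm),
                               alarm_mean = ac$alarm_mean,
                               nonalarm_mean = ac$nonalarm_mean,
                               neutral_mean = ac$neutral_mean,
                               noise_sd = ac$noise_sd, n_raters = ac$n_raters,
                               n_per_type = ac$n_per_type, seed = config$seed)
  rt_path <- file.path(out_dir, "alarm_ratings.tsv")
  write_rating_table(ratings, rt_path)
  ranking <- best_split(ratings)
  rk_path <- file.path(out_dir, "split_ranking.json")
  write_split_ranking(ranking, rk_path)
  state$ratings <- ratings
  list(files = c(rt_path, rk_path),
       summary = list(best_alarm_types = attr(ranking, "best")$alarm_types,
                      best_F = ranking[[1]]$anova$F))
}

stage_behavior <- function(config, out_dir, state) {
  bc <- config$behavior
  rt7 <- rt_spec(response_window_ms = bc$response_window_ms)
  # confusion structure: mostly correct, errors biased toward alarm columns
  cats <- scream_types()
  P <- build_demo_confusion(cats, correct = 0.75, alarm_bias = 2)
  log7 <- make_afc_log(confusion_spec(cats, P, miss_rate = bc$miss_rate),
                       rt7, n_participants = bc$n_participants_7afc,
                       trials_per_type = bc$trials_per_type,
                       seed = config$seed)
  conf <- confusion_from_log(log7)
  fa <- false_alarm_rates(conf)
  dp <- dprime_table(conf)
  sum7 <- rt_accuracy_summary(log7)
  sum3 <- rt_accuracy_summary(log7, alarm_grouping())

  log2 <- make_2afc_log(accuracy = 0.9, rt = rt_spec(
                          response_window_ms = bc$response_window_ms),
                        n_participants = bc$n_participants_2afc,
                        trials_per_type_per_block = bc$trials_per_type_per_block,
                        miss_rate = bc$miss_rate_2afc, seed = config$seed + 2L)
  pw <- afc2_pairwise(log2)
  combo <- afc2_combo_categories(log2)

  paths <- c(log7 = "afc7_log.tsv", log2 = "afc2_log.tsv")
  p_log7 <- file.path(out_dir, paths["log7"]); write_trial_log(log7, p_log7)
  p_log2 <- file.path(out_dir, paths["log2"]); write_trial_log(log2, p_log2)
  p_sum <- file.path(out_dir, "behavior_summaries.json")
  jsonlite::write_json(list(
    false_alarm_rates = as.list(fa),
    dprime = dp,
    rt_accuracy_7level = sum7, rt_accuracy_3level = sum3,
    pairwise_2afc = as.data.frame(pw),
    combo_classes = combo$class_of_pair,
    combo_rt_anova = unclass(combo$rt_anova)[c("F", "df_num", "df_den", "p", "eta_sq")],
    combo_accuracy_anova = unclass(combo$accuracy_anova)[c("F", "df_num", "df_den", "p", "eta_sq")]),
    p_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  list(files = c(p_log7, p_log2, p_sum),
       summary = list(mean_dprime = mean(dp$d_prime),
                      combo_rt_F = combo$rt_anova$F))
}

# row-stochastic confusion with off-diagonal mass tilted toward alarm columns
build_demo_confusion <- function(cats, correct = 0.75, alarm_bias = 2) {
  k <- length(cats)
  P <- matrix(0, k, k, dimnames = list(cats, cats))
  for (i in seq_len(k)) {
    w <- ifelse(cats %in% alarm_types(), alarm_bias, 1)
    w[i] <- 0
    P[i, ] <- (1 - correct) * w / sum(w)
    P[i, i] <- correct
  }
  P
}
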