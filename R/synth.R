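#' Synthesize a scream-like audio clip
#'
#' Builds a harmonic carrier (fundamental `f0_hz` plus 6 harmonics with 1/k
#' amplitudes), multiplies it by `1 + am_depth * b(t)` where `b(t)` is
#' band-limited noise confined to `am_band`, adds broadband noise at
#' `noise_level`, and scales the result to peak 0.9. The generator is defined
#' by what the downstream analyses must detect — planted temporal-modulation
#' energy in a known band — not by vocal-tract realism.
#'
#' @param spec a [scream_spec].
#' @param seed integer seed; the output is a pure function of `(spec, seed)`.
#' @return An [audio_clip] of `round(duration_s * rate_hz)` samples.
#' @export
make_scream_clip <- function(spec, seed = 1L) {
  if (!inherits(spec, "scream_spec")) spec <- do.call(scream_spec, spec)
  withr::with_seed(as.integer(seed), {
    n <- round(spec$duration_s * spec$rate_hz)
    t <- (seq_len(n) - 1) / spec$rate_hz
    carrier <- rep(0, n)
    for (k in 1:7) {
      fk <- k * spec$f0_hz
      if (fk < spec$rate_hz / 2) {
        carrier <- carrier + sin(2 * pi * fk * t + stats::runif(1, 0, 2 * pi)) / k
      }
    }
    env <- rep(1, n)
    if (!is.null(spec$am_band) && spec$am_depth > 0) {
      b <- bandlimited_noise(n, spec$rate_hz, spec$am_band)
      env <- 1 + spec$am_depth * b
    }
    x <- carrier * env
    if (spec$noise_level > 0) {
      x <- x + spec$noise_level * max(abs(x)) * stats::rnorm(n)
    }
    x <- 0.9 * x / max(abs(x))
    audio_clip(x, spec$rate_hz, scream_type = spec$scream_type)
  })
}

# white noise band-passed by zeroing FFT bins outside the given band(s)
# (rows of `bands` are (lo, hi) in Hz), normalized to unit peak
bandlimited_noise <- function(n, rate, bands) {
  bands <- if (is.matrix(bands)) bands else matrix(bands, nrow = 1)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                        # two-sided frequency magnitude
  keep <- rep(FALSE, n)
  for (b in seq_len(nrow(bands))) {
    keep <- keep | (f >= bands[b, 1] & f <= bands[b, 2])
  }
  W[!keep] <- 0
  b <- Re(stats::fft(W, inverse = TRUE)) / n
  b / max(abs(b))
}

# per-type synthesis presets: which roughness bands are planted and how deep.
# Alarm screams carry both the ~60 Hz and ~160 Hz bands; pleasure and sadness
# carry the low band at moderate depth; joy weakly; neutral is unmodulated.
type_synth_preset <- function(type) {
  switch(type,
    neutral  = list(am_band = NULL,        am_depth = 0.0, f0 = 400),
    pleasure = list(am_band = c(50, 70),   am_depth = 0.5, f0 = 550),
    sadness  = list(am_band = c(50, 70),   am_depth = 0.5, f0 = 450),
    joy      = list(am_band = c(50, 70),   am_depth = 0.2, f0 = 650),
    pain     = list(am_band = rbind(c(50, 70), c(140, 180)), am_depth = 0.8, f0 = 600),
    fear     = list(am_band = rbind(c(50, 70), c(140, 180)), am_depth = 0.8, f0 = 700),
    anger    = list(am_band = rbind(c(50, 70), c(140, 180)), am_depth = 0.8, f0 = 500),
    stop("unknown scream type: ", type))
}

#' Generate a synthetic scream corpus
#'
#' One clip per (speaker, type, instance) cell. Speaker sex alternates
#' (odd speakers female) to keep corpora balanced; female speakers' carriers
#' are shifted up by 20%. Per-type modulation presets plant the roughness
#' bands the acoustic analyses must recover. The default design yields the
#' reference corpus size of 12 x 7 x 5 = 420 clips.
#'
#' @param design a [corpus_design].
#' @param duration_s,rate_hz clip parameters passed to [scream_spec()].
#' @return A list of class `scream_set` with elements `clips` (list of
#'   [audio_clip]) and `metadata` (data.frame: clip_id, speaker_id, sex,
#'   scream_type, instance).
#' @export
make_corpus <- function(design = corpus_design(), duration_s = 0.8,
                        rate_hz = 16000) {
  if (!inherits(design, "corpus_design")) stop("design: need a corpus_design")
  grid <- expand.grid(instance = seq_len(design$instances_per_type),
                      scream_type = design$types,
                      speaker = seq_len(design$n_speakers),
                      stringsAsFactors = FALSE)
  clips <- vector("list", nrow(grid))
  meta <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sp <- grid$speaker[i]; ty <- grid$scream_type[i]; inst <- grid$instance[i]
    sex <- if (sp %% 2L == 1L) "female" else "male"
    preset <- type_synth_preset(ty)
    f0 <- preset$f0 * (if (sex == "female") 1.2 else 1.0)
    spec <- scream_spec(scream_type = ty, duration_s = duration_s, f0_hz = f0,
                        am_band = preset$am_band, am_depth = preset$am_depth,
                        noise_level = 0.05, rate_hz = rate_hz)
    clip_seed <- (design$seed * 7919L + sp * 1009L + inst * 97L +
                    match(ty, scream_types())) %% .Machine$integer.max
    clip <- make_scream_clip(spec, seed = clip_seed)
    clip$clip_id <- sprintf("s%02d_%s_%02d", sp, ty, inst)
    clip$metadata <- list(speaker_id = sprintf("s%02d", sp), sex = sex,
                          scream_type = ty)
    clips[[i]] <- clip
    meta[[i]] <- data.frame(clip_id = clip$clip_id,
                            speaker_id = sprintf("s%02d", sp), sex = sex,
                            scream_type = ty, instance = inst,
                            stringsAsFactors = FALSE)
  }
  structure(list(clips = clips, metadata = do.call(rbind, meta)),
            class = "scream_set")
}

#' @export
print.scream_set <- function(x, ...) {
  cat(sprintf("<scream_set> %d clips, %d speakers, %d types\n",
              length(x$clips), length(unique(x$metadata$speaker_id)),
              length(unique(x$metadata$scream_type))))
  invisible(x)
}

#' Generate a synthetic acoustic feature table
#'
#' Class means sit on the vertices of a regular simplex (centered unit
#' vectors) embedded at a random orientation and scaled by `separation`, in
#' units of the within-class standard deviation (within-class covariance is
#' the identity); the pairwise distance between class means is then
#' `sqrt(2) * separation`. The default dimensions match the reference design
#' of 7 classes x 60 sounds x 88 features.
#'
#' @param n_classes,n_per_class,n_features table dimensions.
#' @param separation between-class distance in within-class SD units;
#'   0 plants no class structure.
#' @param seed integer seed.
#' @return A list of class `feature_table` with `values` (matrix),
#'   `sound_ids`, `class_labels`, `feature_names`, `normalized`.
#' @export
make_feature_table <- function(n_classes = 7, n_per_class = 60,
                               n_features = 88, separation = 3, seed = 1L) {
  if (n_classes < 1 || n_per_class < 1 || n_features < 1) {
    stop("counts must all be >= 1")
  }
  if (separation < 0) stop("separation: must be >= 0")
  if (n_features < n_classes) stop("n_features must be >= n_classes")
  withr::with_seed(as.integer(seed), {
    # regular simplex: centered unit vectors have pairwise distance sqrt(2)
    E <- diag(n_classes)
    E <- sweep(E, 2, colMeans(E))
    E <- E * separation
    Q <- qr.Q(qr(matrix(stats::rnorm(n_features * n_classes), n_features)))
    means <- E %*% t(Q)                     # n_classes x n_features
    labels <- if (n_classes <= 7) scream_types()[seq_len(n_classes)] else
      sprintf("class%02d", seq_len(n_classes))
    n <- n_classes * n_per_class
    values <- matrix(stats::rnorm(n * n_features), n, n_features)
    class_labels <- rep(labels, each = n_per_class)
    for (ci in seq_len(n_classes)) {
      idx <- which(class_labels == labels[ci])
      values[idx, ] <- sweep(values[idx, , drop = FALSE], 2, means[ci, ], "+")
    }
    feature_table(values,
                  sound_ids = sprintf("snd%04d", seq_len(n)),
                  class_labels = class_labels,
                  feature_names = sprintf("f%03d", seq_len(n_features)))
  })
}

#' Construct a feature table object
#'
#' @param values n_sounds x n_features numeric matrix, no missing values.
#' @param sound_ids,class_labels,feature_names row/label/column names.
#' @param normalized whether columns are already z-normalized.
#' @return A list of class `feature_table`.
#' @export
feature_table <- function(values, sound_ids, class_labels, feature_names,
                          normalized = FALSE) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("values: missing or non-finite entries")
  if (length(sound_ids) != nrow(values)) stop("sound_ids length mismatch")
  if (length(class_labels) != nrow(values)) stop("class_labels length mismatch")
  if (length(feature_names) != ncol(values)) stop("feature_names length mismatch")
  dimnames(values) <- list(sound_ids, feature_names)
  structure(list(values = values, sound_ids = as.character(sound_ids),
                 class_labels = as.character(class_labels),
                 feature_names = as.character(feature_names),
                 normalized = isTRUE(normalized)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sounds x %d features, %d classes%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$class_labels)),
              if (x$normalized) " (z-normalized)" else ""))
  invisible(x)
}

#' Simulate a 7AFC categorization trial log
#'
#' Each trial presents one true type; with probability `miss_rate` the trial
#' is missed (no response, no RT), otherwise the response is drawn from the
#' confusion spec's row for the true type and the RT from a per-type
#' log-normal truncated at the response window. Defaults mirror the 7AFC
#' design: 33 participants, 72 trials per type (3 sessions x 168 trials),
#' 6.53% miss rate, 3,000-ms window.
#'
#' @param confusion a [confusion_spec].
#' @param rt an [rt_spec].
#' @param n_participants,trials_per_type design counts.
#' @param seed integer seed.
#' @return A data.frame of class `trial_log` with columns participant,
#'   block, stimulus_id, true_type, response_type (NA when missed), rt_ms,
#'   missed; attributes `task_kind = "7AFC"`, `response_window_ms`,
#'   `categories`.
#' @export
make_afc_log <- function(confusion = confusion_spec(), rt = rt_spec(),
                         n_participants = 33, trials_per_type = 72,
                         seed = 1L) {
  stopifnot(inherits(confusion, "confusion_spec"), inherits(rt, "rt_spec"))
  if (n_participants < 1 || trials_per_type < 1) stop("counts must be >= 1")
  cats <- confusion$categories
  if (!all(cats %in% names(rt$meanlog_ms))) {
    stop("rt spec must name every category")
  }
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_participants)
    for (p in seq_len(n_participants)) {
      true <- rep(cats, each = trials_per_type)
      true <- sample(true)                    # presentation order randomized
      n <- length(true)
      missed <- stats::runif(n) < confusion$miss_rate
      resp <- rep(NA_character_, n)
      for (ci in seq_along(cats)) {
        idx <- which(true == cats[ci] & !missed)
        if (length(idx)) {
          resp[idx] <- sample(cats, length(idx), replace = TRUE,
                              prob = confusion$response_probabilities[ci, ])
        }
      }
      rt_ms <- rep(NA_real_, n)
      for (ci in seq_along(cats)) {
        idx <- which(true == cats[ci] & !missed)
        if (length(idx)) {
          rt_ms[idx] <- rlnorm_trunc(length(idx),
                                     rt$meanlog_ms[[cats[ci]]],
                                     rt$sdlog[[cats[ci]]],
                                     rt$response_window_ms)
        }
      }
      rows[[p]] <- data.frame(
        participant = sprintf("p%02d", p), block = 1L,
        stimulus_id = sprintf("p%02d_t%04d", p, seq_len(n)),
        true_type = true, response_type = resp, rt_ms = rt_ms,
        missed = missed, stringsAsFactors = FALSE)
    }
    trial_log(do.call(rbind, rows), task_kind = "7AFC",
              response_window_ms = rt$response_window_ms, categories = cats)
  })
}

#' Simulate a 2AFC discrimination trial log over all 21 type pairs
#'
#' One block per unordered pair of the 7 types; within a block each of the
#' two types is presented `trials_per_type_per_block` times and the response
#' is one of the two block types. Defaults mirror the 2AFC design:
#' 35 participants, 36 trials per type per block (72-trial blocks), 1.55%
#' miss rate, 3,000-ms window.
#'
#' @param accuracy named per-type probability of a correct response (or a
#'   scalar applied to all types).
#' @param rt an [rt_spec].
#' @param n_participants,trials_per_type_per_block design counts.
#' @param miss_rate probability of a missed trial.
#' @param types category vocabulary (the 7 default types give 21 blocks).
#' @param seed integer seed.
#' @return A `trial_log` data.frame with `task_kind = "2AFC"`; `block`
#'   encodes the pair as `"typeA|typeB"`.
#' @export
make_2afc_log <- function(accuracy = 0.9, rt = rt_spec(),
                          n_participants = 35, trials_per_type_per_block = 36,
                          miss_rate = 0.0155, types = scream_types(),
                          seed = 1L) {
  stopifnot(inherits(rt, "rt_spec"))
  if (length(accuracy) == 1L && is.null(names(accuracy))) {
    accuracy <- stats::setNames(rep(accuracy, length(types)), types)
  }
  if (!all(types %in% names(accuracy))) stop("accuracy must name every type")
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracy: must lie in [0, 1]")
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate: must lie in [0, 1)")
  pairs <- utils::combn(types, 2)
  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n_participants * ncol(pairs))
    ri <- 0L
    for (p in seq_len(n_participants)) {
      for (b in seq_len(ncol(pairs))) {
        pr <- pairs[, b]
        true <- sample(rep(pr, each = trials_per_type_per_block))
        n <- length(true)
        missed <- stats::runif(n) < miss_rate
        other <- ifelse(true == pr[1], pr[2], pr[1])
        correct <- stats::runif(n) < accuracy[true]
        resp <- ifelse(correct, true, other)
        resp[missed] <- NA_character_
        rt_ms <- rep(NA_real_, n)
        ok <- !missed
        rt_ms[ok] <- rlnorm_trunc(sum(ok), rt$meanlog_ms[true[ok]],
                                  rt$sdlog[true[ok]], rt$response_window_ms)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          participant = sprintf("p%02d", p),
          block = paste(pr, collapse = "|"),
          stimulus_id = sprintf("p%02d_b%02d_t%04d", p, b, seq_len(n)),
          true_type = true, response_type = resp, rt_ms = rt_ms,
          missed = missed, stringsAsFactors = FALSE)
      }
    }
    trial_log(do.call(rbind, rows), task_kind = "2AFC",
              response_window_ms = rt$response_window_ms, categories = types)
  })
}

# inverse-CDF sampling from a log-normal truncated above at `upper` (ms)
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  pmax(1, stats::qlnorm(stats::runif(n) * stats::plnorm(upper, meanlog, sdlog),
                        meanlog, sdlog))
}

#' Construct a trial log
#'
#' @param df data.frame with columns participant, block, stimulus_id,
#'   true_type, response_type, rt_ms, missed.
#' @param task_kind `"7AFC"` or `"2AFC"`.
#' @param response_window_ms maximum RT.
#' @param categories category vocabulary.
#' @return `df` with class `trial_log` and the task attributes attached.
#' @export
trial_log <- function(df, task_kind = c("7AFC", "2AFC"),
                      response_window_ms = 3000, categories = scream_types()) {
  task_kind <- match.arg(task_kind)
  needed <- c("participant", "block", "stimulus_id", "true_type",
              "response_type", "rt_ms", "missed")
  if (!all(needed %in% names(df))) {
    stop("trial log missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  if (!all(df$true_type %in% categories)) stop("true_type outside category list")
  has_resp <- !df$missed
  if (any(has_resp & (!is.finite(df$rt_ms) | df$rt_ms <= 0 |
                      df$rt_ms > response_window_ms))) {
    stop("rt_ms must lie in (0, response_window_ms] for responded trials")
  }
  structure(df, class = c("trial_log", "data.frame"), task_kind = task_kind,
            response_window_ms = response_window_ms, categories = categories)
}

#' Simulate an alarm-rating table with a planted categorization
#'
#' Each rater rates each scream on \[0, 1\]; a scream's latent mean is
#' `neutral_mean`, `alarm_mean`, or `nonalarm_mean` according to its type's
#' side of the planted split, plus Gaussian noise, clipped to the rating
#' scale. Defaults mirror the rating study's size (23 raters, 60 screams
#' per type, 420 screams). The default latent means place the neutral level
#' midway between the two scream categories: the neutral vocalization forms
#' its own ANOVA level in every candidate categorization, so its placement
#' carries no information about the alarm partition, and the midway position
#' maximizes the margin by which the planted partition wins the exhaustive
#' search over rival categorizations.
#'
#' @param split a [category_split]; the planted alarm/non-alarm partition.
#' @param alarm_mean,nonalarm_mean,neutral_mean latent type means in \[0, 1\].
#' @param noise_sd rating noise SD.
#' @param n_raters,n_per_type design counts.
#' @param seed integer seed.
#' @return A list of class `rating_table` with `ratings` (raters x screams
#'   matrix), `scream_types` (type of each scream column), `scream_ids`.
#' @export
make_rating_table <- function(split = category_split(alarm_types()),
                              alarm_mean = 0.8, nonalarm_mean = 0.4,
                              neutral_mean = 0.6, noise_sd = 0.1,
                              n_raters = 23, n_per_type = 60, seed = 1L) {
  stopifnot(inherits(split, "category_split"))
  means <- c(alarm_mean, nonalarm_mean, neutral_mean)
  if (any(means < 0 | means > 1)) stop("rating means must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd: must be >= 0")
  if (n_raters < 1 || n_per_type < 1) stop("counts must be >= 1")
  types <- rep(scream_types(), each = n_per_type)
  mu <- ifelse(types == "neutral", neutral_mean,
               ifelse(types %in% split$alarm_types, alarm_mean, nonalarm_mean))
  withr::with_seed(as.integer(seed), {
    n_screams <- length(types)
    ratings <- matrix(rep(mu, each = n_raters), n_raters, n_screams) +
      stats::rnorm(n_raters * n_screams, sd = noise_sd)
    ratings <- pmin(pmax(ratings, 0), 1)
    rating_table(ratings, scream_types = types,
                 scream_ids = sprintf("scr%04d", seq_len(n_screams)))
  })
}

#' Construct a rating table
#'
#' @param ratings raters x screams matrix of ratings in \[0, 1\].
#' @param scream_types type of each scream (column).
#' @param scream_ids,rater_ids identifiers.
#' @return A list of class `rating_table`.
#' @export
rating_table <- function(ratings, scream_types, scream_ids = NULL,
                         rater_ids = NULL) {
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings)) || any(ratings < 0 | ratings > 1)) {
    stop("ratings: must all lie in [0, 1]")
  }
  if (length(scream_types) != ncol(ratings)) {
    stop("scream_types length must match ncol(ratings)")
  }
  if (is.null(scream_ids)) scream_ids <- sprintf("scr%04d", seq_len(ncol(ratings)))
  if (is.null(rater_ids)) rater_ids <- sprintf("r%02d", seq_len(nrow(ratings)))
  dimnames(ratings) <- list(rater_ids, scream_ids)
  structure(list(ratings = ratings, scream_types = as.character(scream_types),
                 scream_ids = as.character(scream_ids),
                 rater_ids = as.character(rater_ids)),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d raters x %d screams (%d types)\n",
              nrow(x$ratings), ncol(x$ratings), length(unique(x$scream_types))))
  invisible(x)
}
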