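#' Scream-type taxonomy
#'
#' The fixed vocabulary of vocalization categories used throughout the
#' package: a neutral intense /a/ vocalization plus six scream types. The six
#' non-neutral types carry a conventional alarm/non-alarm partition
#' (\{pain, fear, anger\} vs \{pleasure, sadness, joy\}) used by the behavioral
#' taxonomy helpers; the alarm-categorization search treats that partition as
#' one candidate among all admissible ones, never as given.
#'
#' @return `scream_types()` returns all 7 category names in canonical order;
#'   `nonneutral_types()` the 6 scream types; `alarm_types()` and
#'   `nonalarm_types()` the conventional partition of the 6.
#' @export
scream_types <- function() {
  c("neutral", "pleasure", "sadness", "joy", "pain", "fear", "anger")
}

#' @rdname scream_types
#' @export
nonneutral_types <- function() setdiff(scream_types(), "neutral")

#' @rdname scream_types
#' @export
alarm_types <- function() c("pain", "fear", "anger")

#' @rdname scream_types
#' @export
nonalarm_types <- function() c("pleasure", "sadness", "joy")

#' Construct an audio clip
#'
#' A mono waveform with its sampling rate and vocalization metadata; the unit
#' of all acoustic analysis in the package.
#'
#' @param samples numeric vector of finite samples in \[-1, 1\].
#' @param rate_hz positive integer sampling rate.
#' @param clip_id character identifier.
#' @param speaker_id,sex,scream_type optional metadata.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, rate_hz, clip_id = "clip",
                       speaker_id = NA_character_, sex = NA_character_,
                       scream_type = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("samples: length must be >= 1")
  if (!all(is.finite(samples))) stop("samples: all values must be finite")
  if (max(abs(samples)) > 1 + 1e-12) stop("samples: amplitude must lie in [-1, 1]")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz: must be a positive scalar")
  }
  structure(
    list(samples = samples, rate_hz = as.integer(rate_hz),
         clip_id = as.character(clip_id),
         metadata = list(speaker_id = speaker_id, sex = sex,
                         scream_type = scream_type)),
    class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s'> %d samples @ %d Hz (%.3f s), type=%s\n",
              x$clip_id, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz,
              x$metadata$scream_type %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip_duration <- function(clip) length(clip$samples) / clip$rate_hz

clip_rms <- function(clip) sqrt(mean(clip$samples^2))

#' Validate a scream synthesis specification
#'
#' @param scream_type one of [scream_types()].
#' @param duration_s clip duration in seconds.
#' @param f0_hz fundamental frequency of the harmonic carrier, Hz.
#' @param am_band numeric length-2 `(low, high)` temporal-modulation band to
#'   plant, Hz, or `NULL` for no planted modulation.
#' @param am_depth modulation depth in \[0, 1\].
#' @param noise_level relative amplitude of additive broadband noise.
#' @param rate_hz sampling rate, Hz.
#' @return A validated list of class `scream_spec`.
#' @export
scream_spec <- function(scream_type = "fear", duration_s = 0.8, f0_hz = 500,
                        am_band = c(50, 70), am_depth = 0.8,
                        noise_level = 0.05, rate_hz = 16000) {
  if (!scream_type %in% scream_types()) {
    stop("scream_type: must be one of ", paste(scream_types(), collapse = ", "))
  }
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s: must be > 0")
  if (!is.numeric(f0_hz) || f0_hz <= 0) stop("f0_hz: must be > 0")
  if (!is.null(am_band)) {
    am_band <- if (is.matrix(am_band)) am_band else matrix(am_band, nrow = 1)
    if (ncol(am_band) != 2L || !all(is.finite(am_band)) ||
        any(am_band[, 1] >= am_band[, 2]) || any(am_band[, 1] < 0)) {
      stop("am_band: each band must be (low, high) with 0 <= low < high")
    }
  }
  if (!is.numeric(am_depth) || am_depth < 0 || am_depth > 1) {
    stop("am_depth: must lie in [0, 1]")
  }
  if (!is.numeric(noise_level) || noise_level < 0) stop("noise_level: must be >= 0")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz: must be > 0")
  # Nyquist must clear the carrier harmonics' fundamental and the AM band edge
  top <- max(f0_hz, if (!is.null(am_band)) max(am_band[, 2]) else 0)
  if (rate_hz <= 2 * top) stop("rate_hz: must exceed twice f0_hz and the AM band upper edge")
  structure(list(scream_type = scream_type, duration_s = duration_s,
                 f0_hz = f0_hz, am_band = am_band, am_depth = am_depth,
                 noise_level = noise_level, rate_hz = rate_hz),
            class = "scream_spec")
}

#' Corpus design for synthetic scream recording
#'
#' Defaults mirror the recording design that yields 420 clips: 12 speakers,
#' 7 vocalization types, 5 selected instances per speaker and type.
#'
#' @param n_speakers number of speakers (sex alternates across speakers).
#' @param types vocalization types to include.
#' @param instances_per_type instances per speaker and type.
#' @param seed integer seed.
#' @return A validated list of class `corpus_design`.
#' @export
corpus_design <- function(n_speakers = 12, types = scream_types(),
                          instances_per_type = 5, seed = 1L) {
  if (n_speakers < 1) stop("n_speakers: must be >= 1")
  if (length(types) < 1 || anyDuplicated(types)) {
    stop("types: must be non-empty and unique")
  }
  if (!all(types %in% scream_types())) stop("types: unknown scream type")
  if (instances_per_type < 1) stop("instances_per_type: must be >= 1")
  structure(list(n_speakers = as.integer(n_speakers), types = types,
                 instances_per_type = as.integer(instances_per_type),
                 seed = as.integer(seed)),
            class = "corpus_design")
}

#' Response-confusion specification for simulated forced-choice tasks
#'
#' @param categories ordered response categories (K types).
#' @param response_probabilities K x K row-stochastic matrix; row = true type,
#'   column = response probability.
#' @param miss_rate probability of a missed (no-response) trial; the observed
#'   miss rate in the 7AFC categorization data is 6.53%.
#' @return A validated list of class `confusion_spec`.
#' @export
confusion_spec <- function(categories = scream_types(),
                           response_probabilities = diag(length(categories)),
                           miss_rate = 0.0653) {
  k <- length(categories)
  if (k < 2 || anyDuplicated(categories)) stop("categories: must be >= 2 unique types")
  p <- as.matrix(response_probabilities)
  if (!all(dim(p) == c(k, k))) stop("response_probabilities: must be K x K")
  if (any(p < 0)) stop("response_probabilities: entries must be >= 0")
  if (any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("response_probabilities: each row must sum to 1 (tolerance 1e-9)")
  }
  if (miss_rate < 0 || miss_rate >= 1) stop("miss_rate: must lie in [0, 1)")
  dimnames(p) <- list(categories, categories)
  structure(list(categories = categories, response_probabilities = p,
                 miss_rate = miss_rate),
            class = "confusion_spec")
}

#' Response-time specification for simulated trials
#'
#' RTs are drawn log-normal per true type and truncated at the response
#' window (the behavioral tasks allowed 3,000 ms).
#'
#' @param meanlog_ms named vector (per type) of log-normal location for RT in ms.
#' @param sdlog scalar or named vector of log-normal scale (> 0).
#' @param response_window_ms maximum RT, ms.
#' @return A validated list of class `rt_spec`.
#' @export
rt_spec <- function(meanlog_ms = stats::setNames(rep(log(900), 7), scream_types()),
                    sdlog = 0.35, response_window_ms = 3000) {
  if (any(sdlog <= 0)) stop("sdlog: must be > 0")
  if (response_window_ms <= 0) stop("response_window_ms: must be > 0")
  if (is.null(names(meanlog_ms))) stop("meanlog_ms: must be named by type")
  if (length(sdlog) == 1L) sdlog <- stats::setNames(rep(sdlog, length(meanlog_ms)),
                                                    names(meanlog_ms))
  structure(list(meanlog_ms = meanlog_ms, sdlog = sdlog,
                 response_window_ms = response_window_ms),
            class = "rt_spec")
}

#' An alarm/non-alarm categorization of the six scream types
#'
#' @param alarm_types,nonalarm_types disjoint sets whose union is the six
#'   non-neutral types; each of size 2-4.
#' @return A validated list of class `category_split`.
#' @export
category_split <- function(alarm_types, nonalarm_types = setdiff(nonneutral_types(), alarm_types)) {
  a <- sort(alarm_types); b <- sort(nonalarm_types)
  if (length(intersect(a, b)) > 0) stop("alarm/nonalarm sets must be disjoint")
  if (!setequal(c(a, b), nonneutral_types())) {
    stop("union of the two sets must be the 6 non-neutral scream types")
  }
  if (!(length(a) %in% 2:4) || !(length(b) %in% 2:4)) {
    stop("each category must contain 2-4 scream types")
  }
  structure(list(alarm_types = a, nonalarm_types = b), class = "category_split")
}

#' @export
print.category_split <- function(x, ...) {
  cat(sprintf("<category_split> alarm={%s} vs non-alarm={%s}\n",
              paste(x$alarm_types, collapse = ","),
              paste(x$nonalarm_types, collapse = ",")))
  invisible(x)
}

split_key <- function(split) {
  # canonical unordered key: the lexicographically smaller member set first
  a <- paste(split$alarm_types, collapse = "+")
  b <- paste(split$nonalarm_types, collapse = "+")
  paste(sort(c(a, b)), collapse = " | ")
}
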