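#' RMS loudness normalization
#'
#' Scales a clip so its root-mean-square amplitude equals the digital target
#' implied by `target_level_db`. Absolute SPL is not recoverable from digital
#' files, so the package uses a documented reference convention: a level of
#' 70 dB maps to digital RMS 0.05, and other levels scale by
#' `10^((level - 70)/20)`. All downstream analyses depend only on RMS
#' equality across clips, not on the absolute reference. If normalization
#' would push samples beyond full scale the clip is scaled down to peak 1
#' instead, with a warning (never hard-clipped).
#'
#' @param clip an [audio_clip] with nonzero RMS.
#' @param target_level_db nominal level in dB (default 70).
#' @param reference_rms digital RMS assigned to 70 dB (default 0.05).
#' @return The normalized [audio_clip].
#' @export
normalize_rms <- function(clip, target_level_db = 70, reference_rms = 0.05) {
  stopifnot(inherits(clip, "audio_clip"))
  rms <- clip_rms(clip)
  if (rms == 0) stop("cannot normalize silence")
  target <- reference_rms * 10^((target_level_db - 70) / 20)
  g <- target / rms
  x <- clip$samples * g
  peak <- max(abs(x))
  if (peak > 1) {
    warning(sprintf("clip '%s': normalization would exceed full scale (peak %.3f); scaled to peak 1",
                    clip$clip_id, peak))
    x <- x / peak
  }
  out <- clip
  out$samples <- x
  out
}

#' Crop to a fixed duration with linear intensity ramps
#'
#' Truncates the clip to `duration_s` (the stimulus standard is 0.8 s) and
#' applies linear fade-in/fade-out ramps of `ramp_s` (standard 15 ms) at both
#' ends, so the first and last samples are exactly zero.
#'
#' @param clip an [audio_clip] at least `duration_s` long.
#' @param duration_s output duration, seconds.
#' @param ramp_s ramp duration, seconds.
#' @return The cropped, faded [audio_clip]; rate and metadata preserved.
#' @export
crop_fade <- function(clip, duration_s = 0.8, ramp_s = 0.015) {
  stopifnot(inherits(clip, "audio_clip"))
  n_out <- round(duration_s * clip$rate_hz)
  if (length(clip$samples) < n_out) {
    stop(sprintf("clip '%s' is shorter (%d samples) than the requested duration (%d)",
                 clip$clip_id, length(clip$samples), n_out))
  }
  if (ramp_s < 0 || 2 * ramp_s > duration_s) stop("ramp_s: must satisfy 0 <= 2*ramp_s <= duration_s")
  x <- clip$samples[seq_len(n_out)]
  n_ramp <- round(ramp_s * clip$rate_hz)
  if (n_ramp > 0) {
    ramp <- seq(0, 1, length.out = n_ramp)
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[(n_out - n_ramp + 1):n_out] <- x[(n_out - n_ramp + 1):n_out] * rev(ramp)
  }
  out <- clip
  out$samples <- x
  out
}

#' Loudness delta between original and normalized clip
#'
#' The RMS-level difference in dB, `20 * log10(RMS_original /
#' RMS_normalized)`: how much louder (positive) or softer (negative) the
#' original recording was than its normalized version. One delta per clip is
#' the input to the delta-vs-alarm-rating correlation.
#'
#' @param original,normalized non-silent [audio_clip]s.
#' @return A list with `clip_id` and `delta_db`.
#' @export
loudness_delta <- function(original, normalized) {
  stopifnot(inherits(original, "audio_clip"), inherits(normalized, "audio_clip"))
  r0 <- clip_rms(original); r1 <- clip_rms(normalized)
  if (r0 == 0 || r1 == 0) stop("cannot compute loudness delta for silence")
  list(clip_id = original$clip_id, delta_db = 20 * log10(r0 / r1))
}

#' Correlate per-clip loudness deltas with mean alarm ratings
#'
#' The design of the loudness-control analysis: one normalization delta per
#' clip against that clip's mean alarm rating, Pearson correlation. A small,
#' non-significant r indicates the alarm ratings are not explained by how
#' much normalization changed each clip.
#'
#' @param deltas data.frame with columns `clip_id`, `delta_db`.
#' @param mean_ratings named numeric vector of mean alarm rating per clip id.
#' @return A `correlation_result` (see [pearson()]).
#' @export
loudness_rating_correlation <- function(deltas, mean_ratings) {
  ids <- intersect(deltas$clip_id, names(mean_ratings))
  if (length(ids) < 3) stop("need >= 3 clips common to both inputs")
  d <- deltas$delta_db[match(ids, deltas$clip_id)]
  pearson(d, unname(mean_ratings[ids]))
}
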