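# shared fixtures, built in code at test time

# a short deterministic clip with a planted low roughness band
fixture_clip <- function(seed = 1L, am_band = c(55, 65), am_depth = 0.8,
                         duration_s = 0.8) {
  make_scream_clip(scream_spec(am_band = am_band, am_depth = am_depth,
                               duration_s = duration_s), seed = seed)
}

# small synthetic MPS grid with iid positive bin power
fixture_grid <- function(seed, nbin = 8, mean = 10, sd = 2,
                         bump_bins = integer(0), bump = 0) {
  withr::with_seed(seed, {
    p <- abs(stats::rnorm(nbin * nbin, mean, sd))
    p[bump_bins] <- p[bump_bins] + bump
    mps_grid(matrix(p, nbin, nbin),
             wt_axis = seq(-100, 100, length.out = nbin),
             ws_axis = seq(0, 10, length.out = nbin))
  })
}

# independent step-up FDR oracle (direct transcription of the BH definition)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# tiny all-correct 7AFC log built by hand
fixture_correct_log <- function(n_per_type = 4, rt = 500) {
  cats <- scream_types()
  df <- data.frame(participant = "p01", block = 1L,
                   stimulus_id = sprintf("t%03d", seq_len(7 * n_per_type)),
                   true_type = rep(cats, each = n_per_type),
                   response_type = rep(cats, each = n_per_type),
                   rt_ms = rt, missed = FALSE, stringsAsFactors = FALSE)
  trial_log(df, task_kind = "7AFC", response_window_ms = 3000,
            categories = cats)
}
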