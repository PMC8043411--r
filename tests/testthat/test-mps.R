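test_that("spectrogram localizes a pure tone and respects its parameters", {
  rate <- 16000
  t <- (0:(0.3 * rate - 1)) / rate
  tone <- audio_clip(0.9 * sin(2 * pi * 1000 * t), rate)
  sg <- spectrogram_log(tone, n_freq_bins = 96)
  target_bin <- which.min(abs(sg$freq_axis - 1000))
  peaks <- apply(sg$values, 1, which.max)
  inner <- 10:(nrow(sg$values) - 10)          # skip edge frames
  expect_true(all(abs(peaks[inner] - target_bin) <= 1))
  expect_equal(diff(sg$time_axis[1:2]), 0.002, tolerance = 1e-12)
  # near-silence: everything at the floor
  quiet <- audio_clip(c(1e-3, rep(1e-12, 4799)), 4800)
  sq <- spectrogram_log(quiet, fmin_hz = 100, fmax_hz = 2000)
  expect_equal(diff(range(sq$values[300:nrow(sq$values), ])), 0)
  expect_error(spectrogram_log(tone, fmin_hz = 0), "fmin")
  expect_error(spectrogram_log(tone, hop_s = -1), "hop")
})

test_that("a constant spectrogram concentrates all MPS power at the origin", {
  sg <- structure(list(values = matrix(5, 40, 16),
                       time_axis = seq(0, by = 0.002, length.out = 40),
                       freq_axis = 100 * 2^(seq(0, 5, length.out = 16))),
                  class = "spectrogram")
  m <- compute_mps(sg)
  origin <- which(m$wt_axis == 0)
  expect_true(all(m$power[-origin, ] <= 1e-6 * max(m$power[origin, 1], 1e-300)))
  expect_true(all(m$power <= 1e-20))          # mean-removed constant is zero
})

test_that("MPS recovers a planted 60-Hz temporal modulation band", {
  cl <- fixture_clip(seed = 11, am_band = c(55, 65))
  m <- compute_mps(spectrogram_log(cl))
  marg <- rowMeans(m$power)
  away_from_dc <- abs(m$wt_axis) > 20
  peak_wt <- abs(m$wt_axis[away_from_dc][which.max(marg[away_from_dc])])
  expect_gte(peak_wt, 55)
  expect_lte(peak_wt, 65)
  expect_gt(band_power(m, 50, 70), band_power(m, 140, 180))
})

test_that("MPS satisfies Hermitian symmetry and Parseval's identity", {
  cl <- fixture_clip(seed = 12)
  sg <- spectrogram_log(cl)
  m <- compute_mps(sg, wt_max = Inf, ws_max = Inf, fold_spectral = FALSE)
  # pair each (wt, ws) bin with its negation where both exist
  it <- match(-m$wt_axis, m$wt_axis)
  is <- match(-m$ws_axis, m$ws_axis)
  ok_t <- which(!is.na(it)); ok_s <- which(!is.na(is))
  expect_gt(length(ok_t) * length(ok_s), 1000)
  expect_equal(m$power[ok_t, ok_s],
               m$power[it[ok_t], is[ok_s]], tolerance = 1e-9)
  # Parseval under the documented normalization
  Mc <- sg$values - mean(sg$values)
  expect_equal(sum(m$power), sum(Mc^2), tolerance = 1e-6)
})

test_that("band power is invariant to time reversal", {
  # clip length chosen so reversed frame centers land on the analysis grid
  withr::with_seed(13, x <- runif(12801, -0.9, 0.9))
  fwd <- audio_clip(x, 16000)
  rev_ <- audio_clip(rev(x), 16000)
  mf <- compute_mps(spectrogram_log(fwd))
  mr <- compute_mps(spectrogram_log(rev_))
  expect_equal(band_power(mf, 50, 70), band_power(mr, 50, 70),
               tolerance = 1e-6)
  expect_equal(band_power(mf, 140, 180), band_power(mr, 140, 180),
               tolerance = 1e-6)
})

test_that("band power trivial contracts hold", {
  ones <- mps_grid(matrix(1, 41, 5), seq(-200, 200, length.out = 41),
                   seq(0, 12, length.out = 5))
  expect_equal(band_power(ones, 50, 70), 1)
  expect_equal(band_power(ones, 140, 180), 1)
  expect_error(band_power(ones, 150, 250), "outside")
  expect_error(band_power(ones, 70, 50), "wt_lo")
})

test_that("group difference is elementwise and antisymmetric", {
  a <- lapply(1:3, fixture_grid)
  b <- lapply(4:6, fixture_grid)
  expect_true(all(mps_group_difference(a, a)$power == 0))
  shifted <- lapply(a, function(g) { g$power <- g$power + 2.5; g })
  expect_equal(mps_group_difference(shifted, a)$power,
               matrix(2.5, 8, 8), tolerance = 1e-12)
  d1 <- mps_group_difference(a, b)$power
  d2 <- mps_group_difference(b, a)$power
  expect_equal(d1, -d2, tolerance = 1e-12)
  bad <- fixture_grid(1, nbin = 4)
  expect_error(mps_group_difference(a, list(bad)), "mismatch")
})

test_that("permutation map is deterministic, bounded, and detects planted bands", {
  a <- lapply(1:6, fixture_grid)
  b <- lapply(7:12, fixture_grid)
  p1 <- mps_permutation_pmap(a, b, n_perm = 200, seed = 5)
  p2 <- mps_permutation_pmap(a, b, n_perm = 200, seed = 5)
  expect_identical(p1$p_values, p2$p_values)
  expect_true(all(p1$p_values >= 1 / 201 & p1$p_values <= 1))
  expect_error(mps_permutation_pmap(a, b, n_perm = 0), "n_perm")
  # planted band: bins 1:16 raised by 3 within-group SDs in group a
  ap <- lapply(1:6, function(s) fixture_grid(s, bump_bins = 1:16, bump = 6))
  pm <- mps_permutation_pmap(ap, b, n_perm = 400, seed = 9)
  expect_gt(mean(pm$p_values[1:16] < 0.05), 0.8)
})

test_that("band-power regression recovers exact and planted relationships", {
  withr::with_seed(41, {
    bp <- data.frame(clip_id = sprintf("c%02d", 1:40),
                     low = runif(40, 0, 10), high = runif(40, 0, 3))
    exact <- setNames(0.1 + 0.05 * bp$low + 0.02 * bp$high, bp$clip_id)
    fit <- alarm_bandpower_regression(bp, exact)
    expect_equal(fit$R2, 1, tolerance = 1e-9)
    expect_equal(unname(fit$coefficients["low"]), 0.05, tolerance = 1e-9)
    # positive planted dependence with noise: both betas positive
    noisy <- setNames(exact + rnorm(40, sd = 0.02), bp$clip_id)
    fit2 <- alarm_bandpower_regression(bp, noisy)
    expect_gt(fit2$coefficients["low"], 0)
    expect_gt(fit2$coefficients["high"], 0)
    # permuted ratings: p approximately uniform over repetitions
    ps <- replicate(300, {
      alarm_bandpower_regression(bp, setNames(sample(exact), bp$clip_id))$p
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  })
})
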