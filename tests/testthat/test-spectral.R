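test_that("the bin grid is exactly 0.25 Hz and tones land on their bins", {
  rec <- tone_recording(7.0, amplitude = 2)
  sp <- compute_epoch_spectra(rec, taper = "rectangular")
  expect_equal(sp$bin_width_hz, 0.25)
  expect_equal(sp$freq_hz, seq(0.25, 31.75, by = 0.25))
  expect_equal(ncol(sp$power), 127L)
  # argmax at the tone frequency in every epoch
  expect_true(all(sp$freq_hz[apply(sp$power, 1, which.max)] == 7.0))
})

test_that("Parseval holds on bin-centered tones", {
  A <- 3.7
  rec <- tone_recording(2.0, amplitude = A, phase = 0.3)
  sp <- compute_epoch_spectra(rec, taper = "rectangular")
  # all power concentrated in the 2.0 Hz bin, equal to A^2/2
  i2 <- which(sp$freq_hz == 2.0)
  expect_lt(max(abs(sp$power[, i2] - A^2 / 2)) / (A^2 / 2), 1e-9)
  expect_lt(max(abs(rowSums(sp$power) - A^2 / 2)) / (A^2 / 2), 1e-9)
  # the power-renormalized Hann taper preserves total tone power
  sph <- compute_epoch_spectra(rec, taper = "hann")
  expect_lt(max(abs(rowSums(sph$power) - A^2 / 2)) / (A^2 / 2), 1e-6)
})

test_that("white-noise spectra are flat across the analysis band", {
  set.seed(202)
  n_ep <- 32768
  n <- n_ep * 256
  rec <- signal_recording(list(EEG2 = rnorm(n), EMG = rep(1, n)), 64)
  sp <- compute_epoch_spectra(rec, taper = "rectangular")
  m <- colMeans(sp$power)
  sel <- sp$freq_hz >= 1 & sp$freq_hz <= 25
  expect_lt(max(abs(m[sel] / mean(m[sel]) - 1)), 0.02)
})

test_that("artifact flagging recovers injected transients", {
  cfg <- archetype_config("NAB", n_hours = 6, seed = 55, artifact_rate = 0.005)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg)
  sp <- compute_epoch_spectra(rec)
  mask <- flag_artifacts(sp)
  truth <- hyp$artifact
  expect_gt(sum(truth), 10)
  sens <- sum(mask & truth) / sum(truth)
  fpr <- sum(mask & !truth) / sum(!truth)
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.01)

  # threshold limits: k = Inf flags nothing; identical epochs flag nothing
  expect_false(any(flag_artifacts(sp, k = Inf)))
  flat <- manual_spectra(matrix(1, nrow = 200, ncol = 127))
  expect_false(any(flag_artifacts(flat)))
  # upstream hypnogram flags are OR-ed in
  m2 <- flag_artifacts(sp, hyp = hyp)
  expect_true(all(m2[truth]))
})

test_that("nrem delta time course matches the hand-computed arithmetic", {
  # 3 NREM epochs with hand-set spectra; one WAKE epoch that must not count
  pw <- matrix(0, nrow = 4, ncol = 127)
  # epoch 1: 10 units in the 1 Hz bin, 10 in the 10 Hz bin
  pw[1, c(4, 40)] <- 10
  # epoch 2: 20 in the 2 Hz bin
  pw[2, 8] <- 20
  # epoch 3: 5 in the 3 Hz bin, 5 in the 20 Hz bin
  pw[3, c(12, 80)] <- 5
  # epoch 4 (WAKE): large power that must be excluded
  pw[4, ] <- 100
  sp <- manual_spectra(pw)
  hyp <- hypnogram(c("NREM", "NREM", "NREM", "WAKE"))
  # normalizer: mean total (0.5-29 Hz) power of NREM epochs = (20+20+10)/3
  # delta (0.5-5 Hz) means: (10+20+5)/3; single bin spanning all epochs
  tc <- nrem_delta_timecourse(sp, hyp, bin_h = 24)
  expect_equal(tc$delta_pct, 100 * (35 / 3) / (50 / 3), tolerance = 1e-12)
  expect_equal(tc$n_epochs, 3)
  # a masked NREM epoch carries no weight
  sp$artifact_mask[2] <- TRUE
  tc2 <- nrem_delta_timecourse(sp, hyp, bin_h = 24)
  expect_equal(tc2$delta_pct, 100 * (15 / 2) / (30 / 2), tolerance = 1e-12)
  # bins without NREM epochs are missing, not zero
  tc3 <- nrem_delta_timecourse(sp, hyp, bin_h = 2 / 3600)
  expect_true(is.na(tc3$delta_pct[4]))
  # zero NREM epochs in the reference day is an error
  expect_error(nrem_delta_timecourse(sp, hypnogram(rep("WAKE", 4))),
               "no unmasked NREM")
})

test_that("normalized quantities are invariant to global amplitude scaling", {
  cfg <- tiny_config(n_hours = 0.5, seed = 61)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg)
  rec2 <- rec
  rec2$channels$EEG2 <- rec2$channels$EEG2 * 7.3
  rec2$channels$EEG1 <- rec2$channels$EEG1 * 7.3
  sp1 <- compute_epoch_spectra(rec)
  sp2 <- compute_epoch_spectra(rec2)
  expect_equal(sp2$power, sp1$power * 7.3^2, tolerance = 1e-12)
  expect_equal(nrem_delta_timecourse(sp2, hyp, 24)$delta_pct,
               nrem_delta_timecourse(sp1, hyp, 24)$delta_pct,
               tolerance = 1e-10)
  expect_equal(state_spectral_profile(sp2, hyp, "NREM")$power_pct,
               state_spectral_profile(sp1, hyp, "NREM")$power_pct,
               tolerance = 1e-10)
  expect_equal(band_power_by_state(sp2, hyp, interval = "light")$power_pct,
               band_power_by_state(sp1, hyp, interval = "light")$power_pct,
               tolerance = 1e-10)
})

test_that("state profiles obey the normalization identities", {
  cfg <- tiny_config(n_hours = 0.5, seed = 62)
  hyp <- simulate_hypnogram(cfg)
  sp <- compute_epoch_spectra(simulate_signals(hyp, cfg))

  # single-state recording: profile sums to exactly 100%
  all_n <- hypnogram(rep("NREM", 450))
  spn <- compute_epoch_spectra(simulate_signals(all_n, cfg))
  expect_equal(sum(state_spectral_profile(spn, all_n, "NREM")$power_pct), 100,
               tolerance = 1e-10)

  # general identity: sum of a state's profile = 100 x state mean total
  # power / grand mean total power
  for (st in c("WAKE", "NREM")) {
    prof <- state_spectral_profile(sp, hyp, st)
    sel <- hyp$states == st
    expected <- 100 * mean(rowSums(sp$power[sel, ])) /
      mean(rowSums(sp$power))
    expect_equal(sum(prof$power_pct), expected, tolerance = 1e-10)
  }

  # NREM profile is delta-dominated under the default signature
  prof_n <- state_spectral_profile(sp, hyp, "NREM")
  delta_bins <- prof_n$freq_hz >= 0.5 & prof_n$freq_hz <= 5
  beta_bins <- prof_n$freq_hz >= 16 & prof_n$freq_hz <= 23
  expect_gt(mean(prof_n$power_pct[delta_bins]),
            mean(prof_n$power_pct[beta_bins]))

  expect_error(state_spectral_profile(sp, hypnogram(rep("WAKE", 450)), "REM"),
               "state absent")
})

test_that("the pooled-day identity of the delta time course holds to 1e-10", {
  cfg <- tiny_config(n_hours = 2, seed = 63, artifact_rate = 0.01)
  hyp <- simulate_hypnogram(cfg)
  sp <- compute_epoch_spectra(simulate_signals(hyp, cfg))
  sp$artifact_mask <- flag_artifacts(sp, hyp = hyp)
  tc <- nrem_delta_timecourse(sp, hyp, bin_h = 1 / 6) # 10-min bins
  use <- !sp$artifact_mask & hyp$states == "NREM"
  pooled <- 100 * mean(band_power(sp, 0.5, 5)[use]) /
    mean(band_power(sp, 0.5, 29)[use])
  weighted <- sum(tc$delta_pct * tc$n_epochs, na.rm = TRUE) / sum(tc$n_epochs)
  expect_equal(weighted, pooled, tolerance = 1e-10)
})

test_that("band powers on flat spectra are proportional to band widths", {
  pw <- matrix(1, nrow = 8, ncol = 127) # 1 unit per bin
  sp <- manual_spectra(pw)
  hyp <- hypnogram(rep("NREM", 8))
  tab <- band_power_by_state(sp, hyp, interval = "light")
  nrem <- tab[tab$state == "NREM", ]
  # bins per band (inclusive 0.25 Hz grid): delta 19, theta 13, sigma 21, beta 29
  widths <- c(delta = 19, theta = 13, sigma = 21, beta = 29)
  expect_equal(nrem$power_pct[match(names(widths), nrem$band)],
               100 * unname(widths) / 127, tolerance = 1e-12)
  # empty state-by-interval cells are missing values
  expect_true(all(is.na(tab$power_pct[tab$state == "REM"])))
})

test_that("theta peak frequency reports the documented tie-break", {
  rec <- tone_recording(7.25, amplitude = 1)
  hyp <- hypnogram(rep("REM", 4))
  sp <- compute_epoch_spectra(rec, taper = "rectangular")
  prof <- state_spectral_profile(sp, hyp, "REM")
  expect_equal(theta_peak_frequency(prof), 7.25)
  flat <- tibble::tibble(freq_hz = seq(0.25, 31.75, 0.25),
                         power_pct = rep(1, 127))
  expect_equal(theta_peak_frequency(flat), 6.0)
  # simulated REM signatures: NAB-vs-LAB peak shift of ~0.8 Hz
  peaks <- vapply(c("NAB", "LAB"), function(ln) {
    cfg <- tiny_config(line = ln, n_hours = 0.5, seed = 64)
    all_r <- hypnogram(rep("REM", 450))
    spr <- compute_epoch_spectra(simulate_signals(all_r, cfg))
    theta_peak_frequency(state_spectral_profile(spr, all_r, "REM"))
  }, numeric(1))
  expect_equal(peaks[["NAB"]] - peaks[["LAB"]], 0.8, tolerance = 0.26)
})
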