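make_features <- function(emg, delta, theta, total) {
  f <- tibble::tibble(
    emg_rms = emg, delta_power = delta, theta_power = theta,
    total_power = total,
    delta_theta_ratio = ifelse(theta > 0, delta / theta, NA_real_),
    theta_total_ratio = ifelse(total > 0, theta / total, NA_real_))
  attr(f, "epoch_length_s") <- 4
  attr(f, "start_zt_s") <- 0
  f
}

fixed_thresholds <- function() {
  structure(list(emg_wake_cut = 2, emg_atonia_cut = 0.7,
                 delta_ratio_cut = 3, theta_ratio_cut = 0.3,
                 s_emg = 0.5, s_theta = 0.1, s_delta = 0.5,
                 method = "fixed"), class = "scoring_thresholds")
}

test_that("feature extraction matches the definitions", {
  n <- 2 * 256
  rec <- signal_recording(list(EEG2 = rnorm(n), EMG = rep(-3, n)), 64)
  sp <- compute_epoch_spectra(rec)
  f <- extract_features(sp, rec)
  expect_equal(f$emg_rms, c(3, 3)) # constant EMG value c -> RMS |c|
  expect_equal(f$total_power, band_power(sp, 0.5, 29))

  # zero EEG: all band powers 0 and ratios undefined (missing)
  rec0 <- signal_recording(list(EEG2 = numeric(n), EMG = rnorm(n)), 64)
  f0 <- extract_features(compute_epoch_spectra(rec0), rec0)
  expect_true(all(f0$delta_power == 0 & f0$total_power == 0))
  expect_true(all(is.na(f0$delta_theta_ratio)))
  expect_true(all(is.na(f0$theta_total_ratio)))

  # misaligned inputs are an error
  rec3 <- signal_recording(list(EEG2 = rnorm(3 * 256), EMG = rnorm(3 * 256)), 64)
  expect_error(extract_features(sp, rec3), "epoch counts differ")
})

test_that("classification follows the rule precedence with nearest-cut fallback", {
  th <- fixed_thresholds()
  f <- make_features(
    emg = c(9, 9, 0.5, 0.5, 1.0, 1.0),
    delta = c(1, 50, 1, 50, 50, 2),
    theta = c(10, 1, 10, 1, 1, 1.9),
    total = c(20, 60, 12, 60, 60, 10))
  hyp <- classify(f, th)
  # 1: high EMG -> WAKE regardless of EEG (REM-like spectrum)
  # 2: high EMG -> WAKE despite NREM-like spectrum
  # 3: atonia + strong theta -> REM
  # 4: atonia but delta-dominant -> NREM
  # 5: intermediate EMG, delta-dominant -> NREM
  expect_identical(as.character(hyp$states)[1:5],
                   c("WAKE", "WAKE", "REM", "NREM", "NREM"))
  # 6: no rule fires (emg 1.0, delta/theta ~1.05, theta/total 0.19);
  # nearest normalized cut decides -> WAKE is 2 MADs away, REM ~ 1.8, NREM ~ 2.1
  d_w <- (log(2) - log(1)) / 0.5
  d_r <- (log(1) - log(0.7)) / 0.5 + (0.3 - 0.19) / 0.1
  d_n <- (log(3) - log(2 / 1.9)) / 0.5
  expect_identical(as.character(hyp$states)[6],
                   c("WAKE", "REM", "NREM")[which.min(c(d_w, d_r, d_n))])
  # pointwise determinism: permuting epochs permutes labels
  perm <- c(3, 1, 2, 6, 5, 4)
  expect_identical(as.character(classify(f[perm, ], th)$states),
                   as.character(hyp$states)[perm])
})

test_that("quantile calibration separates a two-component EMG distribution", {
  set.seed(71)
  emg <- c(exp(rnorm(600, log(3), 0.05)), exp(rnorm(400, log(1), 0.05)))
  f <- make_features(emg, delta = rep(5, 1000), theta = rep(1, 1000),
                     total = rep(10, 1000))
  th <- calibrate_thresholds(f)
  expect_gt(th$emg_wake_cut, 1.3)
  expect_lt(th$emg_wake_cut, 3.1)
  expect_lt(th$emg_atonia_cut, th$emg_wake_cut)

  expect_error(calibrate_thresholds(f[1:50, ]), "at least 100 epochs")
  f_const <- make_features(rep(1, 200), rep(1, 200), rep(1, 200), rep(2, 200))
  expect_error(calibrate_thresholds(f_const), "degenerate")
})

test_that("labeled calibration is at least as accurate as quantile calibration", {
  cfg <- tiny_config(n_hours = 4, seed = 72)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg)
  sp <- compute_epoch_spectra(rec)
  f <- extract_features(sp, rec)
  train <- 1:1800
  test <- 1801:3600
  lab <- as.character(hyp$states)
  lab[test] <- NA
  th_q <- calibrate_thresholds(f, "quantile")
  th_l <- calibrate_thresholds(f, "labeled", labels = lab)
  acc <- function(th) {
    pred <- classify(f, th)
    mean(pred$states[test] == hyp$states[test])
  }
  expect_gte(acc(th_l), acc(th_q) - 1e-9)
  expect_gte(acc(th_l), 0.9)
})

test_that("scale invariance: positive gain on EEG and EMG leaves labels unchanged", {
  cfg <- tiny_config(n_hours = 2, seed = 73)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg)
  sp1 <- compute_epoch_spectra(rec)
  f1 <- extract_features(sp1, rec)
  rec2 <- rec
  rec2$channels$EEG2 <- rec2$channels$EEG2 * 12.5
  rec2$channels$EMG <- rec2$channels$EMG * 0.2
  sp2 <- compute_epoch_spectra(rec2)
  f2 <- extract_features(sp2, rec2)
  l1 <- classify(f1, calibrate_thresholds(f1))
  l2 <- classify(f2, calibrate_thresholds(f2))
  expect_identical(l1$states, l2$states)
})

test_that("smoothing relabels isolated epochs and nothing else", {
  h <- function(x) {
    key <- c(N = "NREM", W = "WAKE", R = "REM")
    hypnogram(unname(key[strsplit(x, "")[[1]]]))
  }
  expect_identical(as.character(smooth_hypnogram(h("NNWNN"))$states),
                   rep("NREM", 5))
  expect_identical(as.character(smooth_hypnogram(h("NWWN"))$states),
                   c("NREM", "WAKE", "WAKE", "NREM"))
  # left-to-right single pass: W at 3 has differing neighbors and survives,
  # R at 4 is isolated between two WAKEs and is relabeled
  expect_identical(as.character(smooth_hypnogram(h("NNWRW"))$states),
                   c("NREM", "NREM", "WAKE", "WAKE", "WAKE"))
  # disabled switch is the identity
  raw <- h("NWNWN")
  expect_identical(smooth_hypnogram(raw, enabled = FALSE)$states, raw$states)
  # on realistic simulations smoothing never rewrites more than a third
  cfg <- tiny_config(n_hours = 2, seed = 74)
  hyp <- simulate_hypnogram(cfg)
  sm <- smooth_hypnogram(hyp)
  expect_lt(mean(sm$states != hyp$states), 1 / 3)
})

test_that("manual corrections are pointwise and audited", {
  hyp <- hypnogram(rep("WAKE", 10))
  expect_identical(apply_corrections(hyp, data.frame()), hyp)
  ed <- data.frame(epoch_index = 4L, state = "REM")
  out <- apply_corrections(hyp, ed)
  expect_identical(as.character(out$states)[5], "REM")
  expect_identical(sum(out$states != hyp$states), 1L)
  expect_equal(attr(out, "corrections")$old, "WAKE")
  expect_error(apply_corrections(hyp, data.frame(epoch_index = 10L,
                                                 state = "REM")),
               "out of range")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(75)
  truth <- hypnogram(sample(c("WAKE", "NREM", "REM"), 500, TRUE,
                            prob = c(.5, .4, .1)))
  noisy <- as.character(truth$states)
  flip <- sample(500, 60)
  noisy[flip] <- sample(c("WAKE", "NREM", "REM"), 60, TRUE)
  ag <- score_agreement(hypnogram(noisy), truth)
  tab <- table(factor(truth$states, c("WAKE", "NREM", "REM")),
               factor(noisy, c("WAKE", "NREM", "REM")))
  expect_equal(ag$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  expect_equal(ag$accuracy, mean(noisy == as.character(truth$states)))
})
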