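#!/usr/bin/env Rscript
# Score the exported example recordings (one animal per line) with the
# self-calibrating classifier and compare against the simulator's
# ground-truth hypnograms. Requires 01_simulate_study.R to have run.

suppressPackageStartupMessages(library(somnarch))

in_dir <- "results/study"
out_dir <- "results/scoring"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (ln in c("NAB", "LAB", "HAB")) {
  edf <- file.path(in_dir, sprintf("%s_ex_baseline.edf", ln))
  if (!file.exists(edf)) stop("run analysis/01_simulate_study.R first")
  rec <- read_recording(edf, "edf")
  truth <- read_hypnogram(file.path(in_dir,
                                    sprintf("%s_ex_baseline_truth.csv", ln)))
  sp <- compute_epoch_spectra(rec)
  sp$artifact_mask <- flag_artifacts(sp)
  feats <- extract_features(sp, rec)
  th <- calibrate_thresholds(feats, method = "quantile")
  scored <- smooth_hypnogram(classify(feats, th))
  write_hypnogram(scored, file.path(out_dir, sprintf("%s_ex_scored.csv", ln)))

  ag <- score_agreement(scored, truth)
  rows[[ln]] <- data.frame(line = ln, accuracy = ag$accuracy,
                           kappa = ag$kappa,
                           wake_recall = ag$recall[["WAKE"]],
                           nrem_recall = ag$recall[["NREM"]],
                           rem_recall = ag$recall[["REM"]])
  cat(sprintf("%s: accuracy %.3f, kappa %.3f, recall W/N/R %.3f/%.3f/%.3f\n",
              ln, ag$accuracy, ag$kappa, ag$recall[["WAKE"]],
              ag$recall[["NREM"]], ag$recall[["REM"]]))
  cat(sprintf("   thresholds: EMG wake >= %.3g, atonia <= %.3g, delta/theta >= %.3g, theta/total >= %.3g\n",
              th$emg_wake_cut, th$emg_atonia_cut, th$delta_ratio_cut,
              th$theta_ratio_cut))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "agreement.csv"),
          row.names = FALSE)
cat("Scored hypnograms and the agreement table are under", out_dir, "\n")
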