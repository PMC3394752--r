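#!/usr/bin/env Rscript
# Simulate the synthetic trait-anxiety sleep study: three mouse lines
# (NAB normal, LAB low, HAB high anxiety-related behavior), ten animals per
# line, each with a 24-h baseline day and a deprivation day (6-h forced wake
# from light onset, 18-h recovery). Hypnograms are written for all animals;
# one example animal per line is additionally exported as full EDF
# recordings with its ground-truth hypnogram CSV.

suppressPackageStartupMessages(library(somnarch))

out_dir <- "results/study"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seeds <- c(NAB = 101, LAB = 102, HAB = 103)
for (ln in names(seeds)) {
  st <- make_study(ln, n_animals = 10, seed = seeds[[ln]], signals = FALSE)
  for (a in st$animals) {
    write_hypnogram(a$baseline$hypnogram,
                    file.path(out_dir, paste0(a$id, "_baseline.csv")))
    write_hypnogram(a$recovery$hypnogram,
                    file.path(out_dir, paste0(a$id, "_recovery.csv")))
  }
  occ <- state_amounts(st$animals[[1]]$baseline$hypnogram, 12)
  cat(sprintf("%s: wrote %d animals; animal 1 light-phase occupancy W/N/R = %s%%\n",
              ln, length(st$animals),
              paste(sprintf("%.1f", occ$percent[occ$zt_bin_start_h == 0]),
                    collapse = "/")))

  # one example animal with full signals, exported as EDF per day
  ex <- simulate_animal(ln, seed = seeds[[ln]] + 500, id = paste0(ln, "_ex"))
  for (day in c("baseline", "recovery")) {
    write_edf(ex[[day]]$recording,
              file.path(out_dir, sprintf("%s_ex_%s.edf", ln, day)))
    write_hypnogram(ex[[day]]$hypnogram,
                    file.path(out_dir, sprintf("%s_ex_%s_truth.csv", ln, day)))
  }
  cat(sprintf("%s: exported example animal EDFs (%s)\n", ln,
              paste0(ln, "_ex_{baseline,recovery}.edf")))
}
cat("Done. Hypnograms and example recordings are under", out_dir, "\n")
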