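#!/usr/bin/env Rscript
# Sleep architecture of the three lines at baseline: state amounts per 12-h
# interval, bout numbers and durations, the six state transitions,
# light/dark amplitudes and sleep latencies, with the study's group
# statistics (one-way ANOVA over lines with Bonferroni post-hocs; Tukey for
# LD amplitudes). Hypnogram-level analysis only, so it runs in seconds.

suppressPackageStartupMessages(library(somnarch))

out_dir <- "results/architecture"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seeds <- c(NAB = 101, LAB = 102, HAB = 103)
per_line <- lapply(names(seeds), function(ln) {
  st <- make_study(ln, n_animals = 10, seed = seeds[[ln]], signals = FALSE)
  res <- lapply(st$animals, function(a) {
    s <- architecture_summary(a$baseline$hypnogram)
    list(states = cbind(line = ln, animal = a$id, s$states),
         transitions = cbind(line = ln, animal = a$id, s$transitions),
         latency = cbind(line = ln, animal = a$id, s$latency),
         ld = cbind(line = ln, animal = a$id, s$ld))
  })
  lapply(setNames(nm = c("states", "transitions", "latency", "ld")),
         function(k) do.call(rbind, lapply(res, `[[`, k)))
})
tabs <- lapply(setNames(nm = c("states", "transitions", "latency", "ld")),
               function(k) do.call(rbind, lapply(per_line, `[[`, k)))
for (k in names(tabs)) {
  write.csv(tabs[[k]], file.path(out_dir, paste0(k, ".csv")), row.names = FALSE)
}

cat("== Percent time per state, 12-h means ==\n")
agg <- aggregate(percent_time ~ line + interval + state, tabs$states, mean)
print(format(agg, digits = 3), row.names = FALSE)

cat("\n== Fragmentation: total transitions per 12 h ==\n")
tot <- aggregate(count ~ line + interval + animal, tabs$transitions, sum)
print(aggregate(count ~ line + interval, tot, mean), row.names = FALSE)
for (interval in c("light", "dark")) {
  d <- tot[tot$interval == interval, ]
  names(d)[names(d) == "count"] <- "value"
  gc <- group_compare(d, factors = "line", posthoc = "bonferroni")
  cat(sprintf("one-way ANOVA (%s): F = %.2f, p = %.2g\n", interval,
              gc$anova$F[1], gc$anova$p[1]))
}

cat("\n== Baseline NREM latency (min) ==\n")
lat <- tabs$latency[tabs$latency$target == "NREM", ]
print(aggregate(latency_min ~ line, lat, median), row.names = FALSE)

cat("\n== Light-dark amplitude of wake occupancy, Tukey HSD ==\n")
ldw <- tabs$ld[tabs$ld$state == "WAKE", ]
names(ldw)[names(ldw) == "ld_amplitude"] <- "value"
gc <- group_compare(ldw, factors = "line", posthoc = "tukey")
print(gc$posthoc$tukey, row.names = FALSE)

cat("\nTables written under", out_dir, "\n")
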