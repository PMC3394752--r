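#!/usr/bin/env Rscript
# Sleep-deprivation rebound: recovery-minus-baseline differences in NREM and
# REM amounts and normalized NREM delta power (2-h and 6-h bins), paired
# baseline-vs-recovery t-tests per line, and the two-way line-by-interval
# ANOVA on the first-6-h rebound. Six animals per line with full signals;
# the streaming runner keeps memory flat.

suppressPackageStartupMessages(library(somnarch))

out_dir <- "results/rebound"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seeds <- c(NAB = 401, LAB = 402, HAB = 403)
studies <- lapply(names(seeds), function(ln) {
  run_line_study(ln, n_animals = 6, seed = seeds[[ln]], score = FALSE)
})
names(studies) <- names(seeds)

rebound <- do.call(rbind, lapply(studies, function(s) s$rebound))
write.csv(rebound, file.path(out_dir, "rebound_2h.csv"), row.names = FALSE)

cat("== First-6-h recovery-minus-baseline delta power (%) ==\n")
r6 <- rebound[rebound$measure == "delta_pct" & rebound$zt_bin_start_h >= 6 &
                rebound$zt_bin_start_h < 12, ]
per_animal <- aggregate(difference ~ line + animal, r6, mean)
print(aggregate(difference ~ line, per_animal, mean), row.names = FALSE)

names(per_animal)[names(per_animal) == "difference"] <- "value"
gc <- group_compare(per_animal, factors = "line", posthoc = "bonferroni")
cat(sprintf("one-way ANOVA over lines: F = %.2f, p = %.3g\n",
            gc$anova$F[1], gc$anova$p[1]))
print(gc$posthoc$bonferroni, row.names = FALSE)

cat("\n== Paired baseline-vs-recovery delta power (first 6 h of recovery vs same ZT) ==\n")
d6 <- do.call(rbind, lapply(studies, function(s) {
  r <- s$rebound[s$rebound$measure == "delta_pct", ]
  r <- r[r$zt_bin_start_h >= 6 & r$zt_bin_start_h < 12, ]
  agg_b <- aggregate(baseline ~ line + animal, r, mean)
  agg_r <- aggregate(recovery ~ line + animal, r, mean)
  rbind(data.frame(line = agg_b$line, animal = agg_b$animal,
                   day = "baseline", value = agg_b$baseline),
        data.frame(line = agg_r$line, animal = agg_r$animal,
                   day = "recovery", value = agg_r$recovery))
}))
print(paired_t_by_group(d6), row.names = FALSE)

cat("\n== Two-way ANOVA on 6-h NREM rebound: line x interval ==\n")
rn <- rebound[rebound$measure == "nrem_pct" & !rebound$in_sd_window, ]
rn$interval6 <- sprintf("ZT%02d", 6 * (rn$zt_bin_start_h %/% 6))
agg <- aggregate(difference ~ line + animal + interval6, rn, mean)
names(agg)[names(agg) == "difference"] <- "value"
names(agg)[names(agg) == "interval6"] <- "interval"
gc2 <- group_compare(agg, factors = c("line", "interval"))
print(gc2$anova, row.names = FALSE)

cat("\nTables written under", out_dir, "\n")
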