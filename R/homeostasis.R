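#' Per-bin sleep measures for one day
#'
#' The three rebound measures in ZT bins of `bin_h` hours: percent time in
#' NREM and REM, and (when spectra are supplied) normalized NREM delta power.
#' For recovery days pass the baseline day's `normalizer` so delta power is
#' expressed on the baseline scale.
#'
#' @param hyp a [hypnogram()] of one day.
#' @param spectra optional aligned `epoch_spectra`.
#' @param bin_h bin width in hours (2 or 6).
#' @param normalizer reference scalar for delta normalization (see
#'   [nrem_power_normalizer()]); computed from this day when `NULL`.
#' @return tibble with `measure` (`nrem_pct`, `rem_pct`, `delta_pct`),
#'   `zt_bin_start_h`, `value`.
#' @export
bin_measures <- function(hyp, spectra = NULL, bin_h = 6, normalizer = NULL) {
  am <- state_amounts(hyp, bin_h)
  out <- rbind(
    tibble::tibble(measure = "nrem_pct",
                   zt_bin_start_h = am$zt_bin_start_h[am$state == "NREM"],
                   value = am$percent[am$state == "NREM"]),
    tibble::tibble(measure = "rem_pct",
                   zt_bin_start_h = am$zt_bin_start_h[am$state == "REM"],
                   value = am$percent[am$state == "REM"]))
  if (!is.null(spectra)) {
    tc <- nrem_delta_timecourse(spectra, hyp, bin_h, normalizer = normalizer)
    out <- rbind(out, tibble::tibble(measure = "delta_pct",
                                     zt_bin_start_h = tc$zt_bin_start_h,
                                     value = tc$delta_pct))
  }
  out
}

#' Recovery-minus-baseline rebound differences
#'
#' Joins two ZT-aligned per-bin measure tables from the same animal and
#' subtracts: `difference = recovery - baseline` per matched (measure, bin).
#' Bins lying fully inside the deprivation window (`[0, sd_end_h)` of the
#' recovery day) are flagged `in_sd_window`; they are reported (wake
#' enforcement QC) but must be excluded from sleep-rebound statistics. A
#' difference is defined only where both days have a defined value.
#'
#' @param baseline_summary,recovery_summary tibbles from [bin_measures()].
#' @param sd_end_h end of the deprivation window, hours after lights-on.
#' @return tibble with `measure`, `zt_bin_start_h`, `baseline`, `recovery`,
#'   `difference`, `in_sd_window`.
#' @export
rebound_differences <- function(baseline_summary, recovery_summary,
                                sd_end_h = 6) {
  key <- function(d) paste(d$measure, d$zt_bin_start_h)
  if (nrow(baseline_summary) != nrow(recovery_summary) ||
      !setequal(key(baseline_summary), key(recovery_summary))) {
    stop("ZT misalignment: baseline and recovery summaries do not share bins")
  }
  b <- baseline_summary[order(key(baseline_summary)), ]
  r <- recovery_summary[order(key(recovery_summary)), ]
  bin_w <- diff(sort(unique(b$zt_bin_start_h)))
  bin_w <- if (length(bin_w)) min(bin_w) else 24
  out <- tibble::tibble(
    measure = b$measure, zt_bin_start_h = b$zt_bin_start_h,
    baseline = b$value, recovery = r$value,
    difference = r$value - b$value,
    in_sd_window = b$zt_bin_start_h >= 0 & (b$zt_bin_start_h + bin_w) <= sd_end_h)
  out[order(out$measure, out$zt_bin_start_h), ]
}

#' Post-deprivation sleep latency
#'
#' The latency rule applied from the end of the deprivation period (ZT6 for
#' the standard 6-h protocol) on the recovery day's hypnogram.
#'
#' @param hyp_recovery recovery-day [hypnogram()] (ZT starting at 0).
#' @param sd_end_zt_s deprivation end, seconds after lights-on.
#' @param target `"NREM"` or `"REM"`.
#' @param ... passed to [sleep_latency()].
#' @export
post_sd_latency <- function(hyp_recovery, sd_end_zt_s = 21600,
                            target = c("NREM", "REM"), ...) {
  sleep_latency(hyp_recovery, sd_end_zt_s, target, ...)
}

#' Group statistics for line comparisons
#'
#' The study's statistics surface over a tidy per-animal table: one-way
#' fixed-effects ANOVA (factor `line`), or two-way with `line` and
#' `interval`, with Bonferroni-adjusted pairwise t-tests and/or Tukey HSD
#' post-hocs; paired two-tailed t-tests for baseline-vs-recovery contrasts
#' are available via [paired_t_by_group()]. Degenerate inputs (no residual
#' variance) are reported as non-testable rather than crashing.
#'
#' @param data data frame with a numeric `value` column and the factor
#'   columns named in `factors`.
#' @param factors one factor name (one-way) or two (two-way with
#'   interaction).
#' @param posthoc any of `"bonferroni"`, `"tukey"` (applied to the first
#'   factor).
#' @param alpha significance level recorded in the report.
#' @return list of class `group_stats`: `testable`, `anova` (term, df, F, p),
#'   `posthoc` tibbles.
#' @export
group_compare <- function(data, factors = "line",
                          posthoc = c("bonferroni", "tukey"), alpha = 0.05) {
  posthoc <- match.arg(posthoc, several.ok = TRUE)
  stopifnot(all(factors %in% names(data)), "value" %in% names(data))
  data <- data[complete.cases(data[c("value", factors)]), , drop = FALSE]
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(data[factors], nlevels, 1L) < 2) ||
      min(table(data[factors])) < 2) {
    stop("need >= 2 groups with >= 2 observations each")
  }
  if (sd(data$value) == 0) {
    return(structure(list(testable = FALSE, alpha = alpha,
                          reason = "degenerate variance: all values equal",
                          anova = NULL, posthoc = NULL),
                     class = "group_stats"))
  }
  fml <- stats::as.formula(paste("value ~", paste(factors, collapse = " * ")))
  fit <- aov(fml, data = data)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  an <- tibble::tibble(term = terms, df = sm$Df, F = sm$`F value`,
                       p = sm$`Pr(>F)`)
  ph <- list()
  if ("bonferroni" %in% posthoc) {
    pt <- pairwise.t.test(data$value, data[[factors[1]]],
                          p.adjust.method = "bonferroni", pool.sd = FALSE)
    m <- pt$p.value
    ph$bonferroni <- tibble::tibble(
      group1 = rep(rownames(m), ncol(m)), group2 = rep(colnames(m), each = nrow(m)),
      p_adj = as.numeric(m))
    ph$bonferroni <- ph$bonferroni[!is.na(ph$bonferroni$p_adj), ]
  }
  if ("tukey" %in% posthoc) {
    tk <- TukeyHSD(fit, which = factors[1])[[factors[1]]]
    ph$tukey <- tibble::tibble(contrast = rownames(tk),
                               diff = tk[, "diff"], p_adj = tk[, "p adj"])
  }
  structure(list(testable = TRUE, alpha = alpha, anova = an, posthoc = ph),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  if (!x$testable) {
    cat("<group_stats> non-testable:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<group_stats> alpha =", x$alpha, "\n")
  print(x$anova)
  for (nm in names(x$posthoc)) {
    cat("post-hoc (", nm, "):\n", sep = "")
    print(x$posthoc[[nm]])
  }
  invisible(x)
}

#' Paired two-tailed t-tests per line
#'
#' Baseline-versus-recovery contrast within each line: a paired two-tailed
#' t-test over animals.
#'
#' @param data data frame with columns `line`, `animal`, `day` (two levels)
#'   and `value`.
#' @param days the two day labels, baseline first.
#' @return tibble with `line`, `n`, `mean_difference`, `t`, `p` (lines whose
#'   differences are constant are reported with `NA` statistics).
#' @export
paired_t_by_group <- function(data, days = c("baseline", "recovery")) {
  lines <- unique(as.character(data$line))
  res <- lapply(lines, function(ln) {
    d <- data[data$line == ln, ]
    b <- d$value[match(paste(unique(d$animal), days[1]),
                       paste(d$animal, d$day))]
    r <- d$value[match(paste(unique(d$animal), days[2]),
                       paste(d$animal, d$day))]
    ok <- stats::complete.cases(b, r)
    b <- b[ok]; r <- r[ok]
    if (length(b) < 2 || sd(r - b) == 0) {
      return(tibble::tibble(line = ln, n = length(b),
                            mean_difference = if (length(b)) mean(r - b) else NA_real_,
                            t = NA_real_, p = NA_real_))
    }
    tt <- t.test(r, b, paired = TRUE)
    tibble::tibble(line = ln, n = length(b), mean_difference = mean(r - b),
                   t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, res)
}
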