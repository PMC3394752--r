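h_of <- function(x, start_zt_s = 0) {
  key <- c(N = "NREM", W = "WAKE", R = "REM")
  hypnogram(unname(key[strsplit(x, "")[[1]]]), 4, start_zt_s)
}

test_that("bout detection returns maximal runs", {
  b <- detect_bouts(h_of("WWNNNRW"))
  expect_identical(b$state, c("WAKE", "NREM", "REM", "WAKE"))
  expect_identical(b$length_epochs, c(2L, 3L, 1L, 1L))
  expect_identical(b$start_epoch, c(0L, 2L, 5L, 6L))
  # a constant interval is exactly one full-length bout
  b1 <- detect_bouts(hypnogram(rep("REM", 50)))
  expect_identical(nrow(b1), 1L)
  expect_identical(b1$length_epochs, 50L)
  # runs spanning the light/dark boundary are clipped to each side
  hyp <- hypnogram(rep("NREM", 100), 4, start_zt_s = 43200 - 200)
  bl <- detect_bouts(hyp, "light")
  bd <- detect_bouts(hyp, "dark")
  expect_identical(bl$length_epochs, 50L)
  expect_identical(bd$length_epochs, 50L)
})

test_that("bout detection equals the boundary-scan oracle on random hypnograms", {
  set.seed(81)
  for (i in 1:120) {
    hyp <- random_hypnogram(sample(50:400, 1),
                            mode = sample(c("iid", "markov"), 1),
                            na_rate = sample(c(0, 0.03), 1))
    for (interval in c("all", "light", "dark")) {
      got <- detect_bouts(hyp, interval)
      want <- oracle_bouts(hyp, interval)
      expect_identical(got$state, want$state)
      expect_identical(got$start_epoch, want$start_epoch)
      expect_identical(as.integer(got$length_epochs),
                       as.integer(want$length_epochs))
    }
  }
})

test_that("transition counts match the pairwise definition", {
  tr <- count_transitions(h_of("WNWN"))
  cnt <- function(t, from, to) t$count[t$from == from & t$to == to]
  expect_identical(cnt(tr, "WAKE", "NREM"), 2L)
  expect_identical(cnt(tr, "NREM", "WAKE"), 1L)
  expect_identical(sum(tr$count), 3L)
  expect_identical(sum(count_transitions(hypnogram(rep("WAKE", 20)))$count), 0L)
  # straddling pairs belong to the interval of the later epoch
  hyp <- hypnogram(c(rep("WAKE", 5), rep("NREM", 5)), 4, 43200 - 20)
  expect_identical(sum(count_transitions(hyp, "light")$count), 0L)
  expect_identical(sum(count_transitions(hyp, "dark")$count), 1L)
})

test_that("transitions equal the per-pair oracle and the boundary identity holds", {
  set.seed(82)
  for (i in 1:120) {
    hyp <- random_hypnogram(sample(50:400, 1), mode = "markov",
                            na_rate = sample(c(0, 0.02), 1))
    for (interval in c("light", "dark", "all")) {
      got <- count_transitions(hyp, interval)
      want <- oracle_transitions(hyp, interval)
      expect_equal(got$count, as.integer(want$count))
    }
    # boundary identity (NA-free case): with straddling pairs credited to
    # the later interval, every bout of state X inside an interval receives
    # exactly one incoming transition, except bouts that open the recording
    # or continue a same-state run from the previous interval
    if (!any(is.na(hyp$states))) {
      s <- as.character(hyp$states)
      for (interval in c("light", "dark")) {
        tr <- count_transitions(hyp, interval)
        b <- detect_bouts(hyp, interval)
        for (st in c("WAKE", "NREM", "REM")) {
          incoming <- sum(tr$count[tr$to == st])
          bs <- b[b$state == st, ]
          no_inflow <- bs$start_epoch == 0 |
            s[pmax(bs$start_epoch, 1)] == st # predecessor continues the run
          expect_identical(as.integer(incoming),
                           as.integer(nrow(bs) - sum(no_inflow)))
        }
      }
    }
  }
})

test_that("state amounts are exact percentages per bin", {
  expect_equal(state_amounts(hypnogram(rep("WAKE", 900)), 1)$percent,
               c(100, 0, 0))
  alt <- hypnogram(rep(c("WAKE", "NREM"), 450))
  expect_equal(state_amounts(alt, 1)$percent, c(50, 50, 0))
  # counting oracle on random hypnograms with NA epochs
  set.seed(83)
  hyp <- random_hypnogram(2 * 1800, mode = "markov", na_rate = 0.05)
  am <- state_amounts(hyp, 1)
  for (b in unique(am$zt_bin_start_h)) {
    idx <- which(floor(zt_of_epoch(hyp) / 3600) == b)
    for (st in c("WAKE", "NREM", "REM")) {
      expect_equal(am$percent[am$zt_bin_start_h == b & am$state == st],
                   100 * sum(hyp$states[idx] == st, na.rm = TRUE) / length(idx))
    }
    # states plus excluded artifact fraction account for every epoch
    expect_equal(sum(am$percent[am$zt_bin_start_h == b]) +
                   100 * mean(is.na(hyp$states[idx])), 100)
  }
})

test_that("light-dark amplitude has the defining sign behavior", {
  day <- hypnogram(c(rep("NREM", 10800), rep("WAKE", 10800)))
  la <- ld_amplitude(day)
  expect_equal(la$ld_amplitude[la$state == "NREM"], 100)
  expect_equal(la$ld_amplitude[la$state == "WAKE"], -100)
  # identical occupancy in both halves gives zero amplitude
  both <- hypnogram(rep(c("WAKE", "NREM"), 10800))
  expect_equal(ld_amplitude(both)$ld_amplitude, c(0, 0, 0))
  # swapping the intervals flips the sign
  swapped <- hypnogram(c(rep("WAKE", 10800), rep("NREM", 10800)))
  expect_equal(ld_amplitude(swapped)$ld_amplitude,
               -ld_amplitude(day)$ld_amplitude)
  # hand fixture: 75/25 wake in light, 25/75 in dark
  mix <- hypnogram(c(rep(c("WAKE", "WAKE", "WAKE", "NREM"), 2700),
                     rep(c("WAKE", "NREM", "NREM", "NREM"), 2700)))
  la2 <- ld_amplitude(mix)
  expect_equal(la2$ld_amplitude[la2$state == "WAKE"], 50)
  expect_equal(la2$ld_amplitude[la2$state == "NREM"], -50)
})

test_that("sleep latency implements the episode rule", {
  # 10 wake epochs then solid NREM: latency 10 * 4 / 60 min
  hyp <- hypnogram(c(rep("WAKE", 10), rep("NREM", 20)))
  expect_equal(sleep_latency(hyp, 0, "NREM"), 10 * 4 / 60)
  expect_equal(sleep_latency(hyp, 0, "REM"), NA_real_)
  expect_true(is.na(sleep_latency(hypnogram(rep("WAKE", 100)), 0, "NREM")))
  expect_error(sleep_latency(hyp, 400, "NREM"), "outside")
  expect_error(sleep_latency(hyp, 2, "NREM"), "epoch boundary")

  # interruptions: N8 W7 N8 has a 7-epoch gap > 6 allowance, no qualifying
  # window of span 15 from the first run; the second run is only 8 long
  frag <- h_of(paste0(strrep("N", 8), strrep("W", 7), strrep("N", 8)))
  expect_true(is.na(sleep_latency(frag, 0, "NREM")))
  # but a 6-epoch gap qualifies from the first epoch
  frag2 <- h_of(paste0(strrep("N", 8), strrep("W", 6), strrep("N", 8)))
  expect_equal(sleep_latency(frag2, 0, "NREM"), 0)

  # net rule: span reading accepts 9 target epochs in a 15-epoch span,
  # net reading demands 15 target epochs
  mixed <- h_of(paste0(strrep("N", 5), strrep("W", 6), strrep("N", 20)))
  expect_equal(sleep_latency(mixed, 0, "NREM", rule = "span"), 0)
  expect_equal(sleep_latency(mixed, 0, "NREM", rule = "net"), 0)
  # 15-epoch span holding 9 target epochs and 6 interruptions
  sparse <- h_of(paste0("NWNWNWNWNWNW", strrep("N", 3), strrep("W", 20)))
  expect_equal(sleep_latency(sparse, 0, "NREM", rule = "span"), 0)
  expect_true(is.na(sleep_latency(sparse, 0, "NREM", rule = "net")))

  # nonzero reference: scan starts there
  late <- hypnogram(c(rep("NREM", 20), rep("WAKE", 10), rep("NREM", 20)))
  expect_equal(sleep_latency(late, 80, "NREM"), 10 * 4 / 60)
})

test_that("latency equals the brute-force oracle on random hypnograms", {
  set.seed(84)
  for (i in 1:300) {
    hyp <- random_hypnogram(sample(60:600, 1),
                            mode = sample(c("iid", "markov"), 1),
                            na_rate = sample(c(0, 0.05), 1))
    for (target in c("NREM", "REM")) {
      expect_equal(sleep_latency(hyp, 0, target),
                   oracle_latency(hyp, 0, target))
    }
  }
})

test_that("latency is antitone in the allowance and isotone in the span", {
  set.seed(85)
  for (i in 1:40) {
    hyp <- random_hypnogram(600, mode = "markov")
    big <- 1e9 # stands in for "no qualifying episode"
    l_allow <- vapply(c(0, 3, 6, 9), function(a) {
      v <- sleep_latency(hyp, 0, "NREM", max_interrupt_epochs = a)
      if (is.na(v)) big else v
    }, numeric(1))
    expect_true(all(diff(l_allow) <= 0))
    l_span <- vapply(c(5, 10, 15, 25), function(m) {
      v <- sleep_latency(hyp, 0, "NREM", min_span_epochs = m)
      if (is.na(v)) big else v
    }, numeric(1))
    expect_true(all(diff(l_span) >= 0))
  }
})

test_that("bout lengths conserve the interval and summaries are consistent", {
  set.seed(86)
  for (i in 1:30) {
    hyp <- random_hypnogram(2 * 10800, mode = "markov") # one full day
    for (interval in c("light", "dark")) {
      b <- detect_bouts(hyp, interval)
      expect_identical(sum(b$length_epochs), 10800L)
    }
    s <- architecture_summary(hyp)
    expect_equal(sum(s$states$percent_time), 200, tolerance = 1e-9)
    for (interval in c("light", "dark")) {
      st <- s$states[s$states$interval == interval, ]
      expect_equal(sum(st$bout_count * st$mean_bout_duration_min, na.rm = TRUE),
                   10800 * 4 / 60, tolerance = 1e-9)
    }
  }
})
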