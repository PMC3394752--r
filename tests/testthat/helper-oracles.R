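# Independent brute-force oracles and fixture builders. These deliberately
# take different algorithmic routes than the package implementation: bouts
# by run-length encoding of interval-segmented keys instead of a boundary
# scan, transitions by per-pair logical sums instead of pair tabulation,
# latency by a literal forward scan of the episode rule.

# Maximal runs via base rle() on a numeric key that changes with the state,
# with NA/invalid epochs, and with the interval segment (so runs clip at
# interval boundaries).
oracle_bouts <- function(hyp, interval = "all") {
  member <- somnarch::interval_epochs(hyp, interval)
  code <- as.integer(hyp$states)
  seg <- cumsum(c(TRUE, diff(member) != 0)) # interval block id
  key <- code + 4 * seg
  key[!member | is.na(code)] <- NA
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !is.na(r$values)
  data.frame(state = c("WAKE", "NREM", "REM")[(r$values[keep] - 1) %% 4 + 1],
             start_epoch = starts[keep] - 1L,
             length_epochs = r$lengths[keep])
}

# Ordered-pair counts by direct logical sums.
oracle_transitions <- function(hyp, interval = "all") {
  states <- c("WAKE", "NREM", "REM")
  code <- as.integer(factor(as.character(hyp$states), states))
  n <- length(code)
  member <- somnarch::interval_epochs(hyp, interval)
  out <- expand.grid(from = states, to = states, stringsAsFactors = FALSE)
  out <- out[out$from != out$to, ]
  out <- out[order(match(out$from, states), match(out$to, states)), ]
  a <- code[-n]
  b <- code[-1]
  ok <- !is.na(a) & !is.na(b) & member[-1]
  out$count <- vapply(seq_len(nrow(out)), function(k) {
    sum(ok & a == match(out$from[k], states) & b == match(out$to[k], states))
  }, numeric(1))
  rownames(out) <- NULL
  out
}

# Literal reading of the latency rule: from the reference, try every
# target-state window start in order; a start qualifies if some later
# target-state epoch closes a window of span >= min_span containing at most
# max_int non-target epochs. The scan from each start can stop once the
# interruption budget is exhausted.
oracle_latency <- function(hyp, reference_zt_s, target,
                           min_span = 15, max_int = 6) {
  r <- as.integer((reference_zt_s - hyp$start_zt_s) / hyp$epoch_length_s)
  s <- as.character(hyp$states)[(r + 1L):length(hyp$states)]
  m <- !is.na(s) & s == target
  n <- length(m)
  for (st in which(m)) {
    bad <- 0L
    e <- st
    while (e <= n && bad <= max_int) {
      if (!m[e]) bad <- bad + 1L
      else if (e - st + 1L >= min_span && bad <= max_int) {
        return((st - 1L) * hyp$epoch_length_s / 60)
      }
      e <- e + 1L
    }
  }
  NA_real_
}

# Random hypnograms: either iid-uniform states or runs from a random Markov
# chain (more realistic run-length structure).
random_hypnogram <- function(n, mode = c("iid", "markov"), na_rate = 0) {
  mode <- match.arg(mode)
  states <- c("WAKE", "NREM", "REM")
  if (mode == "iid") {
    s <- sample(states, n, replace = TRUE)
  } else {
    stay <- runif(3, 0.6, 0.98)
    s <- character(n)
    cur <- sample.int(3, 1)
    for (i in seq_len(n)) {
      s[i] <- states[cur]
      if (runif(1) > stay[cur]) cur <- sample(setdiff(1:3, cur), 1)
    }
  }
  art <- runif(n) < na_rate
  s[art] <- NA
  somnarch::hypnogram(s, 4, 0, artifact = art)
}

# Pure-tone recording (plus a dummy EMG channel) for spectral tests.
tone_recording <- function(freq_hz, amplitude = 1, n_epochs = 4, fs = 64,
                           epoch_s = 4, phase = 0) {
  n <- n_epochs * fs * epoch_s
  t <- (seq_len(n) - 1) / fs
  signal_recording(list(EEG1 = amplitude * sin(2 * pi * freq_hz * t + phase),
                        EEG2 = amplitude * sin(2 * pi * freq_hz * t + phase),
                        EMG = rep(0.1, n)),
                   sampling_rate_hz = fs)
}

# Hand-buildable epoch_spectra object for arithmetic-oracle tests.
manual_spectra <- function(power, fs = 64, epoch_s = 4, start_zt_s = 0) {
  nf <- ncol(power)
  structure(list(power = power, freq_hz = seq_len(nf) * fs / (fs * epoch_s),
                 bin_width_hz = fs / (fs * epoch_s),
                 artifact_mask = rep(FALSE, nrow(power)),
                 epoch_length_s = epoch_s, start_zt_s = start_zt_s,
                 taper = "manual", channel = "EEG2"),
            class = "epoch_spectra")
}

# Small, fast simulation config shared across tests.
tiny_config <- function(..., line = "NAB", n_hours = 1, seed = 1,
                        artifact_rate = 0) {
  archetype_config(line, n_hours = n_hours, seed = seed,
                   artifact_rate = artifact_rate, ...)
}
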