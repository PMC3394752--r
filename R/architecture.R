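#' Detect bouts (maximal same-state runs)
#'
#' A bout is a maximal run of consecutive epochs in one state. Restricted to
#' an interval, runs are clipped at the interval boundary: a run spanning the
#' light/dark boundary contributes a clipped bout to each side. Artifact
#' epochs count as their best-guess state; epochs with no underlying state
#' (`NA`) break runs and belong to no bout.
#'
#' @param hyp a [hypnogram()].
#' @param interval `"all"`, `"light"` or `"dark"`.
#' @return tibble with `state`, `start_epoch` (0-based), `length_epochs`,
#'   `zt_start_s`.
#' @export
detect_bouts <- function(hyp, interval = c("all", "light", "dark")) {
  interval <- match.arg(interval)
  member <- interval_epochs(hyp, interval)
  code <- as.integer(hyp$states)
  n <- length(code)
  valid <- member & !is.na(code)
  # boundary scan: an epoch continues the previous run iff both epochs are
  # usable, share the state, and sit in the same interval block
  cont <- c(FALSE, valid[-1] & valid[-n] & code[-1] == code[-n] &
              member[-1] == member[-n])
  starts <- which(valid & !cont)
  ends <- which(valid & !c(cont[-1], FALSE))
  tibble::tibble(
    state = SOMN_STATES[code[starts]],
    start_epoch = starts - 1L,
    length_epochs = ends - starts + 1L,
    zt_start_s = zt_of_epoch(hyp, starts - 1L))
}

#' Count ordered state transitions
#'
#' Counts adjacent epoch pairs `(i, i+1)` with differing states, per ordered
#' pair of distinct states. A pair straddling the interval boundary is
#' credited to the interval containing epoch `i+1`. Pairs involving an
#' `NA`-state epoch are ignored.
#'
#' @param hyp a [hypnogram()].
#' @param interval `"all"`, `"light"` or `"dark"`.
#' @return tibble with `from`, `to`, `count` (six ordered pairs).
#' @export
count_transitions <- function(hyp, interval = c("all", "light", "dark")) {
  interval <- match.arg(interval)
  code <- as.integer(hyp$states)
  n <- length(code)
  out <- expand.grid(from = SOMN_STATES, to = SOMN_STATES,
                     stringsAsFactors = FALSE)
  out <- out[out$from != out$to, ]
  out <- out[order(match(out$from, SOMN_STATES), match(out$to, SOMN_STATES)), ]
  rownames(out) <- NULL
  if (n < 2) {
    out$count <- 0L
    return(tibble::as_tibble(out))
  }
  a <- code[-n]; b <- code[-1]
  member <- interval_epochs(hyp, interval)[-1] # membership of epoch i+1
  sel <- member & !is.na(a) & !is.na(b) & a != b
  tab <- tabulate((a[sel] - 1L) * 3L + b[sel], nbins = 9L)
  cell <- (match(out$from, SOMN_STATES) - 1L) * 3L + match(out$to, SOMN_STATES)
  out$count <- tab[cell]
  tibble::as_tibble(out)
}

#' Percent time per state in ZT bins
#'
#' Per bin of `bin_h` hours (from the recording start): 100 x epochs in
#' state / epochs in bin. The denominator counts every epoch, so the three
#' state percentages plus the excluded (`NA`-state) fraction sum to 100.
#'
#' @param hyp a [hypnogram()].
#' @param bin_h bin width in hours (2 and 12 in the standard analyses).
#' @return tibble with `zt_bin_start_h`, `state`, `percent`.
#' @export
state_amounts <- function(hyp, bin_h = 12) {
  zt <- zt_of_epoch(hyp)
  bin <- floor((zt - zt[1]) / (bin_h * 3600))
  bins <- sort(unique(bin))
  res <- lapply(bins, function(b) {
    in_bin <- bin == b
    tab <- table(factor(hyp$states[in_bin], SOMN_STATES))
    tibble::tibble(zt_bin_start_h = (zt[1] + b * bin_h * 3600) / 3600,
                   state = SOMN_STATES,
                   percent = 100 * as.numeric(tab) / sum(in_bin))
  })
  do.call(rbind, res)
}

#' Light-minus-dark amplitude of state occupancy
#'
#' The circadian rhythmicity index per state: percent time in the light
#' interval minus percent time in the dark interval.
#'
#' @param hyp a [hypnogram()] covering both intervals (one 24-h day).
#' @return tibble with `state`, `light_pct`, `dark_pct`, `ld_amplitude`.
#' @export
ld_amplitude <- function(hyp) {
  pct <- function(interval) {
    sel <- interval_epochs(hyp, interval)
    tab <- table(factor(hyp$states[sel], SOMN_STATES))
    100 * as.numeric(tab) / sum(sel)
  }
  l <- pct("light"); d <- pct("dark")
  tibble::tibble(state = SOMN_STATES, light_pct = l, dark_pct = d,
                 ld_amplitude = l - d)
}

#' Latency to consolidated sleep
#'
#' Scans forward from a reference time for the earliest consolidated episode
#' of the target state: a window that starts and ends with a target-state
#' epoch, spans at least `min_span_epochs` epochs, and contains at most
#' `max_interrupt_epochs` non-target epochs in total (the default reads the
#' 15-epoch minimum as the episode's span, interruptions included; the
#' `"net"` rule instead requires 15 target epochs net of interruptions).
#' Latency is the time from the reference to the window start, in minutes;
#' `NA` if no qualifying window exists. Artifact epochs count as their
#' best-guess state; `NA`-state epochs count as non-target.
#'
#' @param hyp a [hypnogram()].
#' @param reference_zt_s reference time (light onset 0, or end of sleep
#'   deprivation); must fall on an epoch boundary inside the hypnogram.
#' @param target `"NREM"` or `"REM"`.
#' @param min_span_epochs minimum episode extent (epochs).
#' @param max_interrupt_epochs allowed non-target epochs inside the episode.
#' @param rule `"span"` (default) or `"net"` (see above).
#' @return latency in minutes, or `NA_real_`.
#' @export
sleep_latency <- function(hyp, reference_zt_s = 0, target = c("NREM", "REM"),
                          min_span_epochs = 15, max_interrupt_epochs = 6,
                          rule = c("span", "net")) {
  target <- match.arg(target)
  rule <- match.arg(rule)
  r <- (reference_zt_s - hyp$start_zt_s) / hyp$epoch_length_s
  if (abs(r - round(r)) > 1e-9) stop("reference does not fall on an epoch boundary")
  r <- as.integer(round(r))
  n <- n_epochs(hyp)
  if (r < 0 || r >= n) stop("reference outside hypnogram")
  s <- as.character(hyp$states)[(r + 1L):n]
  m <- !is.na(s) & s == target
  if (!any(m)) return(NA_real_)
  nn <- length(m)
  nt <- cumsum(!m) # non-target count in [1, j]
  tt <- cumsum(m)
  starts <- which(m)
  # widest admissible end per start: last j with nt[j] - nt[start] <= allowance
  e_max <- findInterval(nt[starts] + max_interrupt_epochs + 0.5, nt)
  # last target position at or before j
  last_t <- integer(nn)
  last_t[m] <- which(m)
  last_t <- cummax(last_t)
  q_end <- last_t[e_max]
  ok <- if (rule == "span") {
    q_end >= starts + min_span_epochs - 1L
  } else {
    tpos <- which(m)
    need <- tt[starts] - 1L + min_span_epochs # index of the required target
    e_min <- ifelse(need <= length(tpos), tpos[pmin(need, length(tpos))], NA)
    !is.na(e_min) & e_min <= e_max
  }
  if (!any(ok)) return(NA_real_)
  (starts[which(ok)[1]] - 1L) * hyp$epoch_length_s / 60
}

#' Full architecture summary of one day
#'
#' Per state and 12-h interval: bout count, mean bout duration (min/bout),
#' percent time; the six ordered transition counts per interval; NREM and
#' REM latency from the given reference; and light-minus-dark amplitudes.
#'
#' @param hyp a [hypnogram()] covering one 24-h day.
#' @param latency_reference_zt_s reference for the latency rule (light onset
#'   0 for baseline days, ZT6 for post-deprivation recovery days).
#' @return list of class `architecture_summary` with elements `states`
#'   (tibble), `transitions` (tibble), `latency` (tibble) and `ld` (tibble).
#' @export
architecture_summary <- function(hyp, latency_reference_zt_s = 0) {
  per_interval <- function(interval) {
    b <- detect_bouts(hyp, interval)
    sel <- interval_epochs(hyp, interval)
    tab <- table(factor(hyp$states[sel], SOMN_STATES))
    tibble::tibble(
      interval = interval, state = SOMN_STATES,
      bout_count = vapply(SOMN_STATES,
                          function(st) sum(b$state == st), numeric(1)),
      mean_bout_duration_min = vapply(SOMN_STATES, function(st) {
        len <- b$length_epochs[b$state == st]
        if (length(len) == 0) NA_real_
        else mean(len) * hyp$epoch_length_s / 60
      }, numeric(1)),
      percent_time = 100 * as.numeric(tab) / sum(sel))
  }
  states <- rbind(per_interval("light"), per_interval("dark"))
  transitions <- rbind(
    cbind(interval = "light", count_transitions(hyp, "light")),
    cbind(interval = "dark", count_transitions(hyp, "dark")))
  latency <- tibble::tibble(
    target = c("NREM", "REM"),
    latency_min = c(sleep_latency(hyp, latency_reference_zt_s, "NREM"),
                    sleep_latency(hyp, latency_reference_zt_s, "REM")))
  structure(list(states = states, transitions = tibble::as_tibble(transitions),
                 latency = latency, ld = ld_amplitude(hyp)),
            class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("<architecture_summary>\n")
  print(x$states)
  cat("latencies (min):\n"); print(x$latency)
  invisible(x)
}
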