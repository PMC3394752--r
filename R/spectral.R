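#' Frequency-band definitions
#'
#' The four analysis bands: delta 0.5-5, theta 6-9, sigma 10-15 and beta
#' 16-23 Hz. The 5-6 Hz gap is intentional (delta and theta do not tile the
#' axis). `preset = "delta4"` narrows delta to 0.5-4 Hz, a variant used for
#' some NREM delta time-course displays.
#'
#' @param preset `"default"` or `"delta4"`.
#' @return tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
somn_bands <- function(preset = c("default", "delta4")) {
  preset <- match.arg(preset)
  tibble::tibble(
    band = c("delta", "theta", "sigma", "beta"),
    lo_hz = c(if (preset == "default") 0.5 else 0.5, 6, 10, 16),
    hi_hz = c(if (preset == "default") 5 else 4, 9, 15, 23))
}

#' Per-epoch FFT power spectra on the 0.25 Hz grid
#'
#' Magnitude-squared one-sided FFT of each 4-s epoch (256 samples at 64 Hz),
#' giving exactly 0.25 Hz bin spacing; power in bin `k` is
#' `2 |X_k|^2 / N^2` so that, with the rectangular taper, the sum over bins
#' equals the epoch's mean squared amplitude (Parseval). The DC and Nyquist
#' bins are dropped: the grid runs 0.25 ... 31.75 Hz (the last full bin below
#' Nyquist). The default Hann taper is power-renormalized (divided by its RMS)
#' so band powers remain on the rectangular scale.
#'
#' @param rec a [signal_recording()].
#' @param channel channel name; the parietal EEG (`"EEG2"`) by default.
#' @param epoch_length_s scoring epoch length, seconds.
#' @param taper `"hann"` or `"rectangular"`.
#' @return object of class `epoch_spectra`: `power` (epochs x bins),
#'   `freq_hz`, `bin_width_hz`, `artifact_mask` (all `FALSE` initially) and
#'   timing metadata.
#' @export
compute_epoch_spectra <- function(rec, channel = "EEG2", epoch_length_s = 4,
                                  taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  if (!channel %in% names(rec$channels)) {
    stop("channel not present: ", channel)
  }
  view <- epoch_view(rec, epoch_length_s)
  m <- view$channels[[channel]]
  spe <- view$samples_per_epoch
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(spe - 1 + 1) / spe) # periodic Hann
    w <- w / sqrt(mean(w^2))
    m <- m * w
  }
  X <- stats::mvfft(m)
  nf <- spe %/% 2L - 1L
  pw <- 2 * (Mod(X[2:(nf + 1L), , drop = FALSE])^2) / spe^2
  structure(list(
    power = t(pw),
    freq_hz = seq_len(nf) * rec$sampling_rate_hz / spe,
    bin_width_hz = rec$sampling_rate_hz / spe,
    artifact_mask = rep(FALSE, view$n_epochs),
    epoch_length_s = epoch_length_s,
    start_zt_s = rec$start_zt_s,
    taper = taper, channel = channel), class = "epoch_spectra")
}

#' @export
print.epoch_spectra <- function(x, ...) {
  cat(sprintf("<epoch_spectra> %d epochs x %d bins (%.2f-%.2f Hz, %g Hz), channel %s, taper %s, %d masked\n",
              nrow(x$power), ncol(x$power), min(x$freq_hz), max(x$freq_hz),
              x$bin_width_hz, x$channel, x$taper, sum(x$artifact_mask)))
  invisible(x)
}

#' Band power per epoch
#'
#' Sum of per-bin power over bins with `lo_hz <= f <= hi_hz` (inclusive
#' edges on the 0.25 Hz grid).
#'
#' @param spectra an `epoch_spectra`.
#' @param lo_hz,hi_hz band edges in Hz.
#' @return numeric vector, one value per epoch (masked epochs included; it is
#'   the caller's averaging that must respect the mask).
#' @export
band_power <- function(spectra, lo_hz, hi_hz) {
  sel <- spectra$freq_hz >= lo_hz & spectra$freq_hz <= hi_hz
  if (!any(sel)) stop("band ", lo_hz, "-", hi_hz, " Hz covers no bins")
  rowSums(spectra$power[, sel, drop = FALSE])
}

#' Flag artifact epochs
#'
#' An epoch is flagged when its total 0.5-29 Hz power exceeds `k` times the
#' centered rolling median of that total (window of `window_epochs` epochs on
#' each side), or when it was already flagged upstream in the hypnogram.
#' `k = Inf` disables power-based flagging.
#'
#' @param spectra an `epoch_spectra`.
#' @param k threshold multiple of the rolling median.
#' @param window_epochs half-width of the rolling-median window.
#' @param hyp optional [hypnogram()] whose artifact flags are OR-ed in.
#' @return logical artifact mask (assign to `spectra$artifact_mask`).
#' @export
flag_artifacts <- function(spectra, k = 8, window_epochs = 450, hyp = NULL) {
  tot <- band_power(spectra, 0.5, 29)
  win <- min(2L * window_epochs + 1L, nrow(spectra$power))
  if (win %% 2L == 0L) win <- win - 1L
  med <- if (win >= 3) runmed(tot, win, endrule = "median") else tot
  mask <- is.finite(tot) & tot > k * med
  if (!is.null(hyp)) {
    if (n_epochs(hyp) != length(mask)) stop("hypnogram/spectra length mismatch")
    mask <- mask | hyp$artifact
  }
  mask
}

zt_of_spectra <- function(spectra) {
  spectra$start_zt_s + (seq_len(nrow(spectra$power)) - 1) * spectra$epoch_length_s
}

check_alignment <- function(spectra, hyp) {
  if (n_epochs(hyp) != nrow(spectra$power)) {
    stop("hypnogram (", n_epochs(hyp), ") and spectra (", nrow(spectra$power),
         ") epoch counts differ")
  }
}

#' Reference normalizer for NREM delta power
#'
#' The per-animal scalar used to normalize NREM delta power: the mean, over
#' all unmasked NREM epochs of the (24-h baseline) reference day, of total
#' 0.5-29 Hz power.
#'
#' @param spectra an `epoch_spectra` of the reference day.
#' @param hyp the aligned [hypnogram()].
#' @export
nrem_power_normalizer <- function(spectra, hyp) {
  check_alignment(spectra, hyp)
  sel <- !spectra$artifact_mask & !is.na(hyp$states) & hyp$states == "NREM"
  if (!any(sel)) stop("no unmasked NREM epochs in the reference day")
  mean(band_power(spectra, 0.5, 29)[sel])
}

#' Normalized NREM delta-power time course
#'
#' Per ZT bin of `bin_h` hours: the mean delta-band (0.5-5 Hz) power over the
#' bin's unmasked NREM epochs, divided by the reference normalizer (see
#' [nrem_power_normalizer()]) and expressed in percent. Bins with no usable
#' NREM epoch are `NA`, never zero. For recovery days, pass the baseline
#' day's normalizer so the two days share a scale.
#'
#' @param spectra an `epoch_spectra`.
#' @param hyp the aligned [hypnogram()].
#' @param bin_h bin width in hours (2 or 6 in practice).
#' @param delta_band numeric length-2, delta band edges in Hz.
#' @param normalizer reference scalar; computed from `spectra`/`hyp` when
#'   `NULL`.
#' @return tibble with `zt_bin_start_h`, `n_epochs` (usable NREM epochs) and
#'   `delta_pct`.
#' @export
nrem_delta_timecourse <- function(spectra, hyp, bin_h = 2,
                                  delta_band = c(0.5, 5), normalizer = NULL) {
  check_alignment(spectra, hyp)
  if (is.null(normalizer)) normalizer <- nrem_power_normalizer(spectra, hyp)
  zt <- zt_of_spectra(spectra)
  bin <- floor((zt - zt[1]) / (bin_h * 3600))
  delta <- band_power(spectra, delta_band[1], delta_band[2])
  use <- !spectra$artifact_mask & !is.na(hyp$states) & hyp$states == "NREM"
  bins <- sort(unique(bin))
  val <- vapply(bins, function(b) {
    s <- use & bin == b
    if (!any(s)) NA_real_ else 100 * mean(delta[s]) / normalizer
  }, numeric(1))
  n_use <- vapply(bins, function(b) sum(use & bin == b), numeric(1))
  tibble::tibble(zt_bin_start_h = (zt[1] + bins * bin_h * 3600) / 3600,
                 n_epochs = n_use, delta_pct = val)
}

#' State spectral profile normalized to 24-h total power
#'
#' Per 0.25 Hz bin: mean power over the state's unmasked epochs, expressed as
#' a percentage of `T`, the mean over ALL unmasked epochs (pooled across
#' states) of total power across the full grid (0.25 Hz up to the last bin
#' below Nyquist, 31.75 Hz at 64 Hz sampling).
#'
#' @param spectra an `epoch_spectra` (typically a 24-h baseline day).
#' @param hyp the aligned [hypnogram()].
#' @param state `"WAKE"`, `"NREM"` or `"REM"`.
#' @return tibble with `freq_hz` and `power_pct`.
#' @export
state_spectral_profile <- function(spectra, hyp, state) {
  check_alignment(spectra, hyp)
  state <- match.arg(state, SOMN_STATES)
  unmasked <- !spectra$artifact_mask
  sel <- unmasked & !is.na(hyp$states) & hyp$states == state
  if (!any(sel)) stop("state absent from recording: ", state)
  grand <- mean(rowSums(spectra$power[unmasked, , drop = FALSE]))
  prof <- colMeans(spectra$power[sel, , drop = FALSE]) / grand * 100
  tibble::tibble(freq_hz = spectra$freq_hz, power_pct = prof)
}

#' Band power per state and light/dark interval
#'
#' For each state and band: the mean band power over the state's unmasked
#' epochs inside the interval, as a percentage of the mean total power
#' (full grid) over all unmasked epochs of the whole recording (the 24-h
#' normalization). Empty state-by-interval cells yield `NA`.
#'
#' @param spectra an `epoch_spectra`.
#' @param hyp the aligned [hypnogram()].
#' @param bands band table as from [somn_bands()].
#' @param interval `"light"` or `"dark"`.
#' @return tibble with `state`, `band`, `interval`, `power_pct`.
#' @export
band_power_by_state <- function(spectra, hyp, bands = somn_bands(),
                                interval = c("light", "dark")) {
  check_alignment(spectra, hyp)
  interval <- match.arg(interval)
  unmasked <- !spectra$artifact_mask
  in_int <- interval_epochs(hyp, interval)
  grand <- mean(rowSums(spectra$power[unmasked, , drop = FALSE]))
  out <- expand.grid(state = SOMN_STATES, band = bands$band,
                     stringsAsFactors = FALSE)
  out$interval <- interval
  out$power_pct <- mapply(function(stt, bnd) {
    b <- bands[bands$band == bnd, ]
    bp <- band_power(spectra, b$lo_hz, b$hi_hz)
    sel <- unmasked & in_int & !is.na(hyp$states) & hyp$states == stt
    if (!any(sel)) NA_real_ else 100 * mean(bp[sel]) / grand
  }, out$state, out$band)
  tibble::as_tibble(out)
}

#' Theta peak frequency of a spectral profile
#'
#' Frequency of the maximum bin within the theta window (6-9 Hz by default);
#' ties resolve to the lower frequency.
#'
#' @param profile tibble with `freq_hz` and a power column (second column
#'   used), e.g. from [state_spectral_profile()].
#' @param lo_hz,hi_hz search window.
#' @return peak frequency in Hz.
#' @export
theta_peak_frequency <- function(profile, lo_hz = 6, hi_hz = 9) {
  sel <- profile$freq_hz >= lo_hz & profile$freq_hz <= hi_hz
  if (!any(sel)) stop("profile does not cover the ", lo_hz, "-", hi_hz, " Hz window")
  f <- profile$freq_hz[sel]
  p <- profile[[2]][sel]
  f[which.max(p)] # which.max returns the first (lowest-frequency) maximum
}
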