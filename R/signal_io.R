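#' Construct a signal recording
#'
#' Container for a multichannel EEG/EMG trace: named channels (EEG in uV,
#' EMG in arbitrary units), the sampling rate, the ZT of the first sample,
#' the light/dark schedule and a day label. All channels must be the same
#' length, and the sampling rate must cover the 0.5-29 Hz analysis band
#' (>= 58 Hz).
#'
#' @param channels named list of equal-length numeric vectors; exactly one
#'   channel name must contain `"EMG"`.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param start_zt_s ZT of the first sample, seconds since lights-on.
#' @param lights_on_period_h,lights_off_period_h schedule (12:12 default).
#' @param day_label `"baseline"` or `"recovery"`.
#' @export
signal_recording <- function(channels, sampling_rate_hz, start_zt_s = 0,
                             lights_on_period_h = 12, lights_off_period_h = 12,
                             day_label = "baseline") {
  if (length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("channels must be a named list")
  }
  len <- vapply(channels, length, integer(1))
  if (length(unique(len)) != 1) {
    stop("all channels must have the same length")
  }
  if (!any(grepl("EMG", names(channels)))) {
    stop("format error: no EMG channel present")
  }
  if (sampling_rate_hz < 58) {
    stop("sampling_rate_hz must be >= 58 Hz (two times the 29 Hz analysis band)")
  }
  structure(list(channels = channels, sampling_rate_hz = sampling_rate_hz,
                 start_zt_s = start_zt_s,
                 lights_on_period_h = lights_on_period_h,
                 lights_off_period_h = lights_off_period_h,
                 day_label = day_label),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<signal_recording> %s: %d channels (%s), %d samples @ %g Hz (%.2f h), start ZT %g s\n",
              x$day_label, length(x$channels),
              paste(names(x$channels), collapse = ", "),
              n, x$sampling_rate_hz, n / x$sampling_rate_hz / 3600,
              x$start_zt_s))
  invisible(x)
}

#' Extract a contiguous sample range of a recording
#' @param rec a [signal_recording()].
#' @param from,to 0-based sample range, half-open.
#' @param day_label label for the slice.
#' @export
slice_recording <- function(rec, from, to, day_label = rec$day_label) {
  n <- length(rec$channels[[1]])
  if (from < 0 || to > n || from >= to) stop("invalid sample range")
  idx <- seq.int(from + 1L, to)
  start <- (rec$start_zt_s + from / rec$sampling_rate_hz) %% 86400
  signal_recording(lapply(rec$channels, `[`, idx), rec$sampling_rate_hz,
                   start, rec$lights_on_period_h, rec$lights_off_period_h,
                   day_label)
}

#' Slice a recording into aligned scoring epochs
#'
#' Partitions every channel into non-overlapping, contiguous 4-s blocks
#' (half-open `[i*epoch, (i+1)*epoch)`, 0-based). The sample count must be an
#' exact multiple of the epoch sample count; a remainder is a timing error.
#'
#' @param rec a [signal_recording()].
#' @param epoch_length_s epoch length in seconds.
#' @return object of class `epoch_view`: per-channel `samples x epochs`
#'   matrices plus timing metadata.
#' @export
epoch_view <- function(rec, epoch_length_s = 4) {
  spe <- rec$sampling_rate_hz * epoch_length_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("timing error: non-integer samples per epoch (",
         rec$sampling_rate_hz, " Hz x ", epoch_length_s, " s)")
  }
  spe <- as.integer(round(spe))
  n <- length(rec$channels[[1]])
  if (n %% spe != 0) {
    stop("timing error: ", n, " samples is not a whole number of ",
         epoch_length_s, "-s epochs (residue ", n %% spe, " samples)")
  }
  structure(list(
    channels = lapply(rec$channels, matrix, nrow = spe),
    n_epochs = n %/% spe, samples_per_epoch = spe,
    epoch_length_s = epoch_length_s, start_zt_s = rec$start_zt_s,
    sampling_rate_hz = rec$sampling_rate_hz), class = "epoch_view")
}

#' Fetch one epoch from an epoch view
#' @param view an [epoch_view()].
#' @param i 0-based epoch index.
#' @return samples x channels matrix for epoch `i`.
#' @export
get_epoch <- function(view, i) {
  if (i < 0 || i >= view$n_epochs) stop("epoch index out of range")
  sapply(view$channels, function(m) m[, i + 1L])
}

## ---- EDF (European Data Format, 16-bit) ----------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording as EDF
#'
#' Standard EDF: 16-bit little-endian samples, 1-s data records, one signal
#' per channel, physical scaling chosen per channel from the data range.
#' Timing metadata that EDF cannot carry (ZT of the first sample, light/dark
#' schedule, day label) goes to a JSON sidecar at `<path>.json`.
#'
#' @param rec a [signal_recording()]; its length must be a whole number of
#'   seconds.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- length(rec$channels[[1]])
  if (n %% fs != 0) {
    stop("timing error: recording is not a whole number of seconds (residue ",
         n %% fs, " samples)")
  }
  n_rec <- n %/% fs
  ns <- length(rec$channels)
  phys <- lapply(rec$channels, function(x) {
    r <- max(abs(range(x)), 1e-6)
    c(-r, r)
  })
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 synthetic somnarch", 80),
    edf_pad("01.01.00", 8), edf_pad("07.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  dims <- ifelse(grepl("EMG", names(rec$channels)), "a.u.", "uV")
  field(names(rec$channels), 16)
  field(rep("synthetic", ns), 80)
  field(dims, 8)
  field(vapply(phys, function(p) sprintf("%.6g", p[1]), ""), 8)
  field(vapply(phys, function(p) sprintf("%.6g", p[2]), ""), 8)
  field(rep(-32768L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  # digitize: dig = round((x - pmin) / (pmax - pmin) * 65535 - 32768)
  dig <- mapply(function(x, p) {
    as.integer(pmin(32767, pmax(-32768,
      round((x - p[1]) / (p[2] - p[1]) * 65535 - 32768))))
  }, rec$channels, phys, SIMPLIFY = FALSE)
  # interleave per record
  m <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (j in seq_len(ns)) {
    m[(j - 1L) * fs + seq_len(fs), ] <- matrix(dig[[j]], nrow = fs)
  }
  writeBin(as.integer(m), con, size = 2, endian = "little")
  sidecar <- list(start_zt_s = rec$start_zt_s,
                  lights_on_period_h = rec$lights_on_period_h,
                  lights_off_period_h = rec$lights_off_period_h,
                  day_label = rec$day_label)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for the 16-bit EDF files this package writes (and plain
#' single-rate EDFs generally). Sampling rate comes from the file header; ZT
#' and schedule metadata come from the `<path>.json` sidecar when present,
#' else from the arguments. A physical-dimension oddity is only a warning;
#' real-world files vary.
#'
#' @param path EDF file path.
#' @param start_zt_s,day_label fallbacks when no sidecar is found.
#' @return a [signal_recording()].
#' @export
read_edf <- function(path, start_zt_s = 0, day_label = "baseline") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  vapply(seq_len(ns), function(i) rd(80), "")
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr / rec_dur)) != 1) {
    stop("format error: channels with differing sampling rates are not supported")
  }
  if (any(!dims %in% c("uV", "a.u.", "mV", ""))) {
    warning("unrecognized physical dimension(s): ",
            paste(unique(dims), collapse = ", "))
  }
  raw <- readBin(con, integer(), n = sum(spr) * n_rec, size = 2,
                 endian = "little")
  if (length(raw) != sum(spr) * n_rec) {
    stop("format error: EDF data shorter than header promises")
  }
  m <- matrix(raw, nrow = sum(spr))
  offs <- c(0L, cumsum(spr))
  channels <- lapply(seq_len(ns), function(j) {
    d <- as.numeric(m[(offs[j] + 1L):offs[j + 1L], ])
    pmin[j] + (d - dmin[j]) / (dmax[j] - dmin[j]) * (pmax[j] - pmin[j])
  })
  names(channels) <- labels
  meta <- list(start_zt_s = start_zt_s, lights_on_period_h = 12,
               lights_off_period_h = 12, day_label = day_label)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE))
  }
  signal_recording(channels, sampling_rate_hz = spr[1] / rec_dur,
                   start_zt_s = meta$start_zt_s,
                   lights_on_period_h = meta$lights_on_period_h,
                   lights_off_period_h = meta$lights_off_period_h,
                   day_label = meta$day_label)
}

## ---- CSV dialect ----------------------------------------------------------

#' Write / read a recording in the package's CSV dialect
#'
#' One column per channel; metadata (sampling rate, ZT, schedule, day label)
#' in a JSON sidecar at `<path>.json`.
#'
#' @param rec a [signal_recording()].
#' @param path file path.
#' @export
write_recording_csv <- function(rec, path) {
  write.csv(as.data.frame(rec$channels), path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate_hz = rec$sampling_rate_hz,
                            start_zt_s = rec$start_zt_s,
                            lights_on_period_h = rec$lights_on_period_h,
                            lights_off_period_h = rec$lights_off_period_h,
                            day_label = rec$day_label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("format error: missing metadata sidecar ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- read.csv(path)
  signal_recording(as.list(df), sampling_rate_hz = meta$sampling_rate_hz,
                   start_zt_s = meta$start_zt_s,
                   lights_on_period_h = meta$lights_on_period_h,
                   lights_off_period_h = meta$lights_off_period_h,
                   day_label = meta$day_label)
}

#' Read a recording (EDF or CSV) with epoch-timing validation
#'
#' Dispatches on `format`, validates that the required EMG channel exists and
#' that the sample count is a whole number of `epoch_length_s` epochs.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`.
#' @param epoch_length_s epoch length used for the timing check.
#' @param ... passed to the format reader.
#' @export
read_recording <- function(path, format = c("edf", "csv"), epoch_length_s = 4,
                           ...) {
  format <- match.arg(format)
  rec <- switch(format, edf = read_edf(path, ...), csv = read_recording_csv(path))
  epoch_view(rec, epoch_length_s) # validates divisibility; result discarded
  rec
}

## ---- hypnogram CSV --------------------------------------------------------

#' Write a hypnogram as CSV
#'
#' Columns: `epoch_index` (0-based), `zt_seconds`, `state` (one of `WAKE`,
#' `NREM`, `REM`, `ARTIFACT`) and `underlying_state` (the best-guess state of
#' artifact epochs, empty otherwise). Artifact epochs are written with
#' `state = ARTIFACT` so that the file is self-contained under the four-label
#' alphabet.
#'
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  st <- as.character(hyp$states)
  under <- ifelse(hyp$artifact & !is.na(st), st, "")
  st_out <- ifelse(hyp$artifact, "ARTIFACT", st)
  write.csv(data.frame(epoch_index = seq_len(n_epochs(hyp)) - 1L,
                       zt_seconds = zt_of_epoch(hyp),
                       state = st_out, underlying_state = under),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' Accepts the dialect written by [write_hypnogram()]; any state token
#' outside `WAKE`/`NREM`/`REM`/`ARTIFACT` and empty files are format errors.
#'
#' @param path file path.
#' @param epoch_length_s epoch length (seconds) of the stored labels.
#' @export
read_hypnogram <- function(path, epoch_length_s = 4) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, colClasses = "character"),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  if (nrow(df) == 0) stop("format error: empty hypnogram file")
  need <- c("epoch_index", "zt_seconds", "state")
  if (!all(need %in% names(df))) {
    stop("format error: hypnogram CSV must have columns ",
         paste(need, collapse = ", "))
  }
  ok <- df$state %in% c(SOMN_STATES, "ARTIFACT")
  if (!all(ok)) {
    stop("format error: unknown state token(s): ",
         paste(unique(df$state[!ok]), collapse = ", "))
  }
  artifact <- df$state == "ARTIFACT"
  st <- df$state
  if ("underlying_state" %in% names(df)) {
    u <- df$underlying_state
    valid_u <- artifact & u %in% SOMN_STATES
    st[valid_u] <- u[valid_u]
  }
  st[st == "ARTIFACT"] <- NA
  hypnogram(st, epoch_length_s, as.numeric(df$zt_seconds[1]), artifact)
}
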