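#' Construct a hypnogram
#'
#' A hypnogram is the time-ordered sequence of vigilance-state labels
#' (`WAKE`, `NREM`, `REM`), one per scoring epoch, together with an artifact
#' flag per epoch. Flagged epochs keep their best-guess state (used by
#' architecture metrics) but are excluded from all spectral averages; an
#' epoch may also be pure `ARTIFACT` with no underlying state (`NA`).
#'
#' @param states character or factor vector over `WAKE`/`NREM`/`REM` (`NA`
#'   allowed only where `artifact` is `TRUE`).
#' @param epoch_length_s scoring epoch length in seconds (default 4).
#' @param start_zt_s zeitgeber time of the first epoch, seconds since lights-on.
#' @param artifact logical vector marking artifact-contaminated epochs.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(states, epoch_length_s = 4, start_zt_s = 0,
                      artifact = rep(FALSE, length(states))) {
  if (length(states) == 0L) stop("hypnogram must contain at least one epoch")
  states <- as.character(states)
  bad <- !is.na(states) & !states %in% SOMN_STATES
  if (any(bad)) {
    stop("unknown state label(s): ", paste(unique(states[bad]), collapse = ", "))
  }
  if (length(artifact) != length(states)) {
    stop("artifact flag length must match states")
  }
  if (any(is.na(states) & !artifact)) {
    stop("NA state is only allowed on artifact-flagged epochs")
  }
  if (epoch_length_s <= 0) stop("epoch_length_s must be positive")
  structure(
    list(states = factor(states, levels = SOMN_STATES),
         artifact = as.logical(artifact),
         epoch_length_s = epoch_length_s,
         start_zt_s = start_zt_s),
    class = "hypnogram")
}

#' Number of epochs in a hypnogram
#' @param x a `hypnogram`.
#' @export
n_epochs <- function(x) length(x$states)

#' Zeitgeber time of each epoch
#'
#' `zt_of_epoch(h)` returns the ZT (seconds since lights-on) of each epoch
#' start: `start_zt_s + epoch_length_s * i` for 0-based epoch index `i`.
#'
#' @param x a `hypnogram`.
#' @param i optional 0-based epoch indices (default: all epochs).
#' @export
zt_of_epoch <- function(x, i = seq_len(n_epochs(x)) - 1L) {
  x$start_zt_s + x$epoch_length_s * i
}

#' Light-phase predicate for zeitgeber times
#'
#' @param zt_s zeitgeber time(s) in seconds.
#' @param light_h,dark_h schedule (12:12 default).
#' @return logical: `TRUE` where the time falls in the light phase.
#' @export
is_light <- function(zt_s, light_h = 12, dark_h = 12) {
  day <- (light_h + dark_h) * 3600
  (zt_s %% day) < light_h * 3600
}

#' Epoch membership of a 12-h interval
#'
#' @param x a `hypnogram`.
#' @param interval `"light"`, `"dark"` or `"all"`.
#' @return logical vector over epochs.
#' @export
interval_epochs <- function(x, interval = c("all", "light", "dark")) {
  interval <- match.arg(interval)
  lt <- is_light(zt_of_epoch(x))
  switch(interval, all = rep(TRUE, n_epochs(x)), light = lt, dark = !lt)
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- n_epochs(x)
  tab <- table(x$states, useNA = "ifany")
  cat(sprintf("<hypnogram> %d epochs of %g s (%.2f h), start ZT %g s\n",
              n, x$epoch_length_s, n * x$epoch_length_s / 3600, x$start_zt_s))
  cat(sprintf("  states: %s\n",
              paste(sprintf("%s %.1f%%", names(tab), 100 * tab / n),
                    collapse = ", ")))
  cat(sprintf("  artifact epochs: %d (%.2f%%)\n",
              sum(x$artifact), 100 * mean(x$artifact)))
  invisible(x)
}

#' Extract a contiguous slice of a hypnogram
#'
#' @param x a `hypnogram`.
#' @param from,to 0-based epoch range, half-open `[from, to)`.
#' @param restart_zt if `TRUE` the slice's `start_zt_s` is reset so the slice
#'   begins at its ZT within the (24 h) day; used when splitting multi-day
#'   sessions into per-day hypnograms.
#' @export
slice_hypnogram <- function(x, from, to, restart_zt = FALSE) {
  n <- n_epochs(x)
  if (from < 0 || to > n || from >= to) stop("invalid epoch range")
  idx <- seq.int(from + 1L, to)
  start <- x$start_zt_s + from * x$epoch_length_s
  if (restart_zt) start <- start %% 86400
  hypnogram(as.character(x$states[idx]), x$epoch_length_s, start,
            x$artifact[idx])
}
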