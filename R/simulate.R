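#' Simulate a hypnogram
#'
#' Realizes the per-epoch inhomogeneous Markov chain over WAKE/NREM/REM with
#' phase-dependent transition matrices. The session starts at ZT0 (lights-on)
#' in WAKE (lights-on rouses the animal). Under the `sd_recovery` protocol the
#' epochs falling in ZT0-ZT6 of day 2 (session hours 24-30, i.e. a 6-h
#' forced-wake block starting at light onset of the deprivation day) are
#' forced to WAKE; the chain resumes from WAKE afterwards. Artifact epochs
#' are drawn independently at `artifact_rate` and flagged while keeping the
#' underlying state. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param protocol `"baseline"` (free-running) or `"sd_recovery"` (6-h sleep
#'   deprivation at light onset of day 2; requires `n_hours >= 24`).
#' @return a [hypnogram()] with the artifact flags set.
#' @export
simulate_hypnogram <- function(config, protocol = c("baseline", "sd_recovery")) {
  protocol <- match.arg(protocol)
  validate_sim_config(config)
  n <- config$n_hours * 3600 / config$epoch_length_s
  if (abs(n - round(n)) > 1e-9) stop("n_hours does not give a whole number of epochs")
  n <- as.integer(round(n))
  zt <- (seq_len(n) - 1) * config$epoch_length_s
  phase <- ifelse(is_light(zt), 1L, 2L)
  forced <- integer(n)
  if (protocol == "sd_recovery") {
    if (config$n_hours < 24) stop("sd_recovery requires n_hours >= 24")
    forced[zt >= 86400 & zt < 86400 + 21600] <- 1L # WAKE
  }
  trans <- array(c(config$transition_rates$light, config$transition_rates$dark),
                 dim = c(3, 3, 2))
  if (!is.null(config$seed)) set.seed(config$seed)
  u <- runif(n)
  states <- markov_chain_sim(n, as.numeric(trans), phase, forced, 1L, u)
  artifact <- runif(n) < config$artifact_rate
  hypnogram(SOMN_STATES[states], config$epoch_length_s, 0, artifact)
}

#' Homeostatic slow-wave process along a hypnogram
#'
#' Two-process-style saturating dynamics: the process rises exponentially
#' toward `ceiling` during wake and REM (time constant `tau_rise_h`) and
#' decays toward `floor` during NREM (`tau_decay_h`). The returned value for
#' each epoch is the level at the epoch's start. Forced-wake blocks therefore
#' drive the process up; consolidated NREM discharges it. With
#' `homeostasis$enabled = FALSE` the process is fixed at 1.
#'
#' @param hyp a [hypnogram()]; artifact epochs count as their underlying
#'   state (NA states count as wake-like for the process).
#' @param config a [sim_config()] supplying the `homeostasis` parameters.
#' @return numeric vector, one value per epoch, within `[floor, ceiling]`.
#' @export
homeostatic_process <- function(hyp, config) {
  h <- config$homeostasis
  if (!isTRUE(h$enabled)) return(rep(1, n_epochs(hyp)))
  is_nrem <- as.integer(!is.na(hyp$states) & hyp$states == "NREM")
  homeostat_process(is_nrem, h$s0, config$epoch_length_s,
                    h$tau_rise_h * 3600, h$tau_decay_h * 3600,
                    h$floor, h$ceiling)
}

# Target one-sided power per 0.25 Hz bin for one state, excluding the
# homeostatic component (returned separately so it can be scaled per epoch).
state_psd <- function(sig, freq) {
  base <- sig$background / pmax(freq, 0.5)
  homeo <- numeric(length(freq))
  comp <- sig$components
  for (i in seq_len(nrow(comp))) {
    g <- comp$amplitude[i] *
      exp(-(freq - comp$center_hz[i])^2 / (2 * comp$bandwidth_hz[i]^2))
    if (isTRUE(comp$homeostatic[i])) homeo <- homeo + g else base <- base + g
  }
  list(base = base, homeo = homeo)
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' Per epoch, the EEG is a Gaussian process synthesized in the frequency
#' domain with the state's target spectrum: 1/f background plus the state's
#' Gaussian components, the homeostatically flagged (NREM delta) component
#' scaled by the current process value. Two independent EEG channels (EEG1
#' frontal, EEG2 parietal) share the same target spectrum; the EMG is white
#' noise at the state's RMS level. Artifact-flagged epochs additionally
#' receive a large broadband transient on both EEG channels. Deterministic
#' given `seed`.
#'
#' @param hyp a [hypnogram()] (from [simulate_hypnogram()] or elsewhere).
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1` so the signal draws do
#'   not replay the state-sequence draws.
#' @param day_label stored on the resulting recording.
#' @return a [signal_recording()] with channels `EEG1`, `EEG2`, `EMG`.
#' @export
simulate_signals <- function(hyp, config,
                             seed = if (is.null(config$seed)) NULL else config$seed + 1L,
                             day_label = "baseline") {
  validate_sim_config(config)
  n <- n_epochs(hyp)
  spe <- samples_per_epoch(config)
  nf <- spe %/% 2L - 1L # interior rfft bins: 0.25 .. Nyquist-0.25
  freq <- seq_len(nf) * config$sampling_rate_hz / spe
  if (!is.null(seed)) set.seed(seed)

  s_val <- homeostatic_process(hyp, config)
  st <- as.character(hyp$states)
  st[is.na(st)] <- "WAKE" # underlying signal for pure-artifact epochs
  psd <- lapply(config$spectral_signature, state_psd, freq = freq)

  # per-epoch target power per bin: base(state) + S * homeo(state)
  base_m <- vapply(psd, `[[`, numeric(nf), "base")   # nf x 3
  homeo_m <- vapply(psd, `[[`, numeric(nf), "homeo")
  sidx <- match(st, colnames(base_m))
  P <- base_m[, sidx, drop = FALSE] + homeo_m[, sidx, drop = FALSE] *
    rep(s_val, each = nf) # nf x n

  # Frequency-domain synthesis: circularly-symmetric coefficients with
  # sigma_k = N * sqrt(P_k); the real and imaginary parts of the inverse FFT
  # are two independent series whose expected one-sided bin power
  # (2/N^2)|FFT|^2 equals P_k. Coefficients are mirrored (sigma_{N-k} =
  # sigma_k), DC and Nyquist are zero.
  sig <- spe * sqrt(P)
  X <- matrix(0 + 0i, nrow = spe, ncol = n)
  z1 <- matrix(rnorm(nf * n), nf, n)
  z2 <- matrix(rnorm(nf * n), nf, n)
  z3 <- matrix(rnorm(nf * n), nf, n)
  z4 <- matrix(rnorm(nf * n), nf, n)
  X[2:(nf + 1L), ] <- sig * (z1 + 1i * z2) / sqrt(2)
  X[spe:(spe - nf + 1L), ] <- sig * (z3 + 1i * z4) / sqrt(2)
  x <- stats::mvfft(X, inverse = TRUE) / spe
  eeg1 <- as.numeric(Re(x))
  eeg2 <- as.numeric(Im(x))

  emg_sd <- config$emg_amplitude[st]
  emg <- rnorm(spe * n, sd = rep(emg_sd, each = spe))

  if (any(hyp$artifact)) {
    # broadband transient: white noise at artifact_gain x the typical epoch RMS
    typ_rms <- sqrt(mean(colSums(P)))
    art_idx <- which(rep(hyp$artifact, each = spe))
    burst <- rnorm(length(art_idx), sd = config$artifact_gain * typ_rms)
    eeg1[art_idx] <- eeg1[art_idx] + burst
    eeg2[art_idx] <- eeg2[art_idx] + rnorm(length(art_idx),
                                           sd = config$artifact_gain * typ_rms)
  }

  signal_recording(list(EEG1 = eeg1, EEG2 = eeg2, EMG = emg),
                   sampling_rate_hz = config$sampling_rate_hz,
                   start_zt_s = hyp$start_zt_s,
                   day_label = day_label)
}

#' Generate a paired baseline/recovery synthetic study
#'
#' Simulates `n_animals` independent 48-h sessions for one line archetype:
#' a 24-h baseline day followed by a deprivation day (6-h forced wake from
#' light onset, then 18 h of recovery), with the homeostatic process running
#' continuously across both days. Each animal gets an independent seed
#' derived from `seed`; ground-truth hypnograms are retained for classifier
#' evaluation.
#'
#' @param line archetype name (`"NAB"`, `"LAB"`, `"HAB"`) or a
#'   [line_archetype()].
#' @param n_animals number of animals (>= 1).
#' @param seed study-level RNG seed.
#' @param signals if `FALSE`, only hypnograms are generated (fast path for
#'   architecture-only analyses).
#' @param ... further [sim_config()] overrides applied to every animal.
#' @return list with `line` and `animals`; each animal holds `id`, `config`,
#'   the full-session ground truth `hypnogram`, and `baseline` / `recovery`
#'   entries each containing a per-day `hypnogram` (ZT restarted at 0) and,
#'   if requested, a `recording`.
#' @export
make_study <- function(line, n_animals, seed, signals = TRUE, ...) {
  if (is.character(line)) line <- line_archetype(line)
  if (n_animals < 1) stop("n_animals must be >= 1")
  seeds <- study_animal_seeds(seed, n_animals)
  animals <- lapply(seq_len(n_animals), function(i) {
    simulate_animal(line, seeds[i], sprintf("%s_%02d", line$name, i),
                    signals = signals, ...)
  })
  list(line = line$name, animals = animals)
}

study_animal_seeds <- function(seed, n_animals) {
  set.seed(seed)
  sample.int(2147483000L, n_animals)
}

#' Simulate one paired baseline/recovery animal
#'
#' One independent 48-h session (baseline day, then 6-h forced wake plus
#' 18-h recovery) for a line archetype, split into per-day hypnograms and,
#' optionally, recordings. This is the unit [make_study()] iterates over;
#' calling it directly lets large studies be processed one animal at a time
#' without holding every recording in memory.
#'
#' @param line archetype name or [line_archetype()].
#' @param seed animal-level RNG seed.
#' @param id animal identifier.
#' @param signals if `FALSE`, hypnograms only.
#' @param ... further [sim_config()] overrides.
#' @export
simulate_animal <- function(line, seed, id = line_name(line), signals = TRUE,
                            ...) {
  if (is.character(line)) line <- line_archetype(line)
  cfg <- archetype_config(line, n_hours = 48, seed = seed, ...)
  n_day <- 24L * as.integer(3600 / cfg$epoch_length_s)
  hyp <- simulate_hypnogram(cfg, protocol = "sd_recovery")
  rec <- if (signals) simulate_signals(hyp, cfg) else NULL
  split_day <- function(day) {
    from <- (day - 1L) * n_day
    lbl <- if (day == 1L) "baseline" else "recovery"
    out <- list(hypnogram = slice_hypnogram(hyp, from, from + n_day,
                                            restart_zt = TRUE))
    if (signals) {
      out$recording <- slice_recording(rec, from * samples_per_epoch(cfg),
                                       (from + n_day) * samples_per_epoch(cfg),
                                       day_label = lbl)
    }
    out
  }
  list(id = id, config = cfg, hypnogram = hyp,
       baseline = split_day(1L), recovery = split_day(2L))
}

line_name <- function(line) if (is.character(line)) line else line$name
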