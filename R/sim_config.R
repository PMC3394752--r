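#' Simulation configuration for synthetic polysomnography
#'
#' Bundles every generative parameter of the synthetic recording model:
#' timing (4-s epochs at 64 Hz, lights on at 7:00, i.e. sessions start at
#' ZT0), phase-dependent per-epoch Markov transition matrices over
#' WAKE/NREM/REM, per-state EEG spectral signatures (Gaussian frequency
#' components over a 1/f background), per-state EMG RMS levels, a
#' two-process-style homeostatic slow-wave process that scales the NREM delta
#' component, an artifact injection rate, and the RNG seed.
#'
#' @param epoch_length_s scoring epoch length, seconds.
#' @param sampling_rate_hz signal sampling rate, Hz. `sampling_rate_hz *
#'   epoch_length_s` must be an integer (256 samples/epoch by default).
#' @param lights_on_clock clock hour of lights-on (recording start = ZT0).
#' @param n_hours session length in hours.
#' @param transition_rates list with elements `light` and `dark`, each a
#'   3x3 row-stochastic matrix over `WAKE`,`NREM`,`REM` of per-epoch
#'   transition probabilities.
#' @param spectral_signature per-state list: `background` (1/f weight) and
#'   `components`, a data frame with columns `center_hz`, `bandwidth_hz`,
#'   `amplitude` and logical `homeostatic` (components whose amplitude is
#'   multiplied by the homeostatic process value).
#' @param emg_amplitude named numeric, per-state EMG RMS (a.u.); the shipped
#'   archetypes satisfy WAKE > NREM >= REM.
#' @param homeostasis list: `tau_rise_h` (rise time constant during
#'   wake/REM, hours), `tau_decay_h` (decay during NREM, hours), `floor`,
#'   `ceiling`, `s0` (initial level), `enabled`.
#' @param artifact_rate per-epoch probability of an injected broadband
#'   artifact transient.
#' @param artifact_gain amplitude of injected artifacts, as a multiple of the
#'   typical epoch EEG RMS.
#' @param seed integer RNG seed, or `NULL`.
#' @return a validated object of class `sim_config`.
#' @seealso [line_archetype()], [simulate_hypnogram()], [simulate_signals()]
#' @export
sim_config <- function(epoch_length_s = 4,
                       sampling_rate_hz = 64,
                       lights_on_clock = 7,
                       n_hours = 24,
                       transition_rates = default_transition_rates("NAB"),
                       spectral_signature = default_spectral_signature("NAB"),
                       emg_amplitude = c(WAKE = 3.0, NREM = 1.0, REM = 0.45),
                       homeostasis = list(tau_rise_h = 8, tau_decay_h = 2,
                                          floor = 0.6, ceiling = 2.2,
                                          s0 = 1, enabled = TRUE),
                       artifact_rate = 0.005,
                       artifact_gain = 10,
                       seed = NULL) {
  cfg <- structure(
    list(epoch_length_s = epoch_length_s, sampling_rate_hz = sampling_rate_hz,
         lights_on_clock = lights_on_clock, n_hours = n_hours,
         transition_rates = transition_rates,
         spectral_signature = spectral_signature,
         emg_amplitude = emg_amplitude, homeostasis = homeostasis,
         artifact_rate = artifact_rate, artifact_gain = artifact_gain,
         seed = seed),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants the generator relies on: row-stochastic transition
#' matrices per phase, probabilities in `[0,1]`, an integer epoch sample
#' count, strictly positive homeostatic time constants with
#' `ceiling > floor >= 0`, and a valid artifact rate.
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; stops with a configuration error otherwise.
#' @export
validate_sim_config <- function(cfg) {
  spe <- cfg$sampling_rate_hz * cfg$epoch_length_s
  if (abs(spe - round(spe)) > 1e-9) {
    stop("configuration error: sampling_rate_hz * epoch_length_s must be an ",
         "integer sample count (got ", spe, ")")
  }
  for (ph in c("light", "dark")) {
    P <- cfg$transition_rates[[ph]]
    if (is.null(P) || !is.matrix(P) || !all(dim(P) == c(3, 3))) {
      stop("configuration error: transition_rates$", ph,
           " must be a 3x3 matrix")
    }
    if (any(P < 0) || any(P > 1)) {
      stop("configuration error: transition probabilities must lie in [0,1]")
    }
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-8)) {
      stop("configuration error: rows of the ", ph,
           "-phase transition matrix must sum to 1 (sums: ",
           paste(signif(rs, 8), collapse = ", "), ")")
    }
  }
  h <- cfg$homeostasis
  if (h$tau_rise_h <= 0 || h$tau_decay_h <= 0) {
    stop("configuration error: homeostatic time constants must be positive")
  }
  if (h$floor < 0 || h$ceiling <= h$floor) {
    stop("configuration error: need ceiling > floor >= 0")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    stop("configuration error: artifact_rate must lie in [0,1]")
  }
  if (!all(SOMN_STATES %in% names(cfg$emg_amplitude))) {
    stop("configuration error: emg_amplitude must name WAKE, NREM and REM")
  }
  invisible(cfg)
}

#' Samples per scoring epoch
#' @param cfg a `sim_config` (or anything with the two timing fields).
#' @export
samples_per_epoch <- function(cfg) {
  as.integer(round(cfg$sampling_rate_hz * cfg$epoch_length_s))
}

state_matrix <- function(rows) {
  m <- matrix(unlist(rows), nrow = 3, byrow = TRUE,
              dimnames = list(SOMN_STATES, SOMN_STATES))
  m
}

#' Default phase-dependent transition matrices per line archetype
#'
#' Per-epoch (4 s) probabilities, designed around the stationary occupancies
#' and geometric bout lengths characteristic of each line: `NAB` consolidated
#' with a robust light/dark rhythm; `LAB` long wake bouts, slow wake exit at
#' light onset (long sleep latency) and extreme dark-phase wake maintenance;
#' `HAB` fragmented, with fast state turnover, blunted dark-phase wakefulness
#' and an elevated NREM-to-REM entry rate. REM is entered only from NREM in
#' all presets (wake-to-REM probability 0), though the model itself permits
#' all six transitions.
#'
#' @param line `"NAB"`, `"LAB"` or `"HAB"`.
#' @return list with 3x3 row-stochastic matrices `light` and `dark`.
#' @export
default_transition_rates <- function(line = c("NAB", "LAB", "HAB")) {
  line <- match.arg(line)
  switch(line,
    NAB = list(
      light = state_matrix(list(c(.985, .015, 0),
                                c(.014, .980, .006),
                                c(.060, .010, .930))),
      dark  = state_matrix(list(c(.988, .012, 0),
                                c(.045, .945, .010),
                                c(.080, .010, .910)))),
    LAB = list(
      light = state_matrix(list(c(.998, .002, 0),
                                c(.004, .994, .002),
                                c(.060, .010, .930))),
      dark  = state_matrix(list(c(.995, .005, 0),
                                c(.020, .975, .005),
                                c(.080, .010, .910)))),
    HAB = list(
      light = state_matrix(list(c(.850, .150, 0),
                                c(.025, .960, .015),
                                c(.065, .025, .910))),
      dark  = state_matrix(list(c(.965, .035, 0),
                                c(.045, .925, .030),
                                c(.090, .020, .890)))))
}

spectral_components <- function(center, bw, amp, homeo = FALSE) {
  data.frame(center_hz = center, bandwidth_hz = bw, amplitude = amp,
             homeostatic = homeo)
}

#' Default per-state EEG spectral signatures per line archetype
#'
#' Power per 0.25 Hz bin is modelled as `background / max(f, 0.5)` plus
#' Gaussian components `amplitude * exp(-(f - center)^2 / (2 bandwidth^2))`.
#' NREM carries a dominant delta component (homeostatically scaled) and a
#' small sigma (spindle-band) component; REM a sharp theta peak; wake a broad
#' low-amplitude theta over a stronger background. Line differences encode
#' the study phenotype directions: the HAB NREM delta component is larger
#' than NAB's, the REM theta peak sits 0.8 Hz (LAB) and 0.9 Hz (HAB) below
#' NAB's 7.0 Hz, and LAB NREM carries an extra beta-band component.
#'
#' @param line `"NAB"`, `"LAB"` or `"HAB"`.
#' @export
default_spectral_signature <- function(line = c("NAB", "LAB", "HAB")) {
  line <- match.arg(line)
  theta_rem <- switch(line, NAB = 7.0, LAB = 6.2, HAB = 6.1)
  delta_amp <- switch(line, NAB = 4.0, LAB = 4.0, HAB = 5.5)
  nrem_comp <- rbind(
    spectral_components(1.5, 1.2, delta_amp, homeo = TRUE),
    spectral_components(12, 1.0, 0.6))
  if (line == "LAB") {
    nrem_comp <- rbind(nrem_comp, spectral_components(19, 2.0, 0.4))
  }
  list(
    WAKE = list(background = 1.2,
                components = spectral_components(7.5, 1.2, 1.0)),
    NREM = list(background = 1.0, components = nrem_comp),
    REM = list(background = 0.8,
               components = rbind(spectral_components(theta_rem, 0.6, 3.0),
                                  spectral_components(1.5, 1.0, 0.5))))
}

#' Line archetypes: NAB, LAB and HAB sleep phenotypes
#'
#' Returns the named archetype as a partial-configuration overlay: the
#' transition matrices, spectral signature and homeostatic time constants
#' that distinguish high- (HAB), normal- (NAB) and low- (LAB)
#' anxiety-related-behavior lines. LAB's long rise time constant encodes its
#' blunted accumulation of slow-wave pressure; HAB's short one, together with
#' its larger delta signature and fragmented dynamics, encodes persistently
#' elevated NREM delta power.
#'
#' @param name `"NAB"`, `"LAB"` or `"HAB"`.
#' @return list with `name` and `overrides` (a partial `sim_config`).
#' @export
line_archetype <- function(name = c("NAB", "LAB", "HAB")) {
  name <- match.arg(name)
  tau_rise <- switch(name, NAB = 8, LAB = 18, HAB = 6)
  # HAB never fully discharges its sleep pressure (elevated floor keeps its
  # NREM delta high through both phases despite its large sleep amounts) and
  # rebounds strongly (high ceiling, fast rise); LAB accumulates slow-wave
  # pressure poorly (slow rise toward a low ceiling), blunting its rebound
  floor_ <- switch(name, NAB = 0.6, LAB = 0.6, HAB = 1.1)
  ceiling_ <- switch(name, NAB = 2.2, LAB = 1.6, HAB = 2.6)
  list(name = name,
       overrides = list(
         transition_rates = default_transition_rates(name),
         spectral_signature = default_spectral_signature(name),
         homeostasis = list(tau_rise_h = tau_rise, tau_decay_h = 2,
                            floor = floor_, ceiling = ceiling_, s0 = 1,
                            enabled = TRUE)))
}

#' Full configuration for a line archetype
#'
#' Convenience wrapper: [sim_config()] defaults with an archetype's
#' overrides applied, plus any further overrides passed as `...`.
#'
#' @param line archetype name or a [line_archetype()] object.
#' @param ... fields of [sim_config()] to override (e.g. `n_hours`, `seed`).
#' @export
archetype_config <- function(line = "NAB", ...) {
  if (is.character(line)) line <- line_archetype(line)
  args <- utils::modifyList(line$overrides, list(...))
  do.call(sim_config, args)
}
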