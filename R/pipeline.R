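#' Analyze one animal of a paired baseline/recovery study
#'
#' Runs the full analysis chain on one animal from [make_study()]: epoch
#' spectra (parietal EEG, Hann taper) and artifact masks for both days, the
#' baseline-day NREM power normalizer, per-bin state amounts and normalized
#' NREM delta power for both days, the baseline architecture summary,
#' post-deprivation latencies, and (optionally) self-calibrated scoring of
#' the baseline day evaluated against the ground-truth hypnogram. Signals
#' and spectra are released when the function returns, so studies of any
#' size can be processed animal by animal.
#'
#' @param animal one element of `make_study(...)$animals` (with recordings).
#' @param bin_h bin width in hours for the time-course measures.
#' @param score if `TRUE`, score the baseline day and report agreement.
#' @param channel EEG channel used for spectra.
#' @return list: `measures` (tibble of per-bin values for both days),
#'   `rebound` (tibble from [rebound_differences()]), `architecture`
#'   (baseline [architecture_summary()]), `latency` (tibble: baseline from
#'   light onset and recovery from SD end), `agreement` (from
#'   [score_agreement()], or `NULL`).
#' @export
analyze_animal <- function(animal, bin_h = 2, score = TRUE, channel = "EEG2") {
  hyp_b <- animal$baseline$hypnogram
  hyp_r <- animal$recovery$hypnogram
  sp_b <- compute_epoch_spectra(animal$baseline$recording, channel)
  sp_r <- compute_epoch_spectra(animal$recovery$recording, channel)
  sp_b$artifact_mask <- flag_artifacts(sp_b, hyp = hyp_b)
  sp_r$artifact_mask <- flag_artifacts(sp_r, hyp = hyp_r)
  norm <- nrem_power_normalizer(sp_b, hyp_b)

  mb <- bin_measures(hyp_b, sp_b, bin_h, normalizer = norm)
  mr <- bin_measures(hyp_r, sp_r, bin_h, normalizer = norm)
  measures <- rbind(cbind(day = "baseline", mb), cbind(day = "recovery", mr))
  rebound <- rebound_differences(mb, mr)

  arch <- architecture_summary(hyp_b, latency_reference_zt_s = 0)
  latency <- rbind(
    tibble::tibble(day = "baseline", target = c("NREM", "REM"),
                   latency_min = c(sleep_latency(hyp_b, 0, "NREM"),
                                   sleep_latency(hyp_b, 0, "REM"))),
    tibble::tibble(day = "recovery", target = c("NREM", "REM"),
                   latency_min = c(post_sd_latency(hyp_r, target = "NREM"),
                                   post_sd_latency(hyp_r, target = "REM"))))

  theta_peak <- if (any(!sp_b$artifact_mask & !is.na(hyp_b$states) &
                          hyp_b$states == "REM")) {
    theta_peak_frequency(state_spectral_profile(sp_b, hyp_b, "REM"))
  } else NA_real_

  agreement <- NULL
  if (score) {
    feats <- extract_features(sp_b, animal$baseline$recording)
    th <- calibrate_thresholds(feats, method = "quantile")
    scored <- smooth_hypnogram(classify(feats, th))
    agreement <- score_agreement(scored, hyp_b)
  }
  list(id = animal$id, measures = tibble::as_tibble(measures),
       rebound = rebound, architecture = arch, latency = latency,
       normalizer = norm, theta_peak_hz = theta_peak, agreement = agreement)
}

#' Simulate and analyze a line study, one animal at a time
#'
#' The streaming equivalent of `analyze_study(make_study(...))`: each
#' animal's recording is simulated, analyzed with [analyze_animal()] and
#' released before the next is generated, keeping memory flat for any study
#' size. Seeding is identical to [make_study()] with the same `seed`.
#'
#' @param line archetype name or [line_archetype()].
#' @param n_animals animals per line.
#' @param seed study-level seed.
#' @param bin_h,score,channel passed to [analyze_animal()].
#' @param ... further [sim_config()] overrides.
#' @return as [analyze_study()].
#' @export
run_line_study <- function(line, n_animals, seed, bin_h = 2, score = TRUE,
                           channel = "EEG2", ...) {
  if (is.character(line)) line <- line_archetype(line)
  if (n_animals < 1) stop("n_animals must be >= 1")
  seeds <- study_animal_seeds(seed, n_animals)
  per <- lapply(seq_len(n_animals), function(i) {
    a <- simulate_animal(line, seeds[i], sprintf("%s_%02d", line$name, i), ...)
    res <- analyze_animal(a, bin_h = bin_h, score = score, channel = channel)
    rm(a)
    res
  })
  bind_study_results(line$name, per)
}

#' Analyze a whole synthetic study
#'
#' Maps [analyze_animal()] over a [make_study()] result and binds the
#' per-animal outputs into tidy study-level tables.
#'
#' @param study a [make_study()] result (with recordings).
#' @param ... passed to [analyze_animal()].
#' @return list of tibbles: `measures`, `rebound`, `latency`, `states`
#'   (per-interval architecture), `transitions`, `ld`, `scoring` (one row
#'   per animal: accuracy, kappa, REM recall), each carrying `line` and
#'   `animal` columns.
#' @export
analyze_study <- function(study, ...) {
  per <- lapply(study$animals, analyze_animal, ...)
  bind_study_results(study$line, per)
}

bind_study_results <- function(line_name, per) {
  tag <- function(extract) {
    do.call(rbind, lapply(per, function(r) {
      cbind(tibble::tibble(line = line_name, animal = r$id), extract(r))
    }))
  }
  scoring <- NULL
  if (!is.null(per[[1]]$agreement)) {
    scoring <- do.call(rbind, lapply(per, function(r) {
      tibble::tibble(line = line_name, animal = r$id,
                     accuracy = r$agreement$accuracy,
                     kappa = r$agreement$kappa,
                     rem_recall = unname(r$agreement$recall["REM"]))
    }))
  }
  theta <- do.call(rbind, lapply(per, function(r) {
    tibble::tibble(line = line_name, animal = r$id,
                   theta_peak_hz = r$theta_peak_hz)
  }))
  list(measures = tag(function(r) r$measures),
       theta_peak = theta,
       rebound = tag(function(r) r$rebound),
       latency = tag(function(r) r$latency),
       states = tag(function(r) r$architecture$states),
       transitions = tag(function(r) r$architecture$transitions),
       ld = tag(function(r) r$architecture$ld),
       scoring = scoring)
}
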