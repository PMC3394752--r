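#' Extract per-epoch scoring features
#'
#' EMG RMS per 4-s epoch from the raw EMG channel, and EEG band powers from
#' the epoch spectra: delta (0.5-5), theta (6-9) and total (0.5-29) power,
#' plus the two dimensionless ratios the classifier uses
#' (`delta_theta_ratio = delta/theta`, `theta_total_ratio = theta/total`).
#' Ratios are `NA` wherever their denominator is zero.
#'
#' @param spectra an `epoch_spectra`.
#' @param rec the aligned [signal_recording()] (for the EMG channel).
#' @param emg_channel EMG channel name.
#' @return tibble of class `epoch_features` with timing attributes carried
#'   from the spectra.
#' @export
extract_features <- function(spectra, rec, emg_channel = "EMG") {
  view <- epoch_view(rec, spectra$epoch_length_s)
  if (view$n_epochs != nrow(spectra$power)) {
    stop("recording (", view$n_epochs, ") and spectra (", nrow(spectra$power),
         ") epoch counts differ")
  }
  if (!emg_channel %in% names(view$channels)) {
    stop("format error: EMG channel not present: ", emg_channel)
  }
  emg_rms <- sqrt(colMeans(view$channels[[emg_channel]]^2))
  delta <- band_power(spectra, 0.5, 5)
  theta <- band_power(spectra, 6, 9)
  total <- band_power(spectra, 0.5, 29)
  feats <- tibble::tibble(
    emg_rms = emg_rms, delta_power = delta, theta_power = theta,
    total_power = total,
    delta_theta_ratio = ifelse(theta > 0, delta / theta, NA_real_),
    theta_total_ratio = ifelse(total > 0, theta / total, NA_real_))
  attr(feats, "epoch_length_s") <- spectra$epoch_length_s
  attr(feats, "start_zt_s") <- spectra$start_zt_s
  class(feats) <- c("epoch_features", class(feats))
  feats
}

find_antimode <- function(v, fallback_q) {
  v <- v[is.finite(v)]
  fb <- as.numeric(quantile(v, fallback_q))
  if (length(unique(v)) < 10) return(fb)
  d <- density(v, n = 512)
  y <- d$y
  # local maxima of the density
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) < 2) return(fb)
  top2 <- sort(pk[order(y[pk], decreasing = TRUE)][1:2])
  valley <- seq.int(top2[1], top2[2])
  d$x[valley[which.min(y[valley])]]
}

#' Calibrate scoring thresholds
#'
#' `quantile`: self-calibrating per recording. The EMG cuts are the 60th
#' (wake) and 20th (atonia) percentiles of log EMG RMS. The spectral-ratio
#' cuts are density antimodes computed among sub-wake epochs (EMG below the
#' wake cut), where the NREM/REM contrast is bimodal; if no clear antimode
#' exists the cut falls back to a fixed quantile. `labeled`: cuts are chosen
#' by a quantile grid search maximizing epoch accuracy against a provided
#' (partial) reference hypnogram.
#'
#' @param features an [extract_features()] table (>= 100 epochs).
#' @param method `"quantile"` or `"labeled"`.
#' @param labels for `"labeled"`: a [hypnogram()] aligned to `features`, or a
#'   factor/character vector of reference states (`NA` = unlabeled).
#' @return object of class `scoring_thresholds`: the four cuts plus robust
#'   feature scales used by the classifier's nearest-cut fallback.
#' @export
calibrate_thresholds <- function(features, method = c("quantile", "labeled"),
                                 labels = NULL) {
  method <- match.arg(method)
  n <- nrow(features)
  if (n < 100) stop("calibration needs at least 100 epochs (got ", n, ")")
  le <- log(features$emg_rms)
  if (!all(is.finite(le)) || sd(le) == 0 ||
      !any(is.finite(features$delta_theta_ratio))) {
    stop("degenerate feature distribution: cannot calibrate")
  }
  scales <- list(
    s_emg = max(mad(le), 1e-6),
    s_theta = max(mad(features$theta_total_ratio, na.rm = TRUE), 1e-6),
    s_delta = max(mad(log(features$delta_theta_ratio), na.rm = TRUE), 1e-6))

  if (method == "quantile") {
    # wake cut: the antimode of log EMG RMS between its two main modes
    # (muscle tone is bimodal across wake vs sleep); the 60th percentile is
    # the fallback when no clear valley exists. A pure quantile cut fails
    # whenever wake occupancy strays far from the quantile, e.g. in
    # wake-dominated phenotypes.
    emg_wake_cut <- exp(find_antimode(le, 0.60))
    emg_atonia_cut <- exp(as.numeric(quantile(le, 0.20)))
    sub <- features$emg_rms < emg_wake_cut
    theta_ratio_cut <- find_antimode(features$theta_total_ratio[sub], 0.80)
    delta_ratio_cut <- exp(find_antimode(log(features$delta_theta_ratio[sub]),
                                         0.20))
    th <- list(emg_wake_cut = emg_wake_cut, emg_atonia_cut = emg_atonia_cut,
               delta_ratio_cut = delta_ratio_cut,
               theta_ratio_cut = theta_ratio_cut)
  } else {
    if (is.null(labels)) stop("labeled calibration requires labels")
    ref <- if (inherits(labels, "hypnogram")) as.character(labels$states)
           else as.character(labels)
    if (length(ref) != n) stop("labels must align with features")
    known <- !is.na(ref)
    if (sum(known) < 100) stop("labeled calibration needs >= 100 labeled epochs")
    qs <- seq(0.02, 0.98, by = 0.03)
    # wake cut: separate WAKE from sleep on log EMG
    cand_w <- as.numeric(quantile(le[known], qs))
    acc_w <- vapply(cand_w, function(ct) {
      mean((le[known] >= ct) == (ref[known] == "WAKE"))
    }, numeric(1))
    emg_wake_cut <- exp(cand_w[which.max(acc_w)])
    sleep <- known & ref != "WAKE" & le < log(emg_wake_cut)
    # atonia + theta cuts: pick REM out of sleep epochs
    cand_a <- as.numeric(quantile(le[sleep], qs))
    cand_t <- as.numeric(quantile(features$theta_total_ratio[sleep], qs,
                                  na.rm = TRUE))
    best <- c(-Inf, NA, NA)
    for (a in cand_a) for (tt in cand_t) {
      pred <- le[sleep] <= a & features$theta_total_ratio[sleep] >= tt
      ac <- mean(pred == (ref[sleep] == "REM"), na.rm = TRUE)
      if (ac > best[1]) best <- c(ac, a, tt)
    }
    emg_atonia_cut <- exp(best[2]); theta_ratio_cut <- best[3]
    # delta cut: NREM vs the rest among non-REM sleep-side epochs
    ldt <- log(features$delta_theta_ratio)
    cand_d <- as.numeric(quantile(ldt[known], qs, na.rm = TRUE))
    acc_d <- vapply(cand_d, function(ct) {
      mean((ldt[sleep] >= ct) == (ref[sleep] == "NREM"), na.rm = TRUE)
    }, numeric(1))
    delta_ratio_cut <- exp(cand_d[which.max(acc_d)])
    th <- list(emg_wake_cut = emg_wake_cut, emg_atonia_cut = emg_atonia_cut,
               delta_ratio_cut = delta_ratio_cut,
               theta_ratio_cut = theta_ratio_cut)
    # final selection: keep the self-calibrated quantile cuts unless the
    # grid-searched cuts beat them clearly on the labeled epochs (a small
    # margin guards against overfitting the labels when both are near
    # ceiling)
    th_q <- calibrate_thresholds(features, "quantile")
    acc_of <- function(thr) {
      pred <- classify(features, thr)
      mean(as.character(pred$states)[known] == ref[known])
    }
    thr_grid <- structure(c(th, scales, list(method = "labeled")),
                          class = "scoring_thresholds")
    if (acc_of(th_q) >= acc_of(thr_grid) - 0.002) {
      th <- th_q[c("emg_wake_cut", "emg_atonia_cut", "delta_ratio_cut",
                   "theta_ratio_cut")]
    }
  }
  if (th$emg_atonia_cut >= th$emg_wake_cut) {
    th$emg_atonia_cut <- th$emg_wake_cut * 0.5
  }
  structure(c(th, scales, list(method = method)),
            class = "scoring_thresholds")
}

#' @export
print.scoring_thresholds <- function(x, ...) {
  cat(sprintf("<scoring_thresholds> (%s) emg wake >= %.3g, atonia <= %.3g, delta/theta >= %.3g, theta/total >= %.3g\n",
              x$method, x$emg_wake_cut, x$emg_atonia_cut, x$delta_ratio_cut,
              x$theta_ratio_cut))
  invisible(x)
}

#' Classify epochs into vigilance states
#'
#' Deterministic, pointwise decision rule with precedence WAKE, REM, NREM:
#' WAKE if `emg_rms >= emg_wake_cut`; else REM if `emg_rms <= emg_atonia_cut`
#' and `theta_total_ratio >= theta_ratio_cut`; else NREM if
#' `delta_theta_ratio >= delta_ratio_cut`. An epoch matching no rule is
#' assigned the nearest class: each class's distance is the sum of its rule's
#' normalized deficits (shortfall from each cut divided by that feature's
#' robust scale, EMG and delta/theta on the log scale), ties resolving in
#' precedence order.
#'
#' @param features an [extract_features()] table.
#' @param thresholds a [calibrate_thresholds()] result.
#' @return a raw (unsmoothed) [hypnogram()].
#' @export
classify <- function(features, thresholds) {
  th <- thresholds
  le <- log(features$emg_rms)
  ttr <- features$theta_total_ratio
  ldt <- log(features$delta_theta_ratio)
  n <- nrow(features)

  wake <- le >= log(th$emg_wake_cut)
  rem <- !wake & le <= log(th$emg_atonia_cut) &
    !is.na(ttr) & ttr >= th$theta_ratio_cut
  nrem <- !wake & !rem & !is.na(ldt) & ldt >= log(th$delta_ratio_cut)

  out <- rep(NA_character_, n)
  out[wake] <- "WAKE"; out[rem] <- "REM"; out[nrem] <- "NREM"
  rest <- is.na(out)
  if (any(rest)) {
    dwake <- (log(th$emg_wake_cut) - le[rest]) / th$s_emg
    drem <- pmax(0, (le[rest] - log(th$emg_atonia_cut)) / th$s_emg) +
      pmax(0, (th$theta_ratio_cut - ttr[rest]) / th$s_theta)
    dnrem <- (log(th$delta_ratio_cut) - ldt[rest]) / th$s_delta
    dm <- cbind(WAKE = dwake, REM = drem, NREM = dnrem)
    dm[!is.finite(dm)] <- Inf
    pick <- apply(dm, 1, function(r) {
      if (all(!is.finite(r))) 1L else which.min(r) # ties: W, then R, then N
    })
    out[rest] <- colnames(dm)[pick]
  }
  hypnogram(out, attr(features, "epoch_length_s") %||% 4,
            attr(features, "start_zt_s") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Smooth a raw hypnogram
#'
#' Automated stand-in for the visual confirmation pass: an isolated
#' single-epoch state whose two neighbors agree is relabeled to the flanking
#' state. Applied once, left to right (earlier relabelings are visible to
#' later positions).
#'
#' @param hyp a [hypnogram()].
#' @param enabled set `FALSE` to disable (returns `hyp` unchanged).
#' @export
smooth_hypnogram <- function(hyp, enabled = TRUE) {
  if (!enabled) return(hyp)
  s <- as.character(hyp$states)
  n <- length(s)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (!is.na(s[i - 1]) && !is.na(s[i + 1]) && !is.na(s[i]) &&
          s[i - 1] == s[i + 1] && s[i] != s[i - 1]) {
        s[i] <- s[i - 1]
      }
    }
  }
  hypnogram(s, hyp$epoch_length_s, hyp$start_zt_s, hyp$artifact)
}

#' Apply manual corrections to a hypnogram
#'
#' Pointwise overrides, with an audit log of all edits retained as the
#' `corrections` attribute.
#'
#' @param hyp a [hypnogram()].
#' @param edits data frame with columns `epoch_index` (0-based) and `state`.
#' @export
apply_corrections <- function(hyp, edits) {
  log0 <- attr(hyp, "corrections")
  if (is.null(edits) || nrow(edits) == 0) return(hyp)
  idx <- edits$epoch_index
  if (any(idx < 0 | idx >= n_epochs(hyp))) {
    stop("edit epoch_index out of range [0, ", n_epochs(hyp) - 1, "]")
  }
  bad <- !edits$state %in% SOMN_STATES
  if (any(bad)) stop("unknown state in edits: ",
                     paste(unique(edits$state[bad]), collapse = ", "))
  s <- as.character(hyp$states)
  entry <- data.frame(epoch_index = idx, old = s[idx + 1L],
                      new = edits$state)
  s[idx + 1L] <- edits$state
  out <- hypnogram(s, hyp$epoch_length_s, hyp$start_zt_s, hyp$artifact)
  attr(out, "corrections") <- rbind(log0, entry)
  out
}

#' Agreement between a scored and a reference hypnogram
#'
#' Epoch-wise accuracy, Cohen's kappa, per-state recall, and the confusion
#' table, computed over epochs that are unflagged in the reference (artifact
#' epochs carry no reliable EEG and are excluded from scoring evaluation).
#'
#' @param pred scored [hypnogram()].
#' @param truth reference [hypnogram()].
#' @return list with `accuracy`, `kappa`, `recall` (named per state) and
#'   `confusion`.
#' @export
score_agreement <- function(pred, truth) {
  if (n_epochs(pred) != n_epochs(truth)) stop("hypnogram lengths differ")
  keep <- !truth$artifact & !is.na(truth$states) & !is.na(pred$states)
  p <- factor(pred$states[keep], levels = SOMN_STATES)
  t_ <- factor(truth$states[keep], levels = SOMN_STATES)
  cm <- table(truth = t_, pred = p)
  po <- sum(diag(cm)) / sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  list(accuracy = po, kappa = (po - pe) / (1 - pe), recall = recall,
       confusion = cm)
}
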