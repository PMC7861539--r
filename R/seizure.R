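#' Spike detection settings
#'
#' @param amplitude_threshold Minimum peak amplitude in mV (default 5, the
#'   boundary between background fluctuations and epileptiform spikes in
#'   this model).
#' @param stim_blank_window Seconds after each stimulus onset within which
#'   peaks are discarded as direct evoked responses (default 0.200).
#' @param min_peak_separation Minimum separation between counted peaks in
#'   seconds (default 0.100), so one discharge is not counted twice.
#' @return An object of class `"spike_detection_spec"`.
#' @export
spike_detection_spec <- function(amplitude_threshold = 5,
                                 stim_blank_window = 0.200,
                                 min_peak_separation = 0.100) {
  if (amplitude_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (stim_blank_window < 0) stop("blank window must be >= 0", call. = FALSE)
  structure(list(amplitude_threshold = amplitude_threshold,
                 stim_blank_window = stim_blank_window,
                 min_peak_separation = min_peak_separation),
            class = "spike_detection_spec")
}

#' Detect suprathreshold spikes in an LFP trace
#'
#' Finds strict local maxima above the amplitude threshold, at least
#' `min_peak_separation` apart (higher peaks win), and discards peaks
#' falling within the blanking window after any stimulus onset (direct
#' evoked responses are not spontaneous spikes).
#'
#' @param lfp Numeric LFP trace (mV).
#' @param time Matching time vector (s).
#' @param stim_onsets Stimulus onset times (s); may be empty.
#' @param spec A [spike_detection_spec()].
#' @return Sorted numeric vector of spike times (s).
#' @export
detect_spikes <- function(lfp, time, stim_onsets = numeric(0),
                          spec = spike_detection_spec()) {
  stopifnot(length(lfp) == length(time))
  dt <- if (length(time) > 1) time[2] - time[1] else 1
  min_dist <- max(1L, as.integer(round(spec$min_peak_separation / dt)))
  pk <- pracma::findpeaks(lfp, minpeakheight = spec$amplitude_threshold,
                          minpeakdistance = min_dist)
  if (is.null(pk)) return(numeric(0))
  times <- sort(time[pk[, 2]])
  if (length(stim_onsets) && spec$stim_blank_window > 0) {
    blanked <- vapply(times, function(tt)
      any(tt >= stim_onsets & tt <= stim_onsets + spec$stim_blank_window),
      logical(1))
    times <- times[!blanked]
  }
  times
}

#' Detect the onset of sustained spike discharges
#'
#' Ictal-like activity is operationalized as a run of `k` spikes occurring
#' in succession. The default reading requires every successive inter-spike
#' interval in the run to be at most `max_isi` seconds (spikes clustered in
#' time form a discharge); `rule = "min_isi"` instead requires every
#' interval to be at least `max_isi` (the literal wording of the criterion,
#' kept for reference).
#'
#' @param spike_times Sorted spike times (s).
#' @param k Run length (default 5 spikes).
#' @param max_isi Inter-spike-interval bound in seconds (default 4).
#' @param rule `"max_isi"` (default) or `"min_isi"`.
#' @return Time of the first spike of the earliest qualifying run, or `NA`
#'   if none exists.
#' @export
detect_onset <- function(spike_times, k = 5, max_isi = 4.0,
                         rule = c("max_isi", "min_isi")) {
  rule <- match.arg(rule)
  n <- length(spike_times)
  if (n < k) return(NA_real_)
  st <- sort(spike_times)
  gaps <- diff(st)
  ok <- if (rule == "max_isi") gaps <= max_isi else gaps >= max_isi
  # run of k spikes = k-1 consecutive qualifying gaps
  for (s in seq_len(n - k + 1)) {
    if (all(ok[s:(s + k - 2)])) return(st[s])
  }
  NA_real_
}

#' Spike and ictal-onset detection for one simulation
#'
#' @param result A [simulate_probing()] result.
#' @param spec A [spike_detection_spec()].
#' @param k,max_isi,rule Passed to [detect_onset()].
#' @param burn_in Seconds at the start of the trace excluded from spike
#'   detection (default 2, one stimulus period): the relaxation from the
#'   zero initial state can overshoot the spike threshold and is not
#'   epileptiform activity.
#' @return An object of class `"onset_result"`: list with `spike_times`
#'   (per population) and `onset_latency_s` (per population, NA if no
#'   onset).
#' @export
detect_ictal_onset <- function(result, spec = spike_detection_spec(),
                               k = 5, max_isi = 4.0, rule = "max_isi",
                               burn_in = 2.0) {
  stopifnot(inherits(result, "simulation_result"))
  spikes <- lapply(1:2, function(i) {
    st <- detect_spikes(result$lfp[, i], result$time,
                        result$stim_onset_times, spec)
    st[st >= burn_in]
  })
  onsets <- vapply(spikes, detect_onset, numeric(1),
                   k = k, max_isi = max_isi, rule = rule)
  structure(list(spike_times = spikes, onset_latency_s = onsets,
                 setting = result$setting$name, seed = result$seed),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat("Ictal-onset detection (", x$setting, ")\n", sep = "")
  for (i in 1:2)
    cat(sprintf("  population %d: %d spikes, onset %s\n", i,
                length(x$spike_times[[i]]),
                if (is.na(x$onset_latency_s[i])) "none"
                else sprintf("%.1f s", x$onset_latency_s[i])))
  invisible(x)
}

#' Pro-ictal safety experiment
#'
#' Repeats a seizure-eliciting simulation (a setting whose extended ramp
#' crosses the ictal threshold) across stimulus amplitudes, detects the
#' onset latency of sustained spike discharges in each realization, and
#' tests whether probing shifts the latency: one-way ANOVA across amplitude
#' groups plus Tukey HSD of every amplitude against the passive baseline.
#' Probing is safe when no amplitude differs significantly from passive
#' observation.
#'
#' @param setting A pro-ictal [build_setting()] result (e.g.
#'   `build_setting("II-A", proictal = TRUE)`).
#' @param amplitudes Stimulus amplitudes, must include 0.
#' @param n_realizations Realizations per amplitude (default 15).
#' @param base_seed Integer master seed.
#' @param spec An [integration_spec()].
#' @param spike_spec A [spike_detection_spec()].
#' @param population Which population's onset latency to analyse (default
#'   1, the ictogenic one).
#' @param alpha Significance level (default 0.05).
#' @return List of class `"proictal_result"`: `onsets` (data frame:
#'   `setting`, `amplitude`, `realization`, `seed`, `onset_latency_s`,
#'   `censored`), `anova_p`, `tukey` (comparison table vs passive), `alpha`.
#'   Realizations with no detected onset are censored and excluded from the
#'   statistics with a warning.
#' @export
proictal_experiment <- function(setting, amplitudes = c(0, 120),
                                n_realizations = 15, base_seed = 1,
                                spec = integration_spec(),
                                spike_spec = spike_detection_spec(),
                                population = 1L, alpha = 0.05) {
  if (!0 %in% amplitudes)
    stop("amplitudes must include 0 (passive baseline)", call. = FALSE)
  rows <- list()
  for (amp in amplitudes) {
    stim <- stimulus_protocol(amp, targets = setting$targets)
    for (r in seq_len(n_realizations)) {
      seed <- derive_seed(base_seed, setting$name, "proictal", amp, r)
      sp <- spec; sp$seed <- seed
      lat <- tryCatch({
        res <- simulate_probing(setting, stim, sp)
        on <- detect_ictal_onset(res, spike_spec)
        on$onset_latency_s[population]
      }, error = function(e) {
        warning(sprintf("amplitude %g realization %d failed: %s",
                        amp, r, conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      rows[[length(rows) + 1L]] <-
        data.frame(setting = setting$name, amplitude = amp, realization = r,
                   seed = seed, onset_latency_s = lat,
                   censored = is.na(lat))
    }
  }
  onsets <- do.call(rbind, rows)
  if (any(onsets$censored))
    warning(sprintf("%d realization(s) without detected onset were censored",
                    sum(onsets$censored)), call. = FALSE)
  usable <- onsets[!onsets$censored, ]
  anova_p <- NA_real_
  tukey <- NULL
  if (length(unique(usable$amplitude)) >= 2 &&
      all(table(usable$amplitude) >= 2)) {
    fit <- aov(onset_latency_s ~ factor(amplitude), data = usable)
    anova_p <- anova(fit)[["Pr(>F)"]][1]
    tukey <- tukey_hsd_vs_passive(usable$onset_latency_s, usable$amplitude,
                                  alpha)
  }
  structure(list(onsets = onsets, anova_p = anova_p, tukey = tukey,
                 alpha = alpha),
            class = "proictal_result")
}

#' @export
print.proictal_result <- function(x, ...) {
  cat("Pro-ictal safety experiment\n")
  agg <- stats::aggregate(onset_latency_s ~ amplitude,
                          data = x$onsets[!x$onsets$censored, ], FUN = mean)
  for (k in seq_len(nrow(agg)))
    cat(sprintf("  amplitude %g: mean onset %.1f s\n",
                agg$amplitude[k], agg$onset_latency_s[k]))
  cat(sprintf("  one-way ANOVA p = %.4g\n", x$anova_p))
  if (!is.null(x$tukey))
    cat(sprintf("  Tukey vs passive: %d/%d amplitudes significant at alpha = %g\n",
                sum(x$tukey$significant), nrow(x$tukey), x$alpha))
  invisible(x)
}
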