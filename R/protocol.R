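#' Periodic probing-stimulus protocol
#'
#' Low-frequency probing is modelled as rectangular pulses of afferent
#' pulse density: amplitude `amplitude` APs/s, width `pulse_width` (10 ms),
#' delivered every `period` seconds (2 s) to the input of the targeted
#' population(s), starting at `start_time`.
#'
#' @param amplitude Pulse amplitude in APs/s; 0 is passive observation.
#' @param pulse_width Pulse duration in seconds (default 0.010).
#' @param period Inter-pulse period in seconds (default 2).
#' @param targets Integer subset of `c(1, 2)`: which population(s) receive
#'   the stimulus.
#' @param start_time Time of the first pulse in seconds (default 2, one full
#'   period of burn-in from the zero initial state).
#' @return An object of class `"stimulus_protocol"`.
#' @examples
#' stim <- stimulus_protocol(120, targets = c(1, 2))
#' @export
stimulus_protocol <- function(amplitude, pulse_width = 0.010, period = 2.0,
                              targets = c(1L, 2L), start_time = 2.0) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0", call. = FALSE)
  if (!(pulse_width > 0 && pulse_width < period))
    stop("pulse_width must satisfy 0 < pulse_width < period", call. = FALSE)
  targets <- sort(unique(as.integer(targets)))
  if (length(targets) && !all(targets %in% 1:2))
    stop("targets must be a subset of c(1, 2)", call. = FALSE)
  if (!is.finite(start_time) || start_time < 0)
    stop("start_time must be finite and >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, pulse_width = pulse_width,
                 period = period, targets = targets,
                 start_time = start_time),
            class = "stimulus_protocol")
}

#' Stimulus value at given times
#'
#' @param t Time(s) in seconds, non-negative.
#' @param protocol A [stimulus_protocol()].
#' @param population Population index (1 or 2).
#' @return Stimulus pulse density in APs/s at each `t`: the protocol
#'   amplitude while a pulse is active and the population is targeted,
#'   otherwise 0.
#' @export
stimulus_value <- function(t, protocol, population) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  stopifnot(population %in% 1:2)
  if (!(population %in% protocol$targets) || protocol$amplitude == 0)
    return(numeric(length(t)) + 0 * t)
  rel <- t - protocol$start_time
  on <- rel >= 0 & (rel %% protocol$period) < protocol$pulse_width
  ifelse(on, protocol$amplitude, 0)
}

#' Scheduled stimulus onset times
#'
#' The pulse schedule is a property of the protocol timing alone, not of the
#' amplitude: a passive run (amplitude 0) has the same virtual schedule,
#' which anchors post-stimulus epoch extraction.
#'
#' @param protocol A [stimulus_protocol()].
#' @param duration Simulation duration in seconds.
#' @return Numeric vector of onset times (s) strictly before `duration`.
#' @export
stimulus_onsets <- function(protocol, duration) {
  if (protocol$start_time >= duration) return(numeric(0))
  seq(protocol$start_time, duration - 1e-12, by = protocol$period)
}

#' Linear ramp of an ictogenic parameter
#'
#' One parameter (`"A1"` excitatory gain of population 1, `"B1"` its slow
#' inhibitory gain, or `"K"` the coupling gain) is shifted linearly in time
#' from `start_value` at `t_start` to `end_value` at `t_end` and held
#' constant outside that window.
#'
#' @param parameter One of `"A1"`, `"B1"`, `"K"`.
#' @param start_value,end_value Parameter values at the ramp endpoints.
#' @param t_start,t_end Ramp window in seconds (`t_start < t_end`). `t_end =
#'   NA` means "the full simulation duration" and is resolved when a
#'   simulation is run.
#' @return An object of class `"parameter_ramp"`.
#' @export
parameter_ramp <- function(parameter, start_value, end_value,
                           t_start = 0, t_end = NA_real_) {
  parameter <- match.arg(parameter, c("A1", "B1", "K"))
  if (!is.na(t_end) && !(t_start < t_end))
    stop("t_start must be < t_end", call. = FALSE)
  structure(list(parameter = parameter,
                 start_value = start_value, end_value = end_value,
                 t_start = t_start, t_end = t_end),
            class = "parameter_ramp")
}

#' Ramp value at given times
#'
#' @param t Time(s) in seconds.
#' @param ramp A [parameter_ramp()] with a resolved (non-`NA`) `t_end`.
#' @return Linearly interpolated parameter value(s), clamped to the endpoint
#'   values outside `[t_start, t_end]`.
#' @export
ramp_value <- function(t, ramp) {
  if (is.na(ramp$t_end))
    stop("ramp t_end is unresolved (NA); supply a duration", call. = FALSE)
  frac <- (t - ramp$t_start) / (ramp$t_end - ramp$t_start)
  frac <- pmin(pmax(frac, 0), 1)
  ramp$start_value + frac * (ramp$end_value - ramp$start_value)
}

# Registry of the named experimental settings. Settings "I-*" probe the
# non-ictogenic population 2 while a parameter of population 1 (or the
# coupling) ramps towards ictal activity; "II-*" probe both populations;
# "S-*" probe the ictogenic population 1 only. Pro-ictal variants extend the
# ramp past the ictal threshold; only the A ramp extension (4.30 -> 4.95) is
# an established value, the B and K extensions are package defaults.
setting_registry <- function() {
  list(
    "I-A"  = list(ramp = c("A1", 2.5, 4.6),  targets = 2L),
    "I-B"  = list(ramp = c("B1", 45, 30),    targets = 2L),
    "I-K"  = list(ramp = c("K", 0, 0.5),     targets = 2L),
    "II-A" = list(ramp = c("A1", 2.5, 4.6),  targets = c(1L, 2L)),
    "II-B" = list(ramp = c("B1", 45, 30),    targets = c(1L, 2L)),
    "II-K" = list(ramp = c("K", 0, 0.5),     targets = c(1L, 2L)),
    "S-A"  = list(ramp = c("A1", 2.5, 4.6),  targets = 1L),
    "S-B"  = list(ramp = c("B1", 45, 30),    targets = 1L)
  )
}

proictal_ramps <- function() {
  list(A1 = c(4.30, 4.95),  # established pro-ictal excitability ramp
       B1 = c(45, 25),      # package default, crosses the ictal threshold
       K  = c(0, 0.8))      # package default, crosses the ictal threshold
}

#' Construct a model setting
#'
#' @param name Setting id: `"I-A"`, `"I-B"`, `"I-K"` (probe population 2),
#'   `"II-A"`, `"II-B"`, `"II-K"` (probe both), `"S-A"`, `"S-B"` (probe the
#'   ictogenic population 1).
#' @param config Base [coupled_config()]; non-ramped parameters keep their
#'   defaults.
#' @param ramp_start,ramp_end Optional overrides of the ramp endpoints.
#' @param t_start,t_end Optional ramp window (default: the full simulation).
#' @param proictal If `TRUE`, use the extended ramp that crosses the ictal
#'   threshold (for the pro-ictal safety experiment).
#' @return An object of class `"model_setting"` with fields `name`, `config`,
#'   `ramp` and `targets`.
#' @examples
#' build_setting("I-B")
#' build_setting("II-A", proictal = TRUE)
#' @export
build_setting <- function(name, config = coupled_config(),
                          ramp_start = NULL, ramp_end = NULL,
                          t_start = 0, t_end = NA_real_,
                          proictal = FALSE) {
  reg <- setting_registry()
  if (!name %in% names(reg))
    stop("unknown setting '", name, "'; valid settings: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  entry <- reg[[name]]
  par <- entry$ramp[1]
  lo <- as.numeric(entry$ramp[2]); hi <- as.numeric(entry$ramp[3])
  if (isTRUE(proictal)) {
    ext <- proictal_ramps()[[par]]
    lo <- ext[1]; hi <- ext[2]
  }
  if (!is.null(ramp_start)) lo <- ramp_start
  if (!is.null(ramp_end)) hi <- ramp_end
  model_setting(name = if (isTRUE(proictal)) paste0(name, "-proictal") else name,
                config = config,
                ramp = parameter_ramp(par, lo, hi, t_start, t_end),
                targets = entry$targets)
}

#' Assemble a model setting from its parts
#'
#' Lower-level constructor behind [build_setting()]; useful for custom
#' experiments, e.g. fixed-parameter runs with `ramp = NULL`.
#'
#' @param name Arbitrary label.
#' @param config A [coupled_config()].
#' @param ramp A [parameter_ramp()] or `NULL` for constant parameters.
#' @param targets Populations receiving the probing stimulus.
#' @return An object of class `"model_setting"`.
#' @export
model_setting <- function(name, config = coupled_config(), ramp = NULL,
                          targets = c(1L, 2L)) {
  if (!is.null(ramp)) stopifnot(inherits(ramp, "parameter_ramp"))
  stopifnot(inherits(config, "coupled_config"))
  targets <- sort(unique(as.integer(targets)))
  structure(list(name = name, config = config, ramp = ramp,
                 targets = targets),
            class = "model_setting")
}

#' @export
print.model_setting <- function(x, ...) {
  cat("Model setting:", x$name, "\n")
  if (!is.null(x$ramp))
    cat(sprintf("  ramp: %s %.3g -> %.3g\n", x$ramp$parameter,
                x$ramp$start_value, x$ramp$end_value))
  else cat("  ramp: none (constant parameters)\n")
  cat("  stimulus targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}
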