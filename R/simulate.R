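#' Integration settings
#'
#' @param dt Step size in seconds (default 0.00195, the 512 Hz sampling
#'   convention of the model).
#' @param duration Total simulated time in seconds (default 2000).
#' @param seed Integer RNG seed; `NULL` leaves the current RNG state alone.
#' @param record_states If `TRUE`, keep the full 20-dimensional state
#'   trajectory (memory-heavy; intended for short runs).
#' @param noise_mode `"per_sample"` draws one `N(mu, sigma)` pulse-density
#'   value per step, held constant over the step (the convention of this
#'   model lineage; the effective noise power then depends on `dt`).
#'   `"sqrt_dt"` scales the deviation by `1/sqrt(dt)` so the accumulated
#'   noise matches a true Euler-Maruyama diffusion of intensity `sigma`.
#' @return An object of class `"integration_spec"`.
#' @export
integration_spec <- function(dt = 0.00195, duration = 2000, seed = NULL,
                             record_states = FALSE,
                             noise_mode = c("per_sample", "sqrt_dt")) {
  noise_mode <- match.arg(noise_mode)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  structure(list(dt = dt, duration = duration, seed = seed,
                 record_states = isTRUE(record_states),
                 noise_mode = noise_mode),
            class = "integration_spec")
}

#' Gaussian pulse-density input stream
#'
#' @param spec A [noise_spec()].
#' @param seed Integer seed.
#' @param n_steps Number of values to draw.
#' @return Numeric vector of `n_steps` i.i.d. `N(mu, sigma)` pulse densities
#'   (APs/s).
#' @export
noise_stream <- function(spec, seed, n_steps) {
  stopifnot(inherits(spec, "noise_spec"), n_steps > 0)
  set.seed(seed)
  rnorm(n_steps, spec$mu, spec$sigma)
}

#' Simulate the coupled stochastic delayed system
#'
#' Integrates the two-population model with the explicit Euler-Maruyama
#' scheme: at each step one `N(mu, sigma)` pulse-density value is drawn per
#' population, the ramped parameter (if any) is evaluated at the step's left
#' endpoint, delayed partner activity is read from a ring buffer of
#' `round(tau_d / dt)` steps (zeros before `t = tau_d`), and the state is
#' advanced by `dt` times the derivative field. The recorded sample `n` is
#' the state after step `n` (time `n * dt`), with the LFP combining that
#' state and the delayed partner value the step used. A given
#' `(setting, stimulus, spec, seed)` combination reproduces bit-identical
#' output.
#'
#' @param setting A [model_setting()] or [build_setting()] result.
#' @param stimulus A [stimulus_protocol()]; its targets default to the
#'   setting's targets.
#' @param spec An [integration_spec()].
#' @return An object of class `"simulation_result"` with elements `time`
#'   (s), `lfp` (matrix, one column per population, mV), `param` (ramped
#'   parameter value per sample), `stim_onset_times` (grid times at which a
#'   pulse was delivered), `schedule` (virtual onset grid times, amplitude
#'   independent), `stim` (per-sample stimulus matrix), `seed`, `setting`,
#'   `stimulus`, `spec`, and optionally `states`.
#' @examples
#' \donttest{
#' s <- build_setting("II-K")
#' res <- simulate_probing(s, stimulus_protocol(120, targets = s$targets),
#'                         integration_spec(duration = 60, seed = 1))
#' }
#' @export
simulate_probing <- function(setting,
                             stimulus = stimulus_protocol(0, targets = setting$targets),
                             spec = integration_spec()) {
  stopifnot(inherits(setting, "model_setting"),
            inherits(stimulus, "stimulus_protocol"),
            inherits(spec, "integration_spec"))
  cfg <- setting$config
  dt <- spec$dt
  n_steps <- floor(spec$duration / dt)
  if (n_steps < 1) stop("duration shorter than one step", call. = FALSE)
  if (spec$duration < stimulus$period)
    stop("duration must cover at least one stimulus period", call. = FALSE)
  g <- max(cfg$params_1$g, cfg$params_2$g)
  if (dt >= 2 / g)
    warning("dt >= 2/g: explicit Euler is unstable for the fast inhibitory block")

  # ramp resolved over the full run unless a window was given
  ramp <- setting$ramp
  ramp_which <- 0L
  ramp_par <- numeric(0)
  te <- (seq_len(n_steps) - 1) * dt  # left endpoints where the RHS is evaluated
  if (!is.null(ramp)) {
    if (is.na(ramp$t_end)) ramp$t_end <- spec$duration
    ramp_which <- match(ramp$parameter, c("A1", "B1", "K"))
    ramp_par <- ramp_value(te, ramp)
  }

  stim1 <- stimulus_value(te, stimulus, 1L)
  stim2 <- stimulus_value(te, stimulus, 2L)

  noise_sd_scale <- if (spec$noise_mode == "sqrt_dt") 1 / sqrt(dt) else 1
  pars <- c(cfg$params_1$A, cfg$params_1$B, cfg$params_1$G,
            cfg$params_2$A, cfg$params_2$B, cfg$params_2$G,
            cfg$params_1$a, cfg$params_1$b, cfg$params_1$g,
            cfg$params_1$C1, cfg$params_1$C2, cfg$params_1$C3,
            cfg$params_1$C4, cfg$params_1$C5, cfg$params_1$C6,
            cfg$params_1$C7,
            cfg$params_1$v0, cfg$params_1$e0, cfg$params_1$r,
            cfg$K,
            cfg$noise_1$mu, cfg$noise_1$sigma * noise_sd_scale,
            cfg$noise_2$mu, cfg$noise_2$sigma * noise_sd_scale)

  delay_steps <- as.integer(round(cfg$tau_d / dt))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  couple_sig <- if (identical(cfg$coupling_signal, "lfp")) 1L else 0L
  raw <- em_integrate_cpp(pars, as.integer(n_steps), dt, delay_steps,
                          as.integer(ramp_which), ramp_par,
                          stim1, stim2,
                          cfg$lfp_include_coupling, couple_sig,
                          spec$record_states)

  # onset grid times: left endpoint of the first step inside each pulse
  sched <- stimulus_onsets(stimulus, spec$duration)
  onset_idx <- ceiling(sched / dt - 1e-9) + 1
  keep <- onset_idx <= n_steps
  sched_times <- (onset_idx[keep] - 1) * dt
  delivered <- if (stimulus$amplitude > 0 && length(stimulus$targets))
    sched_times else numeric(0)

  out <- list(time = seq_len(n_steps) * dt,
              lfp = cbind(lfp1 = raw$lfp1, lfp2 = raw$lfp2),
              param = if (ramp_which > 0) ramp_par else
                rep(NA_real_, n_steps),
              stim = cbind(stim1 = stim1, stim2 = stim2),
              stim_onset_times = delivered,
              schedule = sched_times,
              onset_idx = onset_idx[keep],
              seed = spec$seed,
              setting = setting, stimulus = stimulus, spec = spec)
  if (spec$record_states) out$states <- raw$states
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation result:", x$setting$name, "\n")
  cat(sprintf("  %d samples at dt = %.5g s (%.1f s), seed = %s\n",
              length(x$time), x$spec$dt, max(x$time),
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  stimulus: amplitude %.3g APs/s, %d scheduled pulses\n",
              x$stimulus$amplitude, length(x$schedule)))
  invisible(x)
}

#' Write LFP traces to CSV
#'
#' Columns: `time_s`, `lfp1_mV`, `lfp2_mV`, `param_value`, `stim1`, `stim2`.
#'
#' @param result A [simulate_probing()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lfp_csv <- function(result, path) {
  stopifnot(inherits(result, "simulation_result"))
  df <- data.frame(time_s = result$time,
                   lfp1_mV = result$lfp[, 1], lfp2_mV = result$lfp[, 2],
                   param_value = result$param,
                   stim1 = result$stim[, 1], stim2 = result$stim[, 2])
  data.table::fwrite(df, path)
  invisible(path)
}
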