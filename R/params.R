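#' Parameters of one Wendling neural mass population
#'
#' A single population lumps four interacting neural masses of the CA1
#' circuit: pyramidal cells, excitatory interneurons (the excitatory
#' self-feedback loop), slow dendrite-projecting inhibitory interneurons and
#' fast soma-projecting inhibitory interneurons. Each synaptic pathway is a
#' second-order linear "pulse to wave" filter with gain `A`, `B` or `G` (mV)
#' and rate constant `a`, `b` or `g` (1/s); firing is generated from the mean
#' membrane potential by the asymmetric sigmoid "wave to pulse" function with
#' parameters `v0` (mV), `e0` (1/s) and `r` (1/mV).
#'
#' Defaults are the standard values for this model: `A = 4`, `B = 40`,
#' `G = 20` mV, `a = 100`, `b = 50`, `g = 350` 1/s, `C1 = 135` with the
#' remaining connectivity constants as fixed fractions of `C1`, and
#' `v0 = 6` mV, `e0 = 2.5` 1/s, `r = 0.56` 1/mV.
#'
#' @param A Average excitatory synaptic gain (mV).
#' @param B Average slow dendritic inhibitory gain (mV).
#' @param G Average fast somatic inhibitory gain (mV).
#' @param a,b,g Synaptic rate constants of the excitatory, slow inhibitory
#'   and fast inhibitory filters (1/s).
#' @param C1,C2,C3,C4,C5,C6,C7 Mean numbers of synaptic contacts
#'   (dimensionless). `C2`, ..., `C7` default to the usual fixed fractions of
#'   `C1`.
#' @param v0 Sigmoid half-activation potential (mV).
#' @param e0 Half of the maximal firing rate (1/s); the sigmoid saturates at
#'   `2 * e0`.
#' @param r Sigmoid steepness (1/mV).
#' @return An object of class `"population_params"` (a named list).
#' @examples
#' p <- population_params()            # normal background regime
#' p_ictal <- population_params(A = 5) # hyperexcitable, seizes
#' @export
population_params <- function(A = 4.0, B = 40, G = 20,
                              a = 100, b = 50, g = 350,
                              C1 = 135, C2 = 0.8 * C1,
                              C3 = 0.25 * C1, C4 = 0.25 * C1,
                              C5 = 0.1 * C1, C6 = 0.1 * C1, C7 = 0.8 * C1,
                              v0 = 6, e0 = 2.5, r = 0.56) {
  p <- list(A = A, B = B, G = G, a = a, b = b, g = g,
            C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5, C6 = C6, C7 = C7,
            v0 = v0, e0 = e0, r = r)
  vals <- unlist(p)
  if (!all(is.finite(vals)))
    stop("all population parameters must be finite", call. = FALSE)
  if (any(c(a, b, g) <= 0))
    stop("rate constants a, b, g must be positive", call. = FALSE)
  if (e0 <= 0 || r <= 0)
    stop("sigmoid parameters e0 and r must be positive", call. = FALSE)
  if (any(c(C1, C2, C3, C4, C5, C6, C7) <= 0))
    stop("connectivity constants C1..C7 must be positive", call. = FALSE)
  structure(p, class = "population_params")
}

#' Gaussian afferent pulse-density input
#'
#' The external drive to the pyramidal cells of each population, modelling
#' the density of afferent action potentials as independent normal draws.
#'
#' @param mu Mean pulse density (APs/s).
#' @param sigma Standard deviation (APs/s); must be non-negative.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(mu = 90, sigma = 1.3) {
  if (!is.finite(mu) || !is.finite(sigma))
    stop("mu and sigma must be finite", call. = FALSE)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "noise_spec")
}

#' Configuration of the coupled two-population model
#'
#' Two populations are coupled bidirectionally through their pyramidal
#' cells with equal gain `K` and a transmission delay `tau_d`, modelling
#' inter-hemispheric hippocampal interaction.
#'
#' @param params_1,params_2 [population_params()] of populations 1 and 2.
#' @param K Inter-population coupling gain (dimensionless, applied equally in
#'   both directions); must be non-negative.
#' @param tau_d Coupling delay in seconds (default 0.010 s).
#' @param noise_1,noise_2 [noise_spec()] inputs of the two populations.
#' @param lfp_include_coupling Whether the simulated LFP of a population
#'   includes the delayed coupling contribution from its partner (default
#'   `TRUE`; the LFP then equals the full pyramidal membrane potential that
#'   drives firing).
#' @param coupling_signal Which delayed partner signal the coupling gain
#'   multiplies: `"y1"` (default) uses the partner's excitatory PSP state
#'   `y1`, which carries a sizeable DC component and makes the coupling
#'   strongly excitatory; `"lfp"` uses the partner's net pyramidal
#'   potential `y1 - y2 - y3`, a much weaker drive.
#' @return An object of class `"coupled_config"`.
#' @examples
#' cfg <- coupled_config(K = 0.3)
#' @export
coupled_config <- function(params_1 = population_params(),
                           params_2 = population_params(),
                           K = 0.3, tau_d = 0.010,
                           noise_1 = noise_spec(), noise_2 = noise_spec(),
                           lfp_include_coupling = TRUE,
                           coupling_signal = c("y1", "lfp")) {
  coupling_signal <- match.arg(coupling_signal)
  stopifnot(inherits(params_1, "population_params"),
            inherits(params_2, "population_params"),
            inherits(noise_1, "noise_spec"),
            inherits(noise_2, "noise_spec"))
  if (!is.finite(K) || K < 0) stop("K must be finite and >= 0", call. = FALSE)
  if (!is.finite(tau_d) || tau_d < 0)
    stop("tau_d must be finite and >= 0", call. = FALSE)
  structure(list(params_1 = params_1, params_2 = params_2,
                 K = K, tau_d = tau_d,
                 noise_1 = noise_1, noise_2 = noise_2,
                 lfp_include_coupling = isTRUE(lfp_include_coupling),
                 coupling_signal = coupling_signal),
            class = "coupled_config")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Wendling population parameters\n")
  cat(sprintf("  gains (mV): A=%.3g B=%.3g G=%.3g\n", x$A, x$B, x$G))
  cat(sprintf("  rates (1/s): a=%.3g b=%.3g g=%.3g\n", x$a, x$b, x$g))
  cat(sprintf("  contacts: C1=%.3g C2=%.3g C3=%.3g C4=%.3g C5=%.3g C6=%.3g C7=%.3g\n",
              x$C1, x$C2, x$C3, x$C4, x$C5, x$C6, x$C7))
  cat(sprintf("  sigmoid: v0=%.3g mV, e0=%.3g 1/s, r=%.3g 1/mV\n", x$v0, x$e0, x$r))
  invisible(x)
}

#' @export
print.coupled_config <- function(x, ...) {
  cat("Coupled two-population model configuration\n")
  cat(sprintf("  K = %.3g, tau_d = %.4g s\n", x$K, x$tau_d))
  cat(sprintf("  noise: pop1 N(%.3g, %.3g), pop2 N(%.3g, %.3g) APs/s\n",
              x$noise_1$mu, x$noise_1$sigma, x$noise_2$mu, x$noise_2$sigma))
  cat(sprintf("  pop1: A=%.3g B=%.3g G=%.3g | pop2: A=%.3g B=%.3g G=%.3g\n",
              x$params_1$A, x$params_1$B, x$params_1$G,
              x$params_2$A, x$params_2$B, x$params_2$G))
  invisible(x)
}
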