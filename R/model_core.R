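#' Wave-to-pulse sigmoid
#'
#' Converts an average membrane potential into an average firing (pulse)
#' density: `S(v) = 2 * e0 / (1 + exp(r * (v0 - v)))`. The function is
#' strictly increasing, bounded in `(0, 2 * e0)`, and equals `e0` exactly at
#' `v = v0`.
#'
#' @param v Membrane potential (mV); may be a vector.
#' @param params A [population_params()] supplying `e0`, `r`, `v0`.
#' @return Firing rate(s) in APs/s, same length as `v`.
#' @examples
#' wendling_sigmoid(6, population_params())  # e0 = 2.5 at v0
#' @export
wendling_sigmoid <- function(v, params = population_params()) {
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("v must be finite numeric", call. = FALSE)
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

# state layout: 20 scalars, population 1 occupies 1:10 (y0..y9),
# population 2 occupies 11:20.
state_index <- function(population, j) (population - 1L) * 10L + j + 1L

check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 20L)
    stop("state must be a numeric vector of length 20 (2 populations x y0..y9)",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  invisible(state)
}

#' Time derivative of the coupled two-population state
#'
#' Evaluates the right-hand side of the ten first-order equations governing
#' each population. For population `i` with partner `j` (using `S` for the
#' sigmoid of population `i` and dropping the population index on
#' parameters):
#' \preformatted{
#'   y0' = y5;  y5' = A a S[K y1_j(t - tau_d) + y1 - y2 - y3] - 2 a y5 - a^2 y0
#'   y1' = y6;  y6' = A a (s + p + C2 S[C1 y0])               - 2 a y6 - a^2 y1
#'   y2' = y7;  y7' = B b C4 S[C3 y0]                         - 2 b y7 - b^2 y2
#'   y3' = y8;  y8' = G g C7 S[C5 y0 - C6 y4]                 - 2 g y8 - g^2 y3
#'   y4' = y9;  y9' = B b S[C3 y0]                            - 2 b y9 - b^2 y4
#' }
#' where `p` is the stochastic afferent pulse density and `s` the probing
#' stimulus.
#'
#' @param state Numeric vector of length 20: population 1 occupies positions
#'   1..10 (`y0..y9`), population 2 positions 11..20.
#' @param p Length-2 vector of afferent pulse densities (APs/s).
#' @param s Length-2 vector of probing stimulus values (APs/s).
#' @param delayed_y1 Length-2 vector; element `i` is the partner's `y1` at
#'   `t - tau_d` as seen by population `i`.
#' @param config A [coupled_config()].
#' @return Numeric vector of length 20 with the time derivatives.
#' @export
wendling_derivatives <- function(state, p, s, delayed_y1,
                                 config = coupled_config()) {
  check_state(state)
  stopifnot(length(p) == 2L, length(s) == 2L, length(delayed_y1) == 2L)
  if (any(!is.finite(c(p, s, delayed_y1))))
    stop("inputs must be finite", call. = FALSE)
  d <- numeric(20L)
  for (i in 1:2) {
    par <- if (i == 1L) config$params_1 else config$params_2
    y <- state[state_index(i, 0:9)]
    S <- function(v) wendling_sigmoid(v, par)
    A <- par$A; B <- par$B; G <- par$G
    a <- par$a; b <- par$b; g <- par$g
    dy <- numeric(10L)
    dy[1]  <- y[6]
    dy[6]  <- A * a * S(config$K * delayed_y1[i] + y[2] - y[3] - y[4]) -
      2 * a * y[6] - a^2 * y[1]
    dy[2]  <- y[7]
    dy[7]  <- A * a * (s[i] + p[i] + par$C2 * S(par$C1 * y[1])) -
      2 * a * y[7] - a^2 * y[2]
    dy[3]  <- y[8]
    dy[8]  <- B * b * par$C4 * S(par$C3 * y[1]) - 2 * b * y[8] - b^2 * y[3]
    dy[4]  <- y[9]
    dy[9]  <- G * g * par$C7 * S(par$C5 * y[1] - par$C6 * y[5]) -
      2 * g * y[9] - g^2 * y[4]
    dy[5]  <- y[10]
    dy[10] <- B * b * S(par$C3 * y[1]) - 2 * b * y[10] - b^2 * y[5]
    d[state_index(i, 0:9)] <- dy
  }
  d
}

#' Simulated local field potential of each population
#'
#' The model output is the average post-synaptic potential of the pyramidal
#' cells: the sum of the excitatory feedback contribution and (with
#' `lfp_include_coupling`) the delayed input from the partner population,
#' minus both inhibitory contributions,
#' `LFP_i = K * y1_j(t - tau_d) + y1_i - y2_i - y3_i`.
#'
#' @inheritParams wendling_derivatives
#' @return Length-2 numeric vector of LFP values (mV).
#' @export
lfp_output <- function(state, delayed_y1 = c(0, 0),
                       config = coupled_config()) {
  check_state(state)
  stopifnot(length(delayed_y1) == 2L)
  Kterm <- if (config$lfp_include_coupling) config$K * delayed_y1 else c(0, 0)
  vapply(1:2, function(i) {
    Kterm[i] + state[state_index(i, 1L)] -
      state[state_index(i, 2L)] - state[state_index(i, 3L)]
  }, numeric(1))
}
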