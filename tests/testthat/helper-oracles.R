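# Independent reference implementations used as oracles. These are written
# as direct transliterations of the governing equations and definitional
# formulas, deliberately sharing no code with the package internals.

oracle_sigmoid <- function(v, e0 = 2.5, r = 0.56, v0 = 6) {
  2 * e0 / (1 + exp(r * (v0 - v)))
}

# Right-hand side of the ten equations per population, straight off the page.
oracle_derivatives <- function(state, p, s, delayed, cfg) {
  out <- numeric(20)
  for (i in 1:2) {
    pp <- if (i == 1) cfg$params_1 else cfg$params_2
    y <- function(j) state[(i - 1) * 10 + j + 1]     # y_j of population i
    S <- function(v) oracle_sigmoid(v, pp$e0, pp$r, pp$v0)
    d <- c(
      y(5),
      y(6),
      y(7),
      y(8),
      y(9),
      pp$A * pp$a * S(cfg$K * delayed[i] + y(1) - y(2) - y(3)) -
        2 * pp$a * y(5) - pp$a^2 * y(0),
      pp$A * pp$a * (s[i] + p[i] + pp$C2 * S(pp$C1 * y(0))) -
        2 * pp$a * y(6) - pp$a^2 * y(1),
      pp$B * pp$b * pp$C4 * S(pp$C3 * y(0)) - 2 * pp$b * y(7) - pp$b^2 * y(2),
      pp$G * pp$g * pp$C7 * S(pp$C5 * y(0) - pp$C6 * y(4)) -
        2 * pp$g * y(8) - pp$g^2 * y(3),
      pp$B * pp$b * S(pp$C3 * y(0)) - 2 * pp$b * y(9) - pp$b^2 * y(4)
    )
    # d is ordered (y0', y1', y2', y3', y4', y5', y6', y7', y8', y9')
    out[(i - 1) * 10 + 1:10] <- d[c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)]
  }
  out
}

# Equilibrium of the symmetric noiseless system by fixed-point iteration on
# the pyramidal PSP state y0 (velocities vanish; both populations equal).
oracle_fixed_point <- function(cfg, p = 90, tol = 1e-13, itmax = 10000) {
  pp <- cfg$params_1
  S <- function(v) oracle_sigmoid(v, pp$e0, pp$r, pp$v0)
  y0 <- 0
  for (it in seq_len(itmax)) {
    y1 <- (pp$A / pp$a) * (p + pp$C2 * S(pp$C1 * y0))
    y2 <- (pp$B / pp$b) * pp$C4 * S(pp$C3 * y0)
    y4 <- (pp$B / pp$b) * S(pp$C3 * y0)
    y3 <- (pp$G / pp$g) * pp$C7 * S(pp$C5 * y0 - pp$C6 * y4)
    new_y0 <- (pp$A / pp$a) * S(cfg$K * y1 + y1 - y2 - y3)
    if (abs(new_y0 - y0) < tol) break
    y0 <- new_y0
  }
  y1 <- (pp$A / pp$a) * (p + pp$C2 * S(pp$C1 * y0))
  y2 <- (pp$B / pp$b) * pp$C4 * S(pp$C3 * y0)
  y4 <- (pp$B / pp$b) * S(pp$C3 * y0)
  y3 <- (pp$G / pp$g) * pp$C7 * S(pp$C5 * y0 - pp$C6 * y4)
  list(y0 = y0, y1 = y1, y2 = y2, y3 = y3, y4 = y4,
       lfp = cfg$K * y1 + y1 - y2 - y3)
}

# Definitional feature implementations.
oracle_variance <- function(x) mean((x - mean(x))^2)
oracle_skewness <- function(x) {
  d <- x - mean(x); mean(d^3) / mean(d^2)^1.5
}
oracle_kurtosis <- function(x) {
  d <- x - mean(x); mean(d^4) / mean(d^2)^2
}
oracle_lag1 <- function(x) {
  n <- length(x); d <- x - mean(x)
  sum(d[1:(n - 1)] * d[2:n]) / sum(d^2)
}
oracle_mi <- function(x, y, n_bins = 16) {
  cut_bins <- function(v) {
    if (diff(range(v)) == 0) return(rep(1L, length(v)))
    as.integer(cut(v, breaks = seq(min(v), max(v), length.out = n_bins + 1),
                   include.lowest = TRUE))
  }
  bx <- cut_bins(x); by <- cut_bins(y)
  n <- length(x)
  mi <- 0
  for (ix in unique(bx)) for (iy in unique(by)) {
    pxy <- sum(bx == ix & by == iy) / n
    if (pxy > 0) {
      px <- sum(bx == ix) / n; py <- sum(by == iy) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Spearman: rank (average ranks for ties) then the Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive scan over all k-spike windows for the discharge-onset rule.
oracle_onset <- function(st, k = 5, max_isi = 4) {
  st <- sort(st)
  n <- length(st)
  if (n < k) return(NA_real_)
  for (s in 1:(n - k + 1)) {
    w <- st[s:(s + k - 1)]
    if (all(diff(w) <= max_isi)) return(w[1])
  }
  NA_real_
}

# Studentized-range significance of one pairwise contrast under equal n.
oracle_tukey_p <- function(g1, g2, groups) {
  all_g <- c(list(g1, g2), groups)
  k <- length(all_g)
  n <- lengths(all_g)
  N <- sum(n)
  gm <- vapply(all_g, mean, numeric(1))
  mse <- sum(vapply(all_g, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  se <- sqrt(mse / 2 * (1 / n[1] + 1 / n[2]))
  q <- abs(gm[1] - gm[2]) / se
  stats::ptukey(q, k, N - k, lower.tail = FALSE)
}

quiet_config <- function() coupled_config()

random_state <- function() runif(20, -10, 10)
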