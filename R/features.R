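#' Extract post-stimulus epochs
#'
#' Cuts one window of `window_s` seconds out of each population's LFP,
#' starting at the sample of each (virtual) stimulus onset. The schedule is
#' amplitude-independent, so passive runs yield the same epoch grid as
#' probed runs. Epochs that would extend past the end of the trace are
#' dropped.
#'
#' @param result A [simulate_probing()] result.
#' @param window_s Epoch length in seconds (default 0.400).
#' @return An object of class `"epoch_matrix"`: a list with `onset_times`,
#'   `window_n`, and `epochs` — a 3-d array `window_n x n_epochs x 2`
#'   (populations in the third dimension).
#' @export
extract_epochs <- function(result, window_s = 0.400) {
  stopifnot(inherits(result, "simulation_result"))
  dt <- result$spec$dt
  if (window_s >= result$stimulus$period)
    stop("epoch window must be shorter than the stimulus period",
         call. = FALSE)
  if (!length(result$schedule))
    stop("empty stimulus schedule: nothing to epoch", call. = FALSE)
  window_n <- as.integer(floor(window_s / dt))
  n <- nrow(result$lfp)
  starts <- result$onset_idx
  starts <- starts[starts + window_n - 1 <= n]
  if (!length(starts))
    stop("no complete epochs fit in the trace", call. = FALSE)
  idx <- outer(0:(window_n - 1), starts, `+`)
  ep <- array(NA_real_, dim = c(window_n, length(starts), 2L))
  ep[, , 1] <- result$lfp[idx, 1]
  ep[, , 2] <- result$lfp[idx, 2]
  structure(list(onset_times = (starts - 1) * dt,
                 window_n = window_n, epochs = ep),
            class = "epoch_matrix")
}

#' Sample moment features of one epoch
#'
#' Biased (1/n) sample moments: variance `m2`, skewness `m3 / m2^(3/2)` and
#' Pearson kurtosis `m4 / m2^2` (a normal sample gives kurtosis near 3; no
#' excess-kurtosis shift is applied). A zero-variance epoch has variance 0
#' and undefined (NA) skewness and kurtosis.
#'
#' @param x Numeric vector of at least 4 samples.
#' @return Named list `variance`, `skewness`, `kurtosis`.
#' @export
moment_features <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0)
    return(list(variance = 0, skewness = NA_real_, kurtosis = NA_real_))
  list(variance = m2,
       skewness = mean(d^3) / m2^1.5,
       kurtosis = mean(d^4) / m2^2)
}

#' Lag-1 autocorrelation of one epoch
#'
#' `r1 = sum((x_t - xbar) (x_{t+1} - xbar)) / sum((x_t - xbar)^2)`, the
#' critical-slowing-down estimator of how slowly the signal forgets a
#' perturbation.
#'
#' @param x Numeric vector of at least 3 samples.
#' @return Value in `[-1, 1]`, or `NA` for a zero-variance epoch.
#' @export
lag1_autocorrelation <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  d <- x - mean(x)
  den <- sum(d^2)
  if (den <= 0) return(NA_real_)
  sum(d[-n] * d[-1]) / den
}

#' Histogram mutual information between two epochs
#'
#' Plug-in estimate of the mutual information between the simultaneous
#' activity of the two populations, used as a synchronization measure. Each
#' epoch is discretized into `n_bins` equal-width bins over its own range,
#' and `MI = sum p(x, y) log2(p(x, y) / (p(x) p(y)))` over the joint
#' histogram. A constant epoch carries no information (MI = 0).
#'
#' @param x,y Equal-length numeric vectors.
#' @param n_bins Number of histogram bins per axis (default 16).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(x, y, n_bins = 16) {
  if (length(x) != length(y))
    stop("epochs must have equal length", call. = FALSE)
  bin <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, length(v)))
    b <- findInterval(v, seq(rng[1], rng[2], length.out = n_bins + 1),
                      rightmost.closed = TRUE)
    pmin(pmax(b, 1L), n_bins)
  }
  bx <- bin(x); by <- bin(y)
  joint <- table(factor(bx, levels = 1:n_bins), factor(by, levels = 1:n_bins))
  pxy <- joint / length(x)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  max(mi, 0)
}

#' Moving-average smoothing of a feature series
#'
#' Order-20 moving average by default. The causal alignment averages the
#' trailing `order` values (a forecasting-appropriate filter); shorter
#' prefixes are averaged over what exists, and missing values are skipped.
#'
#' @param x Numeric vector (may contain NA).
#' @param order Filter order (window length), at least 1.
#' @param align `"causal"` (trailing window, default) or `"centered"`.
#' @return Smoothed vector of the same length.
#' @export
smooth_series <- function(x, order = 20, align = c("causal", "centered")) {
  align <- match.arg(align)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  n <- length(x)
  out <- rep(NA_real_, n)
  half <- floor(order / 2)
  for (k in seq_len(n)) {
    w <- if (align == "causal") x[max(1, k - order + 1):k]
         else x[max(1, k - half):min(n, k - half + order - 1)]
    w <- w[!is.na(w)]
    if (length(w)) out[k] <- mean(w)
  }
  out
}

#' Per-epoch early-warning feature series
#'
#' Computes variance, skewness, kurtosis and lag-1 autocorrelation of every
#' post-stimulus epoch of each population, plus the per-epoch mutual
#' information between the two populations, then smooths each series with a
#' moving-average filter.
#'
#' @param result A [simulate_probing()] result.
#' @param window_s Epoch length in seconds (default 0.400).
#' @param n_bins Mutual-information histogram bins (default 16).
#' @param smooth_order Moving-average order (default 20).
#' @param align Smoothing alignment, see [smooth_series()].
#' @return A data frame of class `"feature_series"` in tidy form with
#'   columns `epoch`, `epoch_time_s`, `param_value` (ramped parameter at the
#'   epoch onset, NA when no ramp), `population` (`"1"`, `"2"`, or `"pair"`
#'   for mutual information), `feature`, `raw_value`, `smoothed_value`.
#' @export
compute_features <- function(result, window_s = 0.400, n_bins = 16,
                             smooth_order = 20,
                             align = c("causal", "centered")) {
  align <- match.arg(align)
  em <- extract_epochs(result, window_s)
  n_ep <- dim(em$epochs)[2]
  ramp <- result$setting$ramp
  pv <- if (is.null(ramp)) rep(NA_real_, n_ep) else {
    if (is.na(ramp$t_end)) ramp$t_end <- result$spec$duration
    ramp_value(em$onset_times, ramp)
  }

  per_pop <- function(pop) {
    ep <- matrix(em$epochs[, , pop], nrow = em$window_n)
    mom <- apply(ep, 2, moment_features)
    data.frame(
      epoch = rep(seq_len(n_ep), 4),
      epoch_time_s = rep(em$onset_times, 4),
      param_value = rep(pv, 4),
      population = as.character(pop),
      feature = rep(c("variance", "skewness", "kurtosis", "lag1_ac"),
                    each = n_ep),
      raw_value = c(vapply(mom, `[[`, numeric(1), "variance"),
                    vapply(mom, `[[`, numeric(1), "skewness"),
                    vapply(mom, `[[`, numeric(1), "kurtosis"),
                    apply(ep, 2, lag1_autocorrelation)),
      stringsAsFactors = FALSE)
  }
  mi <- vapply(seq_len(n_ep), function(k)
    mutual_information(em$epochs[, k, 1], em$epochs[, k, 2], n_bins),
    numeric(1))
  df <- rbind(per_pop(1), per_pop(2),
              data.frame(epoch = seq_len(n_ep), epoch_time_s = em$onset_times,
                         param_value = pv, population = "pair",
                         feature = "mutual_information", raw_value = mi,
                         stringsAsFactors = FALSE))
  df$smoothed_value <- NA_real_
  for (key in unique(paste(df$population, df$feature))) {
    sel <- paste(df$population, df$feature) == key
    df$smoothed_value[sel] <- smooth_series(df$raw_value[sel], smooth_order,
                                            align)
  }
  class(df) <- c("feature_series", "data.frame")
  df
}

#' Write a feature series to tidy CSV
#'
#' @param features A [compute_features()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  data.table::fwrite(as.data.frame(features), path)
  invisible(path)
}
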