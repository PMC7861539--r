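#' Spearman rank correlation between a feature series and the ramp
#'
#' Ranks both series (average ranks for ties) and returns the Pearson
#' correlation of the ranks; pairs with a missing value in either series
#' are dropped first. Rank correlation captures any monotone association,
#' which is what "the feature tracks the ictogenic parameter" means here.
#'
#' @param feature Numeric vector (typically a smoothed per-epoch feature).
#' @param parameter Numeric vector of the ramped parameter at epoch onsets.
#' @return Spearman's rho in `[-1, 1]`, or `NA` if fewer than 3 complete
#'   pairs remain or either series is entirely tied.
#' @export
spearman_rho <- function(feature, parameter) {
  stopifnot(length(feature) == length(parameter))
  ok <- is.finite(feature) & is.finite(parameter)
  x <- feature[ok]; y <- parameter[ok]
  if (length(x) < 3) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  suppressWarnings(cor(x, y, method = "spearman"))
}

# deterministic 31-bit seed from arbitrary labels; keeps noise streams
# distinct across (setting, amplitude, realization) cells
derive_seed <- function(base_seed, ...) {
  s <- paste(base_seed, ..., sep = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Probing-efficiency scores of one simulation
#'
#' @param features A [compute_features()] result from a simulation with a
#'   parameter ramp.
#' @param use `"smoothed"` (default) or `"raw"` feature values.
#' @return Data frame with one row per (population, feature) and its
#'   Spearman rho against the ramped parameter.
#' @export
score_features <- function(features, use = c("smoothed", "raw")) {
  use <- match.arg(use)
  col <- if (use == "smoothed") "smoothed_value" else "raw_value"
  keys <- unique(features[, c("population", "feature")])
  keys$rho <- vapply(seq_len(nrow(keys)), function(k) {
    sel <- features$population == keys$population[k] &
      features$feature == keys$feature[k]
    spearman_rho(features[[col]][sel], features$param_value[sel])
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}

#' Amplitude sweep of probing efficiency
#'
#' For every stimulus amplitude and realization: simulate the setting,
#' extract and smooth the feature series, and correlate each one (Spearman)
#' with the ramped parameter. Realization seeds are derived deterministically
#' from `base_seed`, the setting name, the amplitude and the realization
#' index, so the whole sweep is reproducible and no noise stream is shared
#' across cells. A diverged integration is recorded as a failed cell
#' (NA rho) with a warning and excluded from downstream statistics.
#'
#' @param setting A [build_setting()] result (with a ramp).
#' @param amplitudes Stimulus amplitudes in APs/s; the paper's grid is
#'   `seq(0, 200, by = 20)` and must include 0 (the passive baseline).
#' @param n_realizations Realizations per amplitude (default 15).
#' @param base_seed Integer master seed.
#' @param spec An [integration_spec()].
#' @param window_s,n_bins,smooth_order,align Passed to [compute_features()].
#' @param use Correlate `"smoothed"` (default) or `"raw"` series.
#' @return A data frame of class `"sweep_result"`: columns `setting`,
#'   `feature`, `population`, `amplitude`, `realization`, `seed`, `rho`.
#' @export
run_amplitude_sweep <- function(setting, amplitudes = seq(0, 200, by = 20),
                                n_realizations = 15, base_seed = 1,
                                spec = integration_spec(),
                                window_s = 0.400, n_bins = 16,
                                smooth_order = 20, align = "causal",
                                use = "smoothed") {
  stopifnot(inherits(setting, "model_setting"))
  if (!0 %in% amplitudes)
    stop("amplitudes must include 0 (passive baseline)", call. = FALSE)
  rows <- list()
  for (amp in amplitudes) {
    stim <- stimulus_protocol(amp, targets = setting$targets)
    for (r in seq_len(n_realizations)) {
      seed <- derive_seed(base_seed, setting$name, amp, r)
      sp <- spec; sp$seed <- seed
      sc <- tryCatch({
        res <- simulate_probing(setting, stim, sp)
        fs <- compute_features(res, window_s, n_bins, smooth_order, align)
        score_features(fs, use)
      }, error = function(e) {
        warning(sprintf("amplitude %g realization %d failed: %s",
                        amp, r, conditionMessage(e)), call. = FALSE)
        sc <- unique(expand.grid(population = c("1", "2", "pair"),
                                 feature = "variance",
                                 stringsAsFactors = FALSE))
        sc$rho <- NA_real_
        sc
      })
      sc$setting <- setting$name
      sc$amplitude <- amp
      sc$realization <- r
      sc$seed <- seed
      rows[[length(rows) + 1L]] <- sc
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("setting", "feature", "population", "amplitude",
                 "realization", "seed", "rho")]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Tukey HSD of each amplitude against the passive baseline
#'
#' All-pairs Tukey honestly-significant-difference test (Tukey-Kramer for
#' unequal group sizes) on per-realization values grouped by amplitude,
#' reporting only the comparisons against the amplitude-0 (passive) group.
#'
#' @param values Numeric vector (e.g. per-realization Spearman rho or onset
#'   latencies); NA entries are dropped.
#' @param amplitudes Group labels, same length; must contain 0 and at least
#'   one other level, each with at least 2 values.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `amplitude`, `diff` (group minus
#'   passive), `lwr`, `upr`, `p_adj`, `significant`.
#' @export
tukey_hsd_vs_passive <- function(values, amplitudes, alpha = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]; amplitudes <- amplitudes[ok]
  grp <- factor(amplitudes)
  if (nlevels(grp) < 2)
    stop("need at least two amplitude groups", call. = FALSE)
  if (!"0" %in% levels(grp))
    stop("passive baseline (amplitude 0) missing", call. = FALSE)
  if (any(table(grp) < 2))
    stop("each amplitude group needs at least 2 values", call. = FALSE)
  fit <- aov(values ~ grp, data = data.frame(values = values, grp = grp))
  tk <- TukeyHSD(fit)$grp
  cmp <- rownames(tk)
  # keep contrasts involving the passive group, oriented as group - passive
  parts <- strsplit(cmp, "-", fixed = TRUE)
  keep <- vapply(parts, function(p) "0" %in% p, logical(1))
  tk <- tk[keep, , drop = FALSE]
  parts <- parts[keep]
  other <- vapply(parts, function(p) p[p != "0"][1], character(1))
  sign_flip <- vapply(parts, function(p) p[1] == "0", logical(1))
  out <- data.frame(amplitude = as.numeric(other),
                    diff = ifelse(sign_flip, -tk[, "diff"], tk[, "diff"]),
                    lwr = ifelse(sign_flip, -tk[, "upr"], tk[, "lwr"]),
                    upr = ifelse(sign_flip, -tk[, "lwr"], tk[, "upr"]),
                    p_adj = tk[, "p adj"])
  out$significant <- out$p_adj < alpha
  out <- out[order(out$amplitude), ]
  rownames(out) <- NULL
  out
}

#' Significance of probing efficiency across an amplitude sweep
#'
#' Applies [tukey_hsd_vs_passive()] to the per-realization rho values of
#' each (feature, population) cell of a sweep.
#'
#' @param sweep A [run_amplitude_sweep()] result.
#' @param alpha Significance level (default 0.05).
#' @param transform `"none"` (default) tests the rho values directly;
#'   `"fisher_z"` applies the variance-stabilizing `atanh` first.
#' @return Tidy data frame: `setting`, `feature`, `population`, `amplitude`,
#'   `diff`, `p_adj`, `significant_vs_passive`.
#' @export
sweep_significance <- function(sweep, alpha = 0.05,
                               transform = c("none", "fisher_z")) {
  transform <- match.arg(transform)
  vals <- sweep$rho
  if (transform == "fisher_z")
    vals <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
  keys <- unique(sweep[, c("setting", "feature", "population")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- sweep$setting == keys$setting[k] &
      sweep$feature == keys$feature[k] &
      sweep$population == keys$population[k]
    tk <- tryCatch(
      tukey_hsd_vs_passive(vals[sel], sweep$amplitude[sel], alpha),
      error = function(e) NULL)
    if (is.null(tk)) next
    tk$setting <- keys$setting[k]
    tk$feature <- keys$feature[k]
    tk$population <- keys$population[k]
    out[[length(out) + 1L]] <- tk
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- res[, c("setting", "feature", "population", "amplitude",
                 "diff", "p_adj", "significant")]
  names(res)[names(res) == "significant"] <- "significant_vs_passive"
  rownames(res) <- NULL
  res
}
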