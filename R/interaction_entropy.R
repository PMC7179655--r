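# Interaction-entropy estimator of -T*dS from interaction-energy
# fluctuations, the 3-SD outlier filter, window planning on stability
# series, and window aggregation.

#' Single-pass outlier filter on an energy series
#'
#' Keeps values within `k_sd` standard deviations of the mean, where
#' mean and SD are those of the full input (single pass, not iterated).
#' Order is preserved.
#'
#' @param series numeric vector (kcal/mol), length >= 2.
#' @param k_sd cutoff in SD units (default 3).
#' @return filtered numeric vector.
#' @export
filter_outliers <- function(series, k_sd = 3.0) {
  if (length(series) == 0L) stop("empty input series")
  if (length(series) < 2L) stop("series must have length >= 2")
  m <- mean(series)
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) return(series)
  series[abs(series - m) <= k_sd * s]
}

#' Interaction entropy of an energy series
#'
#' `-T*dS = kT * ln( (1/N) sum_i exp(beta * (E_i - <E>)) )` with
#' `beta = 1/kT`, `k = 1.9872041e-3` kcal/(mol K). Computed through a
#' log-sum-exp guard so large fluctuations cannot overflow. The result
#' is non-negative by Jensen's inequality, zero only for a constant
#' series.
#'
#' @param series numeric vector of interaction energies (kcal/mol).
#' @param temperature temperature in K (default 300).
#' @param filter_sd if non-NULL, apply [filter_outliers()] with this
#'   cutoff first and record how many frames were dropped.
#' @return `IEResult`: list with `mean_e_int`, `minus_t_ds`,
#'   `n_frames_used`, `n_frames_filtered`, `temperature`.
#' @export
interaction_entropy <- function(series, temperature = 300,
                                filter_sd = NULL) {
  if (length(series) == 0L) stop("empty input series")
  if (any(!is.finite(series))) stop("non-finite values in energy series")
  if (temperature <= 0) stop("temperature must be positive")
  n_in <- length(series)
  if (!is.null(filter_sd)) series <- filter_outliers(series, filter_sd)
  kt <- KBOLTZ * temperature
  d <- (series - mean(series)) / kt
  m <- max(d)
  lse <- m + log(mean(exp(d - m)))
  mtds <- kt * lse
  if (mtds < 0) mtds <- max(mtds, 0) # guard vanishing negative round-off
  structure(list(mean_e_int = mean(series), minus_t_ds = mtds,
                 n_frames_used = length(series),
                 n_frames_filtered = n_in - length(series),
                 temperature = temperature),
            class = "IEResult")
}

#' @export
print.IEResult <- function(x, ...) {
  cat(sprintf(
    "IEResult: <E_int>=%.3f kcal/mol, -TdS=%.3f kcal/mol (%d frames, %d filtered, T=%g K)\n",
    x$mean_e_int, x$minus_t_ds, x$n_frames_used, x$n_frames_filtered,
    x$temperature))
  invisible(x)
}

#' Window plan defaults
#'
#' The production protocol: five non-overlapping 5-ns windows per
#' replicate, three replicates (15 windows total), 100 equally spaced
#' enthalpy frames per window, entropy from all frames in the window.
#'
#' @param window_ps window length in ps.
#' @param n_windows windows per replicate.
#' @param n_replicates number of replicates.
#' @param enthalpy_frames equally spaced frames per window used for the
#'   enthalpy terms.
#' @return list of class `WindowPlan`.
#' @export
window_plan <- function(window_ps = 5000, n_windows = 5, n_replicates = 3,
                        enthalpy_frames = 100) {
  structure(list(window_ps = window_ps, n_windows = n_windows,
                 n_replicates = n_replicates,
                 enthalpy_frames = enthalpy_frames),
            class = "WindowPlan")
}

#' Select stable analysis windows from a stability series
#'
#' Greedily picks `n_windows` non-overlapping windows of
#' `window_ps / frame_interval` frames minimizing the within-window
#' standard deviation of the stability series (ligand heavy-atom RMSD
#' in the production pipeline); earliest start wins ties.
#'
#' @param stability per-frame stability metric (e.g. ligand RMSD, A).
#' @param frame_interval frame spacing in ps.
#' @param window_ps window length in ps (default 5000).
#' @param n_windows number of windows (default 5).
#' @param starts optional explicit window start frames (overrides the
#'   stability search).
#' @return data.frame with columns `start`, `end` (frame indices,
#'   inclusive), ordered by start.
#' @export
plan_windows <- function(stability, frame_interval, window_ps = 5000,
                         n_windows = 5, starts = NULL) {
  fw <- round(window_ps / frame_interval)
  n <- length(stability)
  if (n < n_windows * fw) {
    stop(sprintf("replicate too short: %d frames < %d windows x %d frames",
                 n, n_windows, fw))
  }
  if (!is.null(starts)) {
    w <- data.frame(start = as.integer(starts),
                    end = as.integer(starts) + fw - 1L)
    if (any(w$end > n)) stop("explicit window exceeds trajectory")
    return(w[order(w$start), , drop = FALSE])
  }
  # sliding-window SD via cumulative sums
  s1 <- cumsum(stability)
  s2 <- cumsum(stability^2)
  win_sum <- s1[fw:n] - c(0, s1)[1:(n - fw + 1)]
  win_sq <- s2[fw:n] - c(0, s2)[1:(n - fw + 1)]
  v <- (win_sq - win_sum^2 / fw) / (fw - 1)
  sd_all <- sqrt(pmax(v, 0))
  avail <- rep(TRUE, length(sd_all))
  chosen <- integer(0)
  for (k in seq_len(n_windows)) {
    if (!any(avail)) stop("greedy window placement failed; supply `starts`")
    cand <- which(avail)
    st <- cand[which.min(sd_all[cand])]
    chosen <- c(chosen, st)
    block <- max(1L, st - fw + 1L):min(length(avail), st + fw - 1L)
    avail[block] <- FALSE
  }
  chosen <- sort(chosen)
  data.frame(start = chosen, end = chosen + fw - 1L)
}

#' Equally spaced enthalpy frame indices within a window
#'
#' @param start,end inclusive frame bounds.
#' @param n number of frames requested (default 100).
#' @return integer vector of unique frame indices.
#' @export
enthalpy_frame_indices <- function(start, end, n = 100) {
  unique(round(seq(start, end, length.out = min(n, end - start + 1L))))
}

#' Mean and sample SD across analysis windows
#'
#' @param values per-window values (kcal/mol), length >= 2.
#' @return list with `mean` and `sd` (n-1 denominator).
#' @export
aggregate_windows <- function(values) {
  if (length(values) < 2L) stop("need >= 2 windows for an SD")
  list(mean = mean(values), sd = stats::sd(values))
}
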