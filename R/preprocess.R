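#' Zero-phase band-pass filtering
#'
#' 5th-order Butterworth high-pass and low-pass filters applied
#' forward-backward (zero phase) along the time axis.  Either cutoff may be
#' NULL to skip that stage.
#'
#' @param data numeric vector, or sensors x time matrix.
#' @param srate sampling rate, Hz.
#' @param high_pass_hz high-pass cutoff, Hz (default 1).
#' @param low_pass_hz low-pass cutoff, Hz (default 30).
#' @param order filter order.
#' @return filtered data, same shape.
#' @export
bandpass <- function(data, srate = 480, high_pass_hz = 1, low_pass_hz = 30,
                     order = 5) {
  if (!is.null(low_pass_hz)) stopifnot(srate > 2 * low_pass_hz)
  vec <- is.null(dim(data))
  x <- if (vec) matrix(data, 1) else data
  if (ncol(x) < 3 * (order + 1))
    stop("time window too short (", ncol(x), " samples) for filter order ",
         order)
  apply_filt <- function(x, filt) {
    t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
  }
  if (!is.null(high_pass_hz) && high_pass_hz > 0)
    x <- apply_filt(x, signal::butter(order, high_pass_hz / (srate / 2),
                                      type = "high"))
  if (!is.null(low_pass_hz))
    x <- apply_filt(x, signal::butter(order, low_pass_hz / (srate / 2),
                                      type = "low"))
  if (vec) as.numeric(x) else x
}

#' Epoch continuous data and baseline-correct
#'
#' Cuts fixed windows around event samples and subtracts, per trial and
#' sensor, the mean over the prestimulus samples (t < 0); the prestimulus
#' mean of every output epoch is exactly zero.  Events too close to the
#' record edge are dropped and logged.
#'
#' @param continuous sensors x time matrix.
#' @param event_samples integer sample indices of stimulus onsets (1-based).
#' @param srate sampling rate, Hz.
#' @param window_ms epoch window around each event, ms.
#' @param conditions optional label per event.
#' @return An `epoch_set`; dropped events are reported in `provenance`.
#' @export
epoch_and_baseline <- function(continuous, event_samples, srate = 480,
                               window_ms = c(-100, 1000),
                               conditions = NULL) {
  stopifnot(window_ms[1] <= 0, window_ms[2] >= 0)
  i0 <- round(window_ms[1] / 1000 * srate)
  i1 <- round(window_ms[2] / 1000 * srate)
  times_ms <- (i0:i1) / srate * 1000
  if (is.null(conditions)) conditions <- rep("stim", length(event_samples))
  keep <- event_samples + i0 >= 1 & event_samples + i1 <= ncol(continuous)
  dropped <- event_samples[!keep]
  prov <- if (length(dropped))
    sprintf("dropped %d event(s) at record edge: %s", length(dropped),
            paste(dropped, collapse = ", ")) else character(0)
  ev <- event_samples[keep]
  arr <- array(0, c(length(ev), nrow(continuous), length(times_ms)))
  pre <- which(times_ms < 0)
  for (tr in seq_along(ev)) {
    seg <- continuous[, (ev[tr] + i0):(ev[tr] + i1), drop = FALSE]
    seg <- seg - rowMeans(seg[, pre, drop = FALSE])
    arr[tr, , ] <- seg
  }
  new_epoch_set(arr, times_ms, conditions[keep], dt = 1 / srate,
                provenance = prov)
}

#' Robust trial averaging
#'
#' Iteratively reweighted averaging that down-weights outlying samples:
#' bisquare weights computed per time sample across trials (independently
#' per sensor), tuning constant 4.685 x MAD, at most `max_iter` iterations.
#' With clean Gaussian data the result is close to the arithmetic mean;
#' identical trials give that waveform with all weights 1.  Optionally the
#' 30 Hz low-pass is repeated afterwards to remove high-frequency noise
#' introduced by the weighting.
#'
#' @param epochs an `epoch_set`.
#' @param condition condition label to average (NULL = all trials).
#' @param tuning bisquare tuning constant (multiplies the MAD).
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the maximum weight change.
#' @param lowpass_hz cutoff for the repeated low-pass after averaging, or
#'   NULL to skip.
#' @return An `evoked` with `weights` (trials x time, averaged over
#'   sensors).
#' @export
robust_average <- function(epochs, condition = NULL, tuning = 4.685,
                           max_iter = 8, tol = 1e-6, lowpass_hz = NULL) {
  sel <- if (is.null(condition)) rep(TRUE, dim(epochs$data)[1])
         else epochs$conditions == condition
  if (sum(sel) < 2) stop("need >= 2 trials to average (got ", sum(sel), ")")
  x <- epochs$data[sel, , , drop = FALSE]
  nt <- dim(x)[1]; ns <- dim(x)[2]; np <- dim(x)[3]
  avg <- matrix(0, ns, np)
  wsum <- matrix(0, nt, np)  # weights averaged over sensors
  converged <- TRUE
  for (s in seq_len(ns)) {
    m <- x[, s, , drop = TRUE]
    if (nt == 1) m <- matrix(m, 1)
    w <- matrix(1, nt, np)
    for (it in seq_len(max_iter)) {
      mu <- colSums(w * m) / colSums(w)
      res <- sweep(m, 2, mu)
      s_mad <- apply(res, 2, stats::mad)
      cw <- tuning * s_mad
      u <- sweep(res, 2, ifelse(cw > 0, cw, Inf), "/")
      w_new <- pmax(1 - u^2, 0)^2
      w_new[, cw == 0] <- 1
      delta <- max(abs(w_new - w))
      w <- w_new
      if (delta < tol) break
    }
    if (delta >= tol && max_iter > 1) converged <- FALSE
    avg[s, ] <- colSums(w * m) / colSums(w)
    wsum <- wsum + w
  }
  if (!converged)
    warning("robust averaging did not fully converge in ", max_iter,
            " iterations; returning last iterate")
  if (!is.null(lowpass_hz))
    avg <- bandpass(avg, srate = 1 / epochs$dt, high_pass_hz = NULL,
                    low_pass_hz = lowpass_hz)
  new_evoked(avg, epochs$times_ms,
             condition = if (is.null(condition)) "all" else condition,
             weights = wsum / ns)
}

#' Global field power
#'
#' The sensor amplitudes squared and summed over all sensors at each time
#' point (sum-of-squares convention, not RMS).
#'
#' @param evoked an `evoked`.
#' @return A `gfp_series`.
#' @export
global_field_power <- function(evoked) {
  stopifnot(nrow(evoked$data) >= 1)
  new_gfp(colSums(evoked$data^2), evoked$times_ms, evoked$condition)
}

#' Peak latency within a search window
#'
#' Latency of the maximum of a GFP series inside the window (default
#' 140-220 ms, bracketing the M170); ties break to the earliest sample.
#'
#' @param gfp a `gfp_series`.
#' @param search_window_ms two-element window, ms.
#' @return peak latency, ms.
#' @export
find_peak <- function(gfp, search_window_ms = c(140, 220)) {
  sel <- which(gfp$times_ms >= search_window_ms[1] &
               gfp$times_ms <= search_window_ms[2])
  if (!length(sel)) stop("search window contains no samples")
  gfp$times_ms[sel[which.max(gfp$values[sel])]]
}

#' Pointwise t-test between two sets of GFP time courses
#'
#' Per-sample t statistic and (two-tailed) p-value comparing two groups of
#' subject-level time courses, paired or independent; contiguous samples
#' with p < alpha are merged into significance windows.  Uncorrected for
#' multiple comparisons by default, matching exploratory sensor-level use.
#'
#' @param gfp_a,gfp_b subjects x time matrices (paired mode requires equal
#'   subject counts and ordering).
#' @param times_ms optional time axis for window reporting.
#' @param paired within-subjects comparison?
#' @param alpha per-sample significance level.
#' @return list with `t`, `p`, `df` and `windows` (data frame of contiguous
#'   significant runs; with `times_ms` also their start/end in ms).
#' @export
pointwise_ttest <- function(gfp_a, gfp_b, times_ms = NULL, paired = FALSE,
                            alpha = 0.05) {
  stopifnot(nrow(gfp_a) >= 2, nrow(gfp_b) >= 2,
            ncol(gfp_a) == ncol(gfp_b))
  if (paired && nrow(gfp_a) != nrow(gfp_b))
    stop("paired mode needs the same subjects in both groups")
  if (paired) {
    d <- gfp_a - gfp_b
    n <- nrow(d)
    tt <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
    df <- n - 1
  } else {
    na <- nrow(gfp_a); nb <- nrow(gfp_b)
    va <- apply(gfp_a, 2, stats::var); vb <- apply(gfp_b, 2, stats::var)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tt <- (colMeans(gfp_a) - colMeans(gfp_b)) /
      sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  tt[!is.finite(tt)] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  sig <- p < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  wdf <- data.frame(start = starts[runs$values],
                    end = ends[runs$values])
  if (!is.null(times_ms) && nrow(wdf)) {
    wdf$start_ms <- times_ms[wdf$start]
    wdf$end_ms <- times_ms[wdf$end]
  }
  list(t = tt, p = p, df = df, windows = wdf)
}
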