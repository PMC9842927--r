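# Band-limiting and spectral estimation for region x time signals.

#' Zero-phase band-pass filter
#'
#' Removes a per-region linear trend, then zeroes every Fourier component with
#' frequency outside [f_lo, f_hi] (boundary inclusive) and inverts the
#' transform. Acting directly on the DFT makes the filter exactly zero-phase
#' and idempotent; the DC component always lies below f_lo and is removed, so
#' the output is mean-free per region.
#'
#' @param ts A \code{\link{bold_timeseries}}.
#' @param f_lo,f_hi Pass-band edges in Hz; require
#'   0 < f_lo < f_hi < 1/(2 tr). Defaults 0.008 and 0.08 (the slow BOLD band).
#' @return A band-limited \code{bold_timeseries} with the same shape.
#' @export
bandpass_filter <- function(ts, f_lo = 0.008, f_hi = 0.08) {
  stopifnot(inherits(ts, "bold_timeseries"))
  nyq <- 1 / (2 * ts$tr)
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < nyq))
    stop(sprintf("band [%g, %g] Hz infeasible for tr = %g s (Nyquist %g Hz)",
                 f_lo, f_hi, ts$tr, nyq))
  n <- n_volumes(ts)
  if (n * ts$tr < 6 / f_lo)
    stop(sprintf("series too short: need >= %g s (6x the longest in-band period), have %g s",
                 6 / f_lo, n * ts$tr))
  freqs <- seq(0, n - 1) / (n * ts$tr)
  freqs <- pmin(freqs, 1 / ts$tr - freqs)        # fold to [0, Nyquist]
  keep <- freqs >= f_lo & freqs <= f_hi
  filt <- t(apply(ts$data, 1, function(x) {
    x <- detrend_linear(x)
    X <- fft(x)
    X[!keep] <- 0
    Re(fft(X, inverse = TRUE)) / n
  }))
  bold_timeseries(filt, tr = ts$tr, region_ids = ts$region_ids,
                  subject_id = ts$subject_id, session_id = ts$session_id)
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  unname(stats::lm.fit(cbind(1, t), x)$residuals)
}

#' Welch averaged-periodogram power spectral density
#'
#' Splits the signal into Hann-windowed segments with 50% overlap (segment
#' length about a quarter of the series by default), averages the
#' periodograms, and returns the one-sided spectrum.
#'
#' @param x Numeric vector.
#' @param fs Sampling frequency in Hz.
#' @param nperseg Segment length; default \code{floor(length(x) / 4)}.
#' @return List with \code{freq} (Hz) and \code{power}.
#' @export
welch_psd <- function(x, fs, nperseg = max(8L, floor(length(x) / 4))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hann
  scale <- sum(win^2) * fs
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(fft(seg))^2 / scale
  }
  acc <- acc / length(starts)
  half <- seq_len(floor(nperseg / 2) + 1L)
  list(freq = (half - 1) * fs / nperseg, power = acc[half])
}

#' Per-region intrinsic frequencies from a cohort of narrowband signals
#'
#' For each region and each run, the frequency of the maximum of the Welch
#' spectral estimate within the band is located; per-region values are then
#' averaged across all runs in the cohort and clamped to the band. These are
#' the node frequencies f_i used by the Hopf model.
#'
#' @param cohort_ts List of \code{\link{bold_timeseries}} sharing region
#'   ordering and tr (a single object is promoted to a list).
#' @param band Numeric length-2 vector (f_lo, f_hi) in Hz.
#' @return Named numeric vector of per-region peak frequencies (Hz).
#' @export
estimate_intrinsic_frequencies <- function(cohort_ts, band = c(0.008, 0.08)) {
  if (inherits(cohort_ts, "bold_timeseries")) cohort_ts <- list(cohort_ts)
  if (length(cohort_ts) == 0L) stop("empty cohort")
  ids <- cohort_ts[[1]]$region_ids
  tr <- cohort_ts[[1]]$tr
  for (ts in cohort_ts)
    if (!identical(ts$region_ids, ids) || ts$tr != tr)
      stop("all series must share region ordering and tr")
  fs <- 1 / tr
  peaks <- sapply(cohort_ts, function(ts) {
    apply(ts$data, 1, function(x) {
      if (sd(x) == 0)
        stop("degenerate (constant) region: cannot locate a spectral peak")
      psd <- welch_psd(x, fs)
      inband <- psd$freq >= band[1] & psd$freq <= band[2]
      if (!any(inband)) stop("no spectral bins inside the band")
      psd$freq[inband][which.max(psd$power[inband])]
    })
  })
  peaks <- if (is.matrix(peaks)) rowMeans(peaks) else mean(peaks)
  out <- pmin(pmax(peaks, band[1]), band[2])
  names(out) <- ids
  out
}
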