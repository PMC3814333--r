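#' Inter-spike intervals of a spike train
#'
#' @param spikes A [spike_train()] or numeric vector of event times.
#' @return Numeric vector of intervals (s).
#' @export
isi <- function(spikes) {
  tt <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  diff(tt)
}

#' Coefficient of variation of inter-spike intervals
#'
#' Standard deviation over mean of the intervals. Invariant to uniform
#' time rescaling.
#'
#' @param isis Numeric vector of intervals (at least two).
#' @return Dimensionless CV.
#' @export
cv_isi <- function(isis) {
  if (length(isis) < 2) stop("at least two intervals are required")
  stats::sd(isis) / mean(isis)
}

#' Irregularity (IR) metric of inter-spike intervals
#'
#' The mean absolute log-ratio of consecutive intervals,
#' `mean(|log(ISI[i+1] / ISI[i])|)`. Because it measures relative changes
#' between neighbouring intervals it is exactly invariant to uniform time
#' rescaling and far less sensitive to slow rate drift than the CV.
#'
#' @param isis Numeric vector of intervals (at least two, all positive).
#' @return Dimensionless IR.
#' @export
ir_isi <- function(isis) {
  if (length(isis) < 2) stop("at least two intervals are required")
  if (any(isis <= 0)) stop("intervals must be positive")
  mean(abs(diff(log(isis))))
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# Windowed, mean-detrended segment FFTs shared by the Welch estimators.
welch_segments <- function(x, fs, window_s, overlap) {
  ns <- round(window_s * fs)
  if (length(x) < ns) stop("trace shorter than one window")
  step <- ns - floor(ns * overlap)
  starts <- seq(1, length(x) - ns + 1, by = step)
  win <- hamming_window(ns)
  nf <- floor(ns / 2) + 1
  X <- vapply(starts, function(s) {
    seg <- x[s:(s + ns - 1)]
    stats::fft((seg - mean(seg)) * win)[1:nf]
  }, complex(nf))
  list(X = X, n_windows = length(starts), ns = ns, win = win,
       freq = (0:(nf - 1)) * fs / ns)
}

#' Welch power spectral density
#'
#' Periodogram averaging with a Hamming window and per-window mean
#' removal; one-sided density.
#'
#' @param x A [signal_trace()], or numeric vector with `fs`.
#' @param fs Sampling rate (Hz) when `x` is a plain vector.
#' @param window_s Window length (s).
#' @param overlap Fractional overlap.
#' @return Data frame with `freq` (Hz) and `power` (per Hz), with the
#'   window count in attribute `n_windows`.
#' @export
welch_psd <- function(x, fs = NULL, window_s = 0.5, overlap = 0.5) {
  if (inherits(x, "signal_trace")) { fs <- x$fs; x <- x$values }
  sg <- welch_segments(x, fs, window_s, overlap)
  scale <- fs * sum(sg$win^2)
  p <- rowMeans(Mod(sg$X)^2) / scale
  one <- rep(2, length(sg$freq)); one[1] <- 1
  if (sg$ns %% 2 == 0) one[length(one)] <- 1
  out <- data.frame(freq = sg$freq, power = p * one)
  attr(out, "n_windows") <- sg$n_windows
  out
}

#' Confidence level for a magnitude-squared coherence spectrum
#'
#' The level below which the coherence of independent signals falls with
#' probability `1 - alpha` in each bin: `1 - alpha^(1/(N-1))` for `N`
#' averaged windows.
#'
#' @param n_windows Number of averaged data windows.
#' @param alpha Significance level.
#' @return The coherence confidence level.
#' @export
coherence_confidence <- function(n_windows, alpha = 0.05) {
  1 - alpha^(1 / (n_windows - 1))
}

#' Welch magnitude-squared coherence
#'
#' `|S_xy|^2 / (S_xx S_yy)` with Welch cross- and auto-spectra (Hamming
#' window, per-window mean removal). Symmetric in its arguments and
#' bounded in `[0, 1]`.
#'
#' @param x,y [signal_trace()]s with equal sampling rates and lengths,
#'   or numeric vectors with `fs`.
#' @param fs Sampling rate (Hz) for plain vectors.
#' @param window_s Window length (s).
#' @param overlap Fractional overlap.
#' @return An object of class `coherence_spectrum`: data frame with
#'   `freq` and `coherence`, with attributes `n_windows`, `conf_level`,
#'   `window_s`, `overlap`.
#' @export
welch_coherence <- function(x, y, fs = NULL, window_s = 0.5, overlap = 0.5) {
  if (inherits(x, "signal_trace")) {
    if (!inherits(y, "signal_trace")) stop("both traces must carry sampling rates")
    if (x$fs != y$fs) stop("mismatched sampling rates")
    fs <- x$fs; x <- x$values; y <- y$values
  }
  if (length(x) != length(y)) stop("traces must have equal length")
  sx <- welch_segments(x, fs, window_s, overlap)
  sy <- welch_segments(y, fs, window_s, overlap)
  Sxy <- rowMeans(sx$X * Conj(sy$X))
  Sxx <- rowMeans(Mod(sx$X)^2)
  Syy <- rowMeans(Mod(sy$X)^2)
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  coh[Sxx == 0 | Syy == 0] <- 0
  out <- data.frame(freq = sx$freq, coherence = coh)
  attr(out, "n_windows") <- sx$n_windows
  attr(out, "conf_level") <- coherence_confidence(sx$n_windows)
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  class(out) <- c("coherence_spectrum", "data.frame")
  out
}

#' Average coherence spectra across repeat simulations
#'
#' @param spectra List of `coherence_spectrum` objects on a common
#'   frequency grid.
#' @return A `coherence_spectrum` with the bin-wise mean coherence; the
#'   attribute `n_trials` records the number of averaged spectra.
#' @export
average_coherence <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  out <- spectra[[1]]
  out$coherence <- rowMeans(vapply(spectra, function(s) s$coherence,
                                   numeric(nrow(out))))
  attr(out, "n_trials") <- length(spectra)
  out
}

#' Peak coherence within a frequency band
#'
#' @param spectrum A `coherence_spectrum`.
#' @param band Frequency band (Hz), default beta.
#' @return List with `freq` and `coherence` of the in-band peak.
#' @export
peak_coherence <- function(spectrum, band = c(12, 30)) {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  i <- which.max(spectrum$coherence[sel])
  list(freq = spectrum$freq[sel][i], coherence = spectrum$coherence[sel][i])
}

#' Irregularity and CV versus firing rate
#'
#' Bins spike trains by mean firing rate and summarises the distribution
#' of the CV and IR interval statistics within each bin.
#'
#' @param spike_trains List of [spike_train()]s (or time vectors).
#' @param duration Observation window used for the rates (s).
#' @param breaks Rate bin edges (Hz).
#' @return Data frame with one row per non-empty bin: `rate_hz` (bin
#'   centre), `n`, and median/quartiles of `cv` and `ir`.
#' @export
irregularity_vs_rate <- function(spike_trains, duration,
                                 breaks = seq(0, 45, by = 2.5)) {
  per <- lapply(spike_trains, function(s) {
    tt <- if (inherits(s, "spike_train")) s$times else s
    if (length(tt) < 3) return(NULL)
    iv <- diff(tt)
    data.frame(rate = length(tt) / duration, cv = cv_isi(iv), ir = ir_isi(iv))
  })
  df <- do.call(rbind, per)
  if (is.null(df)) stop("no trains with at least three spikes")
  bin <- cut(df$rate, breaks, include.lowest = TRUE)
  rows <- lapply(split(df, bin), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(rate_hz = mean(d$rate), n = nrow(d),
               cv_median = stats::median(d$cv),
               cv_q1 = unname(stats::quantile(d$cv, 0.25)),
               cv_q3 = unname(stats::quantile(d$cv, 0.75)),
               ir_median = stats::median(d$ir),
               ir_q1 = unname(stats::quantile(d$ir, 0.25)),
               ir_q3 = unname(stats::quantile(d$ir, 0.75)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
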