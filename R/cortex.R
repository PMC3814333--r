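#' Create a sheet of coupled phase oscillators
#'
#' Builds an `oscillator_sheet`: an N x N lattice of phase oscillators with
#' periodic boundary conditions. Each oscillator carries a fixed intrinsic
#' frequency drawn from a normal distribution; the broad frequency
#' distribution is what injects realistic variability into the emergent
#' wave patterns, without any explicit noise terms.
#'
#' @param n Grid size (nodes per side).
#' @param freq_mean_hz,freq_sd_hz Mean and standard deviation (Hz) of the
#'   intrinsic oscillator frequencies. `freq_sd_hz = 0` gives a homogeneous
#'   sheet.
#' @param seed Optional integer seed for the random phases and frequencies.
#' @param phases,freqs Optional explicit N x N matrices overriding the
#'   random draws (phases in radians, frequencies in Hz).
#' @return An object of class `oscillator_sheet` with elements `phases`
#'   (radians, wrapped to `[0, 2*pi)`), `freqs` (Hz), `n` and `time` (s).
#' @export
oscillator_sheet <- function(n = 128, freq_mean_hz = 20, freq_sd_hz = 4,
                             seed = NULL, phases = NULL, freqs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phases)) phases <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  if (is.null(freqs)) freqs <- matrix(stats::rnorm(n * n, freq_mean_hz, freq_sd_hz), n, n)
  stopifnot(all(dim(phases) == c(n, n)), all(dim(freqs) == c(n, n)))
  structure(list(phases = wrap_phase(phases), freqs = freqs, n = n, time = 0),
            class = "oscillator_sheet")
}

wrap_phase <- function(x) x - 2 * pi * floor(x / (2 * pi))

#' @export
print.oscillator_sheet <- function(x, ...) {
  cat(sprintf("<oscillator_sheet> %d x %d nodes, t = %.3f s, freq %.1f +/- %.1f Hz\n",
              x$n, x$n, x$time, mean(x$freqs), stats::sd(x$freqs)))
  invisible(x)
}

#' Anisotropic inhibitory-surround coupling kernel
#'
#' Builds the spatial coupling kernel of the cortical sheet. The radial
#' profile is the fourth radial derivative of a Gaussian, which has a
#' positive (excitatory) centre surrounded by a negative (inhibitory)
#' annulus. The strength of the inhibitory surround varies with angle,
#' interpolating smoothly (pi-periodic) between `s_major` on the major axis
#' (at angle `phi_k`) and `s_minor` on the minor axis. Anisotropy of the
#' surround orients the emergent traveling waves along the major axis.
#'
#' The positive lobe is L1-normalised before the global `gain` is applied,
#' so `gain` is the summed excitatory coupling weight (rad/s at full phase
#' opposition).
#'
#' @param extent Kernel support in nodes (odd integer).
#' @param sigma Gaussian scale in nodes. The default corresponds to a
#'   full-width-half-height of 11 nodes.
#' @param s_major,s_minor Inhibitory surround strengths along the major and
#'   minor axes (dimensionless, `>= 0`). Equal values give an isotropic
#'   kernel.
#' @param phi_k Orientation of the major axis, radians from horizontal.
#' @param gain Global coupling gain.
#' @return An object of class `coupling_kernel` with the signed `weights`
#'   matrix (`extent` x `extent`) and the parameters.
#' @export
coupling_kernel <- function(extent = 37, sigma = 11 / (2 * sqrt(2 * log(2))),
                            s_major = 1, s_minor = 0.4, phi_k = 0, gain = 60) {
  if (sigma <= 0) stop("sigma must be positive")
  if (extent %% 2 != 1) stop("kernel extent must be odd")
  if (s_major < 0 || s_minor < 0) stop("surround strengths must be non-negative")
  half <- (extent - 1) / 2
  xs <- -half:half
  X <- matrix(xs, extent, extent)
  Y <- t(X)
  r2 <- (X^2 + Y^2) / sigma^2
  # 4th radial derivative of exp(-r^2 / (2 sigma^2)), scaled by sigma^4
  h <- exp(-r2 / 2) * (3 - 6 * r2 + r2^2)
  phi <- atan2(Y, X)
  s <- s_minor + (s_major - s_minor) * cos(phi - phi_k)^2
  w <- pmax(h, 0) - s * pmax(-h, 0)
  w <- w / sum(pmax(h, 0)) * gain
  structure(list(weights = w, extent = extent, sigma = sigma,
                 s_major = s_major, s_minor = s_minor, phi_k = phi_k,
                 gain = gain),
            class = "coupling_kernel")
}

#' @export
print.coupling_kernel <- function(x, ...) {
  cat(sprintf(
    "<coupling_kernel> %dx%d, sigma %.2f nodes, s = (%.2f, %.2f), phi_k %.1f deg, gain %.1f\n",
    x$extent, x$extent, x$sigma, x$s_major, x$s_minor, x$phi_k * 180 / pi, x$gain))
  invisible(x)
}

# Lay a small centred kernel matrix onto the full n x n periodic grid with
# its centre at element (1, 1), the layout assumed by FFT convolution.
wrap_kernel <- function(weights, n) {
  extent <- nrow(weights)
  if (extent > n) stop("kernel extent exceeds grid size")
  half <- (extent - 1) / 2
  full <- matrix(0, n, n)
  idx <- function(k) ((k - half - 1) %% n) + 1  # kernel index -> grid index
  full[idx(1:extent), idx(1:extent)] <- weights
  full
}

# Periodic convolution of a real field with a kernel given on the full grid
# (centre at [1,1]) via FFT.
conv_periodic <- function(field, kernel_full) {
  Re(stats::fft(stats::fft(kernel_full) * stats::fft(field), inverse = TRUE)) /
    length(field)
}

#' Advance the oscillator sheet by one Euler step
#'
#' Each phase advances by `dt * (2*pi*omega + sum_j K(x_j - x_i)
#' sin(theta_j - theta_i))`, with the pairwise sum realised as a periodic
#' spatial convolution. Deterministic given the sheet and kernel.
#'
#' @param sheet An [oscillator_sheet()].
#' @param kernel A [coupling_kernel()]; its extent must not exceed the grid.
#' @param dt Time step in seconds (at most 1 ms).
#' @return The advanced `oscillator_sheet`.
#' @export
step_sheet <- function(sheet, kernel, dt = 5e-4) {
  stopifnot(inherits(sheet, "oscillator_sheet"), inherits(kernel, "coupling_kernel"))
  if (dt > 1e-3) stop("dt must be <= 1 ms")
  if (kernel$extent > sheet$n) stop("kernel extent exceeds grid size")
  kf <- wrap_kernel(kernel$weights, sheet$n)
  th <- sheet$phases
  # sum_j K sin(theta_j - theta_i) = cos(theta_i) (K*sin) - sin(theta_i) (K*cos)
  cs <- conv_periodic(cos(th), kf)
  sn <- conv_periodic(sin(th), kf)
  coupling <- cos(th) * sn - sin(th) * cs
  sheet$phases <- wrap_phase(th + dt * (2 * pi * sheet$freqs + coupling))
  sheet$time <- sheet$time + dt
  sheet
}

#' Simulate the cortical sheet
#'
#' Integrates the spatially coupled phase-oscillator sheet with an explicit
#' Euler scheme and records, at sampling interval `1/fs`, the simulated LFP
#' (spatial mean of `cos(theta)`), optionally the full phase grids, and
#' optionally the phase-only dendritic currents of a set of Gabor kernels
#' evaluated at given grid positions (the fast path used by the descending
#' motor experiments).
#'
#' @param n Grid size (nodes per side).
#' @param duration Simulated time in seconds.
#' @param kernel A [coupling_kernel()].
#' @param freq_mean_hz,freq_sd_hz Intrinsic frequency distribution (Hz).
#' @param dt Integration step (s).
#' @param fs Sampling rate of the recorded traces (Hz); must divide `1/dt`.
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param record_phases Record the full phase grid at every sample (memory
#'   grows as `n^2 * duration * fs`; intended for small grids).
#' @param filters Optional list of [phase_gabor_kernel()] objects to apply
#'   to the cosine-phase field at every sample.
#' @param positions Optional integer matrix (rows, cols; 1-based) of grid
#'   positions at which each filter output is recorded. Required when
#'   `filters` is given.
#' @param sheet Optional pre-built [oscillator_sheet()] (overrides `n`,
#'   `freq_*` and `seed` for the initial state).
#' @return An object of class `phase_history`: list with `lfp` (a
#'   [signal_trace()], mean-normalised), `phases` (n x n x samples array or
#'   `NULL`), `currents` (list of matrices, positions x samples, in nA),
#'   `fs`, `dt`, `duration`, `n`, `kernel`, and the final `sheet`.
#' @export
simulate_cortex <- function(n = 128, duration = 30, kernel = coupling_kernel(),
                            freq_mean_hz = 20, freq_sd_hz = 4,
                            dt = 5e-4, fs = 1000, seed = NULL,
                            record_phases = FALSE,
                            filters = NULL, positions = NULL,
                            sheet = NULL) {
  if (is.null(sheet)) {
    sheet <- oscillator_sheet(n, freq_mean_hz, freq_sd_hz, seed = seed)
  }
  n <- sheet$n
  if (kernel$extent > n) stop("kernel extent exceeds grid size")
  sample_every <- round(1 / (fs * dt))
  if (abs(sample_every - 1 / (fs * dt)) > 1e-9) {
    stop("1/fs must be an integer multiple of dt")
  }
  n_steps <- round(duration / dt)
  khat <- stats::fft(wrap_kernel(kernel$weights, n))
  ghat <- list()
  if (!is.null(filters)) {
    if (is.null(positions)) stop("positions are required when filters are given")
    # conjugate turns FFT convolution into correlation, i.e. the kernel is
    # applied as G(q) * field(p + q) around each position p
    ghat <- lapply(filters, function(f) {
      stopifnot(inherits(f, "phase_gabor_kernel"))
      Conj(stats::fft(phase_gabor_full(f, n)))
    })
    pos0 <- as.matrix(positions) - 1L
    storage.mode(pos0) <- "integer"
  } else {
    pos0 <- matrix(integer(0), 0, 2)
  }
  res <- cortex_run_cpp(sheet$phases, sheet$freqs, khat, dt, n_steps,
                        sample_every, ghat, pos0, record_phases)
  n_samples <- length(res$esum)
  times <- (seq_len(n_samples) - 1) / fs
  lfp <- signal_trace(Re(res$esum) / n^2, fs = fs)
  currents <- NULL
  if (!is.null(filters)) {
    currents <- lapply(res$currents, function(m) m)
  }
  sheet$phases <- res$theta
  sheet$time <- sheet$time + n_steps * dt
  structure(list(lfp = lfp, phases = res$phases, currents = currents,
                 times = times, fs = fs, dt = dt, duration = duration,
                 n = n, kernel = kernel, sheet = sheet),
            class = "phase_history")
}

#' @export
print.phase_history <- function(x, ...) {
  cat(sprintf("<phase_history> %d x %d sheet, %.1f s at %g Hz sampling (%d samples)\n",
              x$n, x$n, x$duration, x$fs, length(x$lfp$values)))
  invisible(x)
}

#' Simulated local field potential from a phase history
#'
#' The LFP treats the cosine of each oscillator phase as a voltage and sums
#' (or averages) it across the sheet.
#'
#' @param history A `phase_history` with recorded phases.
#' @param normalize `"mean"` (default) divides by the node count; `"sum"`
#'   returns the raw sum.
#' @return A [signal_trace()].
#' @export
compute_lfp <- function(history, normalize = c("mean", "sum")) {
  normalize <- match.arg(normalize)
  if (is.null(history$phases)) {
    if (!is.null(history$lfp)) {
      v <- history$lfp$values
      if (normalize == "sum") v <- v * history$n^2
      return(signal_trace(v, fs = history$fs))
    }
    stop("history has no recorded phases")
  }
  v <- apply(cos(history$phases), 3, sum)
  if (normalize == "mean") v <- v / (dim(history$phases)[1] * dim(history$phases)[2])
  signal_trace(v, fs = history$fs)
}

#' Welch power spectrum of an LFP trace
#'
#' Spectral density estimate using Welch's periodogram method with a
#' Hamming window of 0.5 s and 50% overlap (the defaults used throughout).
#'
#' @param trace A [signal_trace()].
#' @param window_s Window length in seconds.
#' @param overlap Fractional window overlap.
#' @return A data frame with columns `freq` (Hz) and `power`.
#' @export
lfp_spectrum <- function(trace, window_s = 0.5, overlap = 0.5) {
  welch_psd(trace, window_s = window_s, overlap = overlap)
}

#' Dominant spatial frequency and orientation of a wave pattern
#'
#' Estimates the dominant wavevector of a (cosine-)phase field from the
#' peak of its 2-D amplitude spectrum, excluding the DC bin.
#'
#' @param field A real n x n matrix (typically `cos(phases)`).
#' @return A list with `wavelength` (nodes), `orientation` (radians,
#'   direction of the wavevector in `[0, pi)`), and `freq` (cycles/node).
#' @export
dominant_wave <- function(field) {
  n1 <- nrow(field); n2 <- ncol(field)
  A <- Mod(stats::fft(field - mean(field)))
  A[1, 1] <- 0
  ij <- arrayInd(which.max(A), dim(A))
  # signed frequencies in cycles/node
  f1 <- (ij[1] - 1); if (f1 > n1 / 2) f1 <- f1 - n1
  f2 <- (ij[2] - 1); if (f2 > n2 / 2) f2 <- f2 - n2
  f1 <- f1 / n1; f2 <- f2 / n2
  f <- sqrt(f1^2 + f2^2)
  ang <- atan2(f2, f1) %% pi
  list(wavelength = 1 / f, orientation = ang, freq = f)
}
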