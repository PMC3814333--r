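#' Phase-only Gabor dendritic kernel
#'
#' The dendritic receptor field of a pyramidal tract neuron in the
#' phase-only approximation: a Gabor weight profile over cortical grid
#' nodes. The dendritic current is the weighted sum of the cosine of the
#' oscillator phases under the kernel, scaled so that the kernel's
#' preferred plane wave (matched wavelength and orientation) yields a
#' configured maximal current.
#'
#' @param wavelength Wavelength of the spatial modulation (grid nodes).
#'   The default matches the dominant spatial frequency of the traveling
#'   waves produced by the default cortical model (see
#'   [default_config()]).
#' @param sigma Gaussian envelope scale (nodes); defaults to one
#'   wavelength.
#' @param orientation Orientation of the modulation axis (radians).
#' @param psi Spatial phase shift (radians); non-zero values build the
#'   asymmetric kernels used in the spike-timing experiments.
#' @param max_current_na Dendritic current (nA) produced by the preferred
#'   defect-free plane wave.
#' @return An object of class `phase_gabor_kernel`.
#' @export
phase_gabor_kernel <- function(wavelength = wavedecode_defaults$ptn_wavelength_nodes,
                               sigma = wavedecode_defaults$ptn_sigma_nodes,
                               orientation = 0, psi = 0,
                               max_current_na = wavedecode_defaults$ptn_max_current_na) {
  stopifnot(wavelength > 0, sigma > 0)
  half <- ceiling(3 * sigma)
  xs <- -half:half
  X <- matrix(xs, length(xs), length(xs))
  Y <- t(X)
  xr <- X * cos(orientation) + Y * sin(orientation)
  # zero-DC Gabor: the envelope-weighted DC term is subtracted so that the
  # filter has no response to spatially uniform synchrony (classical
  # zero-mean Gabor correction)
  dc <- exp(-2 * pi^2 * (sigma / wavelength)^2) * cos(psi)
  w <- exp(-(X^2 + Y^2) / (2 * sigma^2)) *
    (cos(2 * pi * xr / wavelength + psi) - dc)
  # amplitude of the response to the matched plane wave cos(2 pi x'/lambda - wt):
  # max over temporal phase of sum(G * cos) = |sum(G * exp(2i pi x'/lambda))|
  amp <- Mod(sum(w * exp(2i * pi * xr / wavelength)))
  scale <- max_current_na / amp
  structure(list(wavelength = wavelength, sigma = sigma,
                 orientation = orientation, psi = psi,
                 max_current_na = max_current_na, scale = scale),
            class = "phase_gabor_kernel")
}

#' @export
print.phase_gabor_kernel <- function(x, ...) {
  cat(sprintf(
    "<phase_gabor_kernel> lambda %.1f nodes, sigma %.1f, orientation %.1f deg, psi %.1f deg, max %.2f nA\n",
    x$wavelength, x$sigma, x$orientation * 180 / pi, x$psi * 180 / pi,
    x$max_current_na))
  invisible(x)
}

#' Rotate a phase Gabor kernel
#'
#' @param kernel A [phase_gabor_kernel()].
#' @param dtheta Rotation to add to the kernel orientation (radians).
#' @return The rotated kernel.
#' @export
rotate_kernel <- function(kernel, dtheta) {
  phase_gabor_kernel(kernel$wavelength, kernel$sigma,
                     kernel$orientation + dtheta, kernel$psi,
                     kernel$max_current_na)
}

# Kernel weights laid out on the full n x n periodic grid (minimum-image
# offsets, centre at element [1,1]), in nA per unit cos(theta).
phase_gabor_full <- function(kernel, n) {
  off <- ((0:(n - 1) + n %/% 2) %% n) - n %/% 2
  X <- matrix(off, n, n)
  Y <- t(X)
  xr <- X * cos(kernel$orientation) + Y * sin(kernel$orientation)
  dc <- exp(-2 * pi^2 * (kernel$sigma / kernel$wavelength)^2) * cos(kernel$psi)
  kernel$scale * exp(-(X^2 + Y^2) / (2 * kernel$sigma^2)) *
    (cos(2 * pi * xr / kernel$wavelength + kernel$psi) - dc)
}

# Gabor-filtered cosine-phase fields for every sample of a recorded phase
# history: returns an n x n x samples array (values in nA).
filter_history <- function(history, kernel) {
  if (is.null(history$phases)) stop("history has no recorded phases")
  n <- history$n
  ghat <- Conj(stats::fft(phase_gabor_full(kernel, n)))
  out <- array(0, dim = dim(history$phases))
  for (s in seq_len(dim(out)[3])) {
    E <- exp(1i * history$phases[, , s])
    out[, , s] <- Re(stats::fft(ghat * stats::fft(E), inverse = TRUE)) / n^2
  }
  out
}

#' Phase-only dendritic current of a PTN
#'
#' `I(t) = scale * sum_xy G(x, y) cos(theta(px + x, py + y, t))` with
#' periodic wrap: the Gabor-weighted sum of the cosine of the oscillator
#' phases around the PTN's cortical position.
#'
#' @param history A `phase_history` with recorded phases.
#' @param kernel A [phase_gabor_kernel()].
#' @param position Integer grid position `c(row, col)` (1-based).
#' @return A [signal_trace()] in nA.
#' @export
dendritic_current <- function(history, kernel, position) {
  f <- filter_history(history, kernel)
  signal_trace(f[position[1], position[2], ], history$fs)
}

#' Parameters of the PTN soma model
#'
#' Constants of the two-variable quadratic (Izhikevich-type) somatic
#' compartment, tuned to the firing response of pyramidal tract neurons.
#'
#' @return A named list.
#' @export
soma_params <- function() {
  list(C = 80, k = 4, v_rest = -70, v_thresh = -50, v_peak = 50,
       a = 0.04, b = 10, c = -60, d = 800, dt_ms = 0.1)
}

#' One Euler step of the soma model (reference implementation)
#'
#' `C dv/dt = k (v - v_rest)(v - v_thresh) - u + I`;
#' `du/dt = a (b (v - v_rest) - u)`. A spike is emitted when `v` reaches
#' `v_peak`, upon which `v <- c` and `u <- u + d`.
#'
#' @param state List with `v` (mV) and `u` (pA).
#' @param I_nA Injection current (nA).
#' @param dt Time step (s).
#' @param params [soma_params()].
#' @return List with updated `v`, `u` and logical `spiked`.
#' @export
soma_step <- function(state, I_nA, dt = 1e-4, params = soma_params()) {
  if (!is.finite(I_nA)) stop("non-finite current")
  I <- I_nA * 1e3  # pA
  dv <- (params$k * (state$v - params$v_rest) * (state$v - params$v_thresh) -
           state$u + I) / params$C
  du <- params$a * (params$b * (state$v - params$v_rest) - state$u)
  v <- state$v + dt * 1e3 * dv
  u <- state$u + dt * 1e3 * du
  spiked <- v >= params$v_peak
  if (spiked) {
    v <- params$c
    u <- u + params$d
  }
  list(v = v, u = u, spiked = spiked)
}

#' Integrate the soma model over a current trace
#'
#' Euler integration at the model step (0.1 ms); the input current trace
#' may be sampled more coarsely and is linearly interpolated. The PTN
#' stage is fully deterministic given its input.
#'
#' @param current A [signal_trace()] in nA, or a numeric vector with `fs`.
#' @param fs Sampling rate of `current` when given as a plain vector (Hz).
#' @param params [soma_params()].
#' @param v0,u0 Initial state.
#' @param record_v Also return the membrane-potential trace.
#' @return A [spike_train()]; when `record_v` is `TRUE`, the trace is
#'   attached as attribute `v` (a `signal_trace` at the model step).
#' @export
simulate_soma <- function(current, fs = NULL, params = soma_params(),
                          v0 = params$v_rest, u0 = 0, record_v = FALSE) {
  if (inherits(current, "signal_trace")) {
    fs <- current$fs
    current <- current$values
  }
  if (is.null(fs)) stop("fs required for plain current vectors")
  if (any(!is.finite(current))) stop("non-finite current")
  dt <- params$dt_ms * 1e-3
  res <- izhikevich_cpp(current * 1e3, 1 / fs, dt, params$C, params$k,
                        params$v_rest, params$v_thresh, params$v_peak,
                        params$a, params$b, params$c, params$d,
                        v0, u0, record_v)
  st <- spike_train(res$spike_times)
  if (record_v) attr(st, "v") <- signal_trace(res$v, 1 / dt)
  st
}

#' Steady-state firing rate versus constant injection current
#'
#' @param currents_na Currents to test (nA).
#' @param settle Settling time discarded before counting (s).
#' @param window Counting window (s).
#' @param params [soma_params()].
#' @return Data frame with `current_na` and `rate_hz`.
#' @export
fi_curve <- function(currents_na = seq(0, 2.5, by = 0.1), settle = 1,
                     window = 2, params = soma_params()) {
  rate <- vapply(currents_na, function(I) {
    tr <- rep(I, round((settle + window) * 10) + 1)
    st <- simulate_soma(tr, fs = 10, params = params)
    sum(st$times >= settle) / window
  }, numeric(1))
  data.frame(current_na = currents_na, rate_hz = rate)
}

#' Mean slope of the f-I curve over the suprathreshold range
#'
#' @param fi Data frame from [fi_curve()].
#' @param range Current range (nA) over which to fit.
#' @return Slope in Hz/nA.
#' @export
fi_slope <- function(fi, range = c(0.6, 2)) {
  sel <- fi$current_na >= range[1] & fi$current_na <= range[2]
  unname(stats::coef(stats::lm(rate_hz ~ current_na, fi[sel, ]))[2])
}

#' Firing rate versus amplitude of 20 Hz sinusoidal forcing
#'
#' The response curve of the periodically forced soma is a devil's
#' staircase: entrainment restricts the steady-state rates to m:n
#' rational multiples of the forcing frequency, with major plateaus at
#' one spike per cycle and two spikes per cycle.
#'
#' @param amplitudes_na Current amplitudes (nA).
#' @param freq Forcing frequency (Hz).
#' @param settle Settling time discarded (s).
#' @param window Counting window (s).
#' @param params [soma_params()].
#' @return Data frame with `amplitude_na` and `rate_hz`.
#' @export
staircase_curve <- function(amplitudes_na = seq(0.3, 1.6, by = 0.01),
                            freq = 20, settle = 1, window = 5,
                            params = soma_params()) {
  fs <- 1e4
  tt <- seq(0, settle + window, by = 1 / fs)
  rate <- vapply(amplitudes_na, function(A) {
    st <- simulate_soma(A * sin(2 * pi * freq * tt), fs = fs, params = params)
    sum(st$times >= settle) / window
  }, numeric(1))
  data.frame(amplitude_na = amplitudes_na, rate_hz = rate)
}

# Oscillation amplitude of a (near-)sinusoidal trace: sqrt(2) * SD is the
# amplitude of a pure sinusoid and is robust to waxing/waning.
osc_amplitude <- function(x) sqrt(2) * stats::sd(x)

#' Orientation tuning curve of the dendritic compartment
#'
#' Measures the oscillation amplitude of the phase-only dendritic current
#' at every sheet position, for kernels rotated away from a reference
#' orientation, pooled over one or more cortical histories.
#'
#' @param histories A `phase_history` (with recorded phases) or list of
#'   them.
#' @param kernel Reference [phase_gabor_kernel()] (offset 0).
#' @param offsets_deg Orientation offsets (degrees).
#' @param level Confidence level of the percentile interval.
#' @return Data frame with `offset_deg`, `mean_na`, `lo_na`, `hi_na`.
#' @export
dendritic_tuning_curve <- function(histories, kernel,
                                   offsets_deg = seq(-90, 90, by = 15),
                                   level = 0.90) {
  if (inherits(histories, "phase_history")) histories <- list(histories)
  q <- c((1 - level) / 2, 1 - (1 - level) / 2)
  rows <- lapply(offsets_deg, function(off) {
    k <- rotate_kernel(kernel, off * pi / 180)
    amps <- unlist(lapply(histories, function(h) {
      f <- filter_history(h, k)
      apply(f, c(1, 2), stats::sd) * sqrt(2)
    }))
    data.frame(offset_deg = off, mean_na = mean(amps),
               lo_na = unname(stats::quantile(amps, q[1])),
               hi_na = unname(stats::quantile(amps, q[2])))
  })
  do.call(rbind, rows)
}

#' Population tuning of randomly placed PTNs
#'
#' Places `n_ptn` PTNs at random grid positions, decodes the given
#' cortical history with kernels at each orientation offset, and returns
#' the firing rates.
#'
#' @param history A `phase_history` with recorded phases.
#' @param kernel Reference [phase_gabor_kernel()].
#' @param offsets_deg Orientation offsets (degrees).
#' @param n_ptn Number of PTNs.
#' @param seed Seed for the random placement.
#' @param settle Settling time excluded from the rate (s).
#' @return A list with `summary` (data frame `offset_deg`,
#'   `mean_rate_hz`) and `rates` (matrix, PTN x offset).
#' @export
population_tuning <- function(history, kernel, offsets_deg = c(0, 30, 60, 90),
                              n_ptn = 200, seed = NULL, settle = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- history$n
  pos <- cbind(sample.int(n, n_ptn, replace = TRUE),
               sample.int(n, n_ptn, replace = TRUE))
  duration <- history$duration
  window <- duration - settle
  rates <- matrix(0, n_ptn, length(offsets_deg))
  for (j in seq_along(offsets_deg)) {
    k <- rotate_kernel(kernel, offsets_deg[j] * pi / 180)
    f <- filter_history(history, k)
    for (p in seq_len(n_ptn)) {
      st <- simulate_soma(f[pos[p, 1], pos[p, 2], ], fs = history$fs)
      rates[p, j] <- sum(st$times >= settle) / window
    }
  }
  list(summary = data.frame(offset_deg = offsets_deg,
                            mean_rate_hz = colMeans(rates)),
       rates = rates, positions = pos)
}

#' Spike-train timing shifts induced by asymmetric dendritic kernels
#'
#' A spatial phase shift `psi` in the Gabor kernel retards the PTN spike
#' train by `psi / (2*pi)` of the oscillation period relative to the
#' symmetric kernel, for identical cortical input.
#'
#' @param history A `phase_history` with recorded phases.
#' @param kernel Reference kernel (`psi = 0`).
#' @param psis Spatial phase shifts to test (radians).
#' @param position PTN grid position `c(row, col)`.
#' @param freq_hz Oscillation frequency used to bound the search to one
#'   period.
#' @return Data frame with `psi`, `lag_s` (circular cross-correlation lag
#'   of the spike train against the `psi = 0` train) and `rate_hz`.
#' @export
phase_shift_experiment <- function(history, kernel, psis = c(0, pi / 2, pi, -pi / 2),
                                   position = c(1, 1), freq_hz = 20) {
  fs <- 2000
  duration <- history$duration
  nb <- round(duration * fs)
  smooth <- function(times) {
    x <- tabulate(pmin(floor(times * fs) + 1, nb), nbins = nb)
    kk <- stats::dnorm(seq(-10, 10), sd = 3)  # ~1.5 ms gaussian smoothing
    as.numeric(stats::filter(x, kk, sides = 2, circular = TRUE))
  }
  trains <- lapply(psis, function(psi) {
    k <- phase_gabor_kernel(kernel$wavelength, kernel$sigma,
                            kernel$orientation, psi, kernel$max_current_na)
    simulate_soma(dendritic_current(history, k, position), fs = history$fs)
  })
  ref <- smooth(trains[[which(psis == 0)[1]]]$times)
  period <- 1 / freq_hz
  max_lag <- round(period / 2 * fs)
  lags <- (-max_lag):max_lag
  out <- lapply(seq_along(psis), function(i) {
    x <- smooth(trains[[i]]$times)
    cc <- vapply(lags, function(L) {
      sum(x * ref[((seq_len(nb) - 1 + L) %% nb) + 1])
    }, numeric(1))
    data.frame(psi = psis[i], lag_s = lags[which.max(cc)] / fs,
               rate_hz = length(trains[[i]]$times) / duration)
  })
  do.call(rbind, out)
}
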