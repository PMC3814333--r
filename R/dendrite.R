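#' Parameters of the dendritic conductance model
#'
#' Membrane and synaptic constants of the point-dendrite compartment:
#' capacitance, leak and per-receptor peak conductances, reversal
#' potentials, and the rise/fall time constants of the post-synaptic
#' conductance transient.
#'
#' @return A named list of parameters (units in the names).
#' @export
dendrite_params <- function() {
  list(C_pF = 80, g_l_nS = 0.01, g_e_nS = 0.01, g_i_nS = 0.01,
       E_l_mV = -70, E_e_mV = 0, E_i_mV = -120,
       tau1_ms = 1.0, tau2_ms = 0.2, dt_ms = 0.1)
}

#' Two-dimensional Gabor profile
#'
#' A Gaussian-windowed sinusoid: the target spatial filter that the signed
#' sum of the excitatory and inhibitory receptor densities must realise.
#' The modulation runs along the axis given by `orientation`, with spatial
#' phase `psi`; `psi = 0` gives an even (cosine) filter whose value at the
#' origin equals `peak`.
#'
#' @param sigma_um Gaussian envelope scale (micrometres).
#' @param wavelength_um Wavelength of the spatial modulation (micrometres).
#' @param psi Spatial phase shift (radians).
#' @param orientation Orientation of the modulation axis (radians).
#' @param peak Peak scale (synapses/um^2 in density use).
#' @return An object of class `gabor_profile`.
#' @export
gabor_profile <- function(sigma_um = 100, wavelength_um = 300, psi = 0,
                          orientation = 0, peak = 0.2) {
  stopifnot(sigma_um > 0, wavelength_um > 0)
  structure(list(sigma = sigma_um, wavelength = wavelength_um,
                 freq = 1 / wavelength_um, psi = psi,
                 orientation = orientation, peak = peak),
            class = "gabor_profile")
}

#' Evaluate a Gabor profile
#'
#' @param p A [gabor_profile()].
#' @param x,y Coordinates in micrometres (vectorised).
#' @return Profile values (same units as `peak`).
#' @export
gabor_value <- function(p, x, y) {
  xr <- x * cos(p$orientation) + y * sin(p$orientation)
  p$peak * exp(-(x^2 + y^2) / (2 * p$sigma^2)) *
    cos(2 * pi * p$freq * xr + p$psi)
}

#' Square evaluation grid for density surfaces
#'
#' @param extent_um Side length of the square support (micrometres),
#'   centred on the origin.
#' @param spacing_um Grid spacing (micrometres).
#' @return A list with `coords` (cell-centre coordinates along one axis)
#'   and `spacing`.
#' @export
density_grid <- function(extent_um = 1200, spacing_um = 5) {
  half <- extent_um / 2
  coords <- seq(-half + spacing_um / 2, half - spacing_um / 2, by = spacing_um)
  list(coords = coords, spacing = spacing_um, extent = extent_um)
}

new_density_surface <- function(values, grid, polarity) {
  stopifnot(all(values >= 0), polarity %in% c("excitatory", "inhibitory"))
  structure(list(values = values, grid = grid, polarity = polarity),
            class = "density_surface")
}

#' Gaussian receptor density surface
#'
#' @param peak Peak density (synapses/um^2).
#' @param sigma_um Gaussian scale (micrometres).
#' @param polarity `"excitatory"` or `"inhibitory"`.
#' @param grid A [density_grid()].
#' @return A `density_surface`.
#' @export
gaussian_density <- function(peak = 0.4, sigma_um = 115,
                             polarity = "excitatory", grid = density_grid()) {
  r2 <- outer(grid$coords^2, grid$coords^2, "+")
  new_density_surface(peak * exp(-r2 / (2 * sigma_um^2)), grid, polarity)
}

# Evaluate a gabor_profile on a density grid (signed matrix; rows index x).
gabor_on_grid <- function(p, grid) {
  X <- matrix(grid$coords, length(grid$coords), length(grid$coords))
  Y <- t(X)
  matrix(gabor_value(p, as.vector(X), as.vector(Y)), nrow(X), ncol(X))
}

#' Solve the complementary receptor density
#'
#' Given a target Gabor filter and a nominated density surface of one
#' polarity, returns the density surface of the opposite polarity such
#' that `excitatory - inhibitory` reproduces the target on the grid.
#' Negative values of the solution (infeasible densities) are clipped to
#' zero; the clipped mass is recorded in the `clipped_mass` attribute
#' (synapse count) and an error is raised when it exceeds 5% of the
#' solution's mass, which indicates that the nominated surface is too
#' small to dominate the target's lobes of its polarity.
#'
#' @param target A [gabor_profile()] or a signed matrix on the same grid.
#' @param nominated A `density_surface` (either polarity).
#' @return The complementary `density_surface`.
#' @export
solve_complement_density <- function(target, nominated) {
  stopifnot(inherits(nominated, "density_surface"))
  g <- if (inherits(target, "gabor_profile")) {
    gabor_on_grid(target, nominated$grid)
  } else target
  sol <- if (nominated$polarity == "excitatory") {
    nominated$values - g   # inhibitory = excitatory - gabor
  } else {
    nominated$values + g   # excitatory = inhibitory + gabor
  }
  clipped <- -sum(sol[sol < 0]) * nominated$grid$spacing^2
  total <- sum(pmax(sol, 0)) * nominated$grid$spacing^2
  if (clipped > 0.05 * total) {
    stop(sprintf(
      "nominated surface too small to dominate the target lobes (clipped mass %.1f of %.1f)",
      clipped, total))
  }
  out <- new_density_surface(
    pmax(sol, 0), nominated$grid,
    if (nominated$polarity == "excitatory") "inhibitory" else "excitatory")
  attr(out, "clipped_mass") <- clipped
  out
}

#' Expected receptor count of a density surface
#'
#' The number of receptors sampled from a surface is, by definition, the
#' volume under the density distribution.
#'
#' @param surface A `density_surface`.
#' @return Expected (real-valued) receptor count.
#' @export
density_mass <- function(surface) {
  sum(surface$values) * surface$grid$spacing^2
}

#' Sample discrete receptor positions from a density surface
#'
#' Draws `round(density_mass(surface))` positions with probability
#' proportional to the density (cell-weighted sampling with uniform jitter
#' within each cell). A zero-mass surface yields an empty sample.
#'
#' @param surface A `density_surface`.
#' @param seed Optional integer seed.
#' @return A data frame with columns `x_um`, `y_um`, `polarity`.
#' @export
sample_receptors <- function(surface, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(density_mass(surface))
  if (n == 0) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      polarity = character(0)))
  }
  p <- as.vector(surface$values)
  cells <- sample.int(length(p), n, replace = TRUE, prob = p)
  nc <- length(surface$grid$coords)
  ix <- (cells - 1) %% nc + 1
  iy <- (cells - 1) %/% nc + 1
  sp <- surface$grid$spacing
  data.frame(
    x_um = surface$grid$coords[ix] + stats::runif(n, -sp / 2, sp / 2),
    y_um = surface$grid$coords[iy] + stats::runif(n, -sp / 2, sp / 2),
    polarity = surface$polarity)
}

#' Build a combined excitatory/inhibitory receptor field
#'
#' Nominates a Gaussian density for one polarity, solves the complementary
#' density against the target Gabor filter, and samples discrete receptors
#' from both surfaces.
#'
#' @param gabor Target [gabor_profile()].
#' @param nominated Which polarity is nominated as Gaussian.
#' @param nominated_peak Peak density of the nominated Gaussian
#'   (synapses/um^2). Defaults follow the standard configuration: 0.4 for
#'   an excitatory nomination, 0.3 for an inhibitory one.
#' @param nominated_sigma_um Gaussian scale of the nominated density.
#' @param grid A [density_grid()].
#' @param seed Optional integer seed for the sampling.
#' @return An object of class `receptor_field`: list with `receptors`
#'   (data frame `x_um`, `y_um`, `polarity`), `counts`, and the two
#'   `surfaces`.
#' @export
receptor_field <- function(gabor = gabor_profile(),
                           nominated = c("excitatory", "inhibitory"),
                           nominated_peak = NULL,
                           nominated_sigma_um = 115,
                           grid = density_grid(), seed = NULL) {
  nominated <- match.arg(nominated)
  if (is.null(nominated_peak)) {
    nominated_peak <- if (nominated == "excitatory") 0.4 else 0.3
  }
  nom <- gaussian_density(nominated_peak, nominated_sigma_um, nominated, grid)
  comp <- solve_complement_density(gabor, nom)
  if (!is.null(seed)) set.seed(seed)
  rec <- rbind(sample_receptors(nom), sample_receptors(comp))
  counts <- c(table(factor(rec$polarity, c("excitatory", "inhibitory"))))
  structure(list(receptors = rec, counts = counts,
                 surfaces = stats::setNames(
                   list(nom, comp), c(nom$polarity, comp$polarity)),
                 gabor = gabor),
            class = "receptor_field")
}

#' @export
print.receptor_field <- function(x, ...) {
  cat(sprintf("<receptor_field> %d excitatory + %d inhibitory receptors\n",
              x$counts[["excitatory"]], x$counts[["inhibitory"]]))
  invisible(x)
}

#' Moving sinusoidal grating
#'
#' A plane sinusoid advancing along its normal, used to emulate traveling
#' wave activity across the receptor field. At any fixed point the signal
#' oscillates at `speed / wavelength` Hz.
#'
#' @param x,y Positions (micrometres; vectorised).
#' @param t Time (seconds; scalar or vector conformable with `x`).
#' @param wavelength_um Spatial wavelength (micrometres).
#' @param speed_um_s Propagation speed (micrometres per second).
#' @param orientation Direction of propagation (radians).
#' @return Amplitudes in `[-1, 1]`.
#' @export
grating_amplitude <- function(x, y, t, wavelength_um = 300,
                              speed_um_s = 6000, orientation = 0) {
  stopifnot(wavelength_um > 0)
  xr <- x * cos(orientation) + y * sin(orientation)
  cos(2 * pi * (xr - speed_um_s * t) / wavelength_um)
}

#' Poisson synaptic bombardment of a receptor field
#'
#' Generates, for every receptor, an inhomogeneous Poisson event train
#' whose instantaneous rate is `rate_fn(x, y, t)` Hz, realised as
#' per-step Bernoulli draws with `p = rate * dt` (negligible bias at the
#' default 0.1 ms step).
#'
#' @param field A `receptor_field` or data frame with `x_um`, `y_um`.
#' @param rate_fn Vectorised function of `(x, y, t)` returning rates (Hz).
#' @param duration Duration (s).
#' @param dt Time step (s).
#' @param seed Optional integer seed.
#' @return A list of numeric event-time vectors, one per receptor.
#' @export
poisson_bombardment <- function(field, rate_fn, duration, dt = 1e-4,
                                seed = NULL) {
  rec <- if (inherits(field, "receptor_field")) field$receptors else field
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(rec)
  n_steps <- round(duration / dt)
  events <- vector("list", n)
  for (i in seq_len(n)) events[[i]] <- numeric(0)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    rate <- rate_fn(rec$x_um, rec$y_um, t)
    if (any(rate < 0)) stop("negative rate")
    hit <- which(stats::runif(n) < rate * dt)
    for (i in hit) events[[i]] <- c(events[[i]], t)
  }
  events
}

# Unit-peak double-exponential post-synaptic conductance transient,
# normalised so the per-event peak equals 1 (the Table-1 receptor
# conductance is applied as a multiplier).
psc_norm <- function(tau1_ms, tau2_ms) {
  tp <- tau1_ms * tau2_ms / (tau1_ms - tau2_ms) * log(tau1_ms / tau2_ms)
  list(t_peak_ms = tp, norm = exp(-tp / tau1_ms) - exp(-tp / tau2_ms))
}

# Filter a per-bin event-count sequence with the unit-peak double
# exponential, exactly (recursive first-order filters on each
# exponential); counts are events whose onset falls at each bin start.
psc_filter <- function(counts, dt_ms, tau1_ms, tau2_ms) {
  a1 <- exp(-dt_ms / tau1_ms)
  a2 <- exp(-dt_ms / tau2_ms)
  y1 <- stats::filter(counts, a1, method = "recursive")
  y2 <- stats::filter(counts, a2, method = "recursive")
  as.numeric(y1 - y2) / psc_norm(tau1_ms, tau2_ms)$norm
}

#' Integrate the conductance-based dendritic membrane
#'
#' Each synaptic event adds a normalised rise-and-fall conductance
#' transient with unit peak times the per-receptor conductance; the
#' excitatory and inhibitory population conductances drive the membrane
#' equation `C dV/dt = g_l (E_l - V) + g_e(t) (E_e - V) + g_i(t) (E_i - V)`
#' integrated by the Euler method at the model time step.
#'
#' @param events Either a list of per-receptor event-time vectors (paired
#'   with `polarity`), or a list with elements `excitatory` and
#'   `inhibitory` giving per-bin event counts at `dt`.
#' @param duration Duration (s).
#' @param params [dendrite_params()].
#' @param polarity Character vector of per-receptor polarities (required
#'   for the event-time form).
#' @return A list of [signal_trace()]s: `v` (mV), `g_e`, `g_i` (nS),
#'   `i_e`, `i_i`, `i_l` (pA), at the model sampling rate.
#' @export
integrate_dendrite <- function(events, duration, params = dendrite_params(),
                               polarity = NULL) {
  dt_ms <- params$dt_ms
  dt <- dt_ms * 1e-3
  n_steps <- round(duration / dt)
  if (!is.null(names(events)) &&
      all(c("excitatory", "inhibitory") %in% names(events))) {
    ce <- events$excitatory
    ci <- events$inhibitory
    stopifnot(length(ce) == n_steps, length(ci) == n_steps)
  } else {
    if (is.null(polarity)) stop("polarity required for per-receptor events")
    bin <- function(idx) {
      tt <- unlist(events[idx], use.names = FALSE)
      tabulate(pmin(floor(tt / dt) + 1, n_steps), nbins = n_steps)
    }
    ce <- bin(which(polarity == "excitatory"))
    ci <- bin(which(polarity == "inhibitory"))
  }
  g_e <- params$g_e_nS * psc_filter(ce, dt_ms, params$tau1_ms, params$tau2_ms)
  g_i <- params$g_i_nS * psc_filter(ci, dt_ms, params$tau1_ms, params$tau2_ms)
  v <- numeric(n_steps)
  vi <- params$E_l_mV
  for (s in seq_len(n_steps)) {
    v[s] <- vi
    i_l <- params$g_l_nS * (params$E_l_mV - vi)
    i_e <- g_e[s] * (params$E_e_mV - vi)
    i_i <- g_i[s] * (params$E_i_mV - vi)
    vi <- vi + dt_ms * (i_l + i_e + i_i) / params$C_pF  # nS*mV = pA; pA/pF = mV/ms
  }
  fs <- 1 / dt
  list(v = signal_trace(v, fs),
       g_e = signal_trace(g_e, fs),
       g_i = signal_trace(g_i, fs),
       i_e = signal_trace(g_e * (params$E_e_mV - v), fs),
       i_i = signal_trace(g_i * (params$E_i_mV - v), fs),
       i_l = signal_trace(params$g_l_nS * (params$E_l_mV - v), fs))
}

#' Simulate the dendritic response to a moving grating
#'
#' Full conductance-based response of a sampled receptor field under
#' Poisson bombardment whose rate is modulated by a moving sinusoidal
#' grating: `rate = rate_mean * (1 + grating)` Hz per receptor (0 to twice
#' the mean). The default fast path aggregates the Poisson processes of
#' each polarity analytically (the population event count in a bin is
#' Poisson with the summed rate, and the sum of the sinusoidal rates over
#' receptors reduces to a single sinusoid computed from the receptor
#' positions), which is exact in distribution for the population
#' conductances. `aggregate = FALSE` draws every receptor separately.
#'
#' @param field A `receptor_field`.
#' @param duration Duration (s).
#' @param orientation Grating propagation direction (radians); the
#'   receptor field's preferred direction is 0.
#' @param wavelength_um,speed_um_s Grating geometry.
#' @param rate_mean_hz Long-run mean rate per receptor (Hz).
#' @param params [dendrite_params()].
#' @param seed Optional integer seed.
#' @param aggregate Use the aggregated population Poisson fast path.
#' @return As [integrate_dendrite()], plus `i_net` (pA, `i_e + i_i`) and
#'   the per-polarity mean rates actually realised.
#' @export
simulate_dendrite_response <- function(field, duration = 5, orientation = 0,
                                       wavelength_um = 300, speed_um_s = 6000,
                                       rate_mean_hz = 20,
                                       params = dendrite_params(),
                                       seed = NULL, aggregate = TRUE) {
  rec <- field$receptors
  if (!is.null(seed)) set.seed(seed)
  dt <- params$dt_ms * 1e-3
  n_steps <- round(duration / dt)
  tt <- (seq_len(n_steps) - 1) * dt
  omega <- 2 * pi * speed_um_s / wavelength_um
  if (aggregate) {
    counts <- list()
    for (pol in c("excitatory", "inhibitory")) {
      sel <- rec$polarity == pol
      xr <- rec$x_um[sel] * cos(orientation) + rec$y_um[sel] * sin(orientation)
      z <- sum(exp(2i * pi * xr / wavelength_um))
      lambda <- rate_mean_hz * (sum(sel) + Re(z * exp(-1i * omega * tt)))
      counts[[pol]] <- stats::rpois(n_steps, lambda * dt)
    }
    res <- integrate_dendrite(counts, duration, params)
  } else {
    rate_fn <- function(x, y, t) {
      rate_mean_hz * (1 + grating_amplitude(x, y, t, wavelength_um,
                                            speed_um_s, orientation))
    }
    ev <- poisson_bombardment(rec, rate_fn, duration, dt)
    res <- integrate_dendrite(ev, duration, params, polarity = rec$polarity)
    counts <- NULL
  }
  res$i_net <- signal_trace(res$i_e$values + res$i_i$values, res$i_e$fs)
  res$mean_rate_hz <- if (aggregate) {
    c(excitatory = sum(counts$excitatory) / duration / sum(rec$polarity == "excitatory"),
      inhibitory = sum(counts$inhibitory) / duration / sum(rec$polarity == "inhibitory"))
  } else NULL
  res
}

#' Spatial frequency response of a sampled receptor field
#'
#' For each candidate wavelength, the response is the maximum over grating
#' phase of the signed sum of grating values at the receptor positions
#' (excitatory +1, inhibitory -1), which equals the modulus of the signed
#' complex sum `sum(polarity * exp(2i*pi*x'/lambda))`. The curve is
#' normalised to its maximum.
#'
#' @param field A `receptor_field` or data frame with `x_um`, `y_um`,
#'   `polarity`.
#' @param wavelengths_um Candidate wavelengths (micrometres).
#' @param orientation Grating direction (radians).
#' @return Data frame with `wavelength_um` and `response`.
#' @export
field_frequency_response <- function(field,
                                     wavelengths_um = seq(100, 1000, by = 10),
                                     orientation = 0) {
  rec <- if (inherits(field, "receptor_field")) field$receptors else field
  if (nrow(rec) == 0) stop("empty receptor field")
  xr <- rec$x_um * cos(orientation) + rec$y_um * sin(orientation)
  s <- ifelse(rec$polarity == "excitatory", 1, -1)
  resp <- vapply(wavelengths_um,
                 function(w) Mod(sum(s * exp(2i * pi * xr / w))),
                 numeric(1))
  m <- max(resp)
  data.frame(wavelength_um = wavelengths_um,
             response = if (m > 0) resp / m else resp)
}

#' Spatial frequency response of a pair of density surfaces
#'
#' Continuous analogue of [field_frequency_response()]: the modulus of the
#' Fourier transform of the signed density (excitatory minus inhibitory)
#' along a given direction.
#'
#' @param excitatory,inhibitory `density_surface`s on a shared grid.
#' @param wavelengths_um Candidate wavelengths (micrometres).
#' @param orientation Direction (radians).
#' @return Data frame with `wavelength_um` and `response` (normalised).
#' @export
surface_frequency_response <- function(excitatory, inhibitory,
                                       wavelengths_um = seq(100, 1000, by = 10),
                                       orientation = 0) {
  g <- excitatory$grid
  signed <- excitatory$values - inhibitory$values
  X <- matrix(g$coords, length(g$coords), length(g$coords))
  Y <- t(X)
  xr <- X * cos(orientation) + Y * sin(orientation)
  resp <- vapply(wavelengths_um, function(w) {
    Mod(sum(signed * exp(2i * pi * xr / w))) * g$spacing^2
  }, numeric(1))
  data.frame(wavelength_um = wavelengths_um, response = resp / max(resp))
}
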