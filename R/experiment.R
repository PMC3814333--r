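# Package-level default constants shared between the module defaults and
# the experiment configuration. Three of these are calibrated rather than
# tabulated model constants (see the methods vignette for the calibration
# procedure and rationale): the global cortical coupling gain, the Gabor
# wavelength matched to the dominant spatial frequency of the emergent
# waves, and the motor-neuron firing threshold.
wavedecode_defaults <- list(
  coupling_gain = 60,
  s_minor = 0.4,
  ptn_wavelength_nodes = 13,
  ptn_sigma_nodes = 2.5,
  ptn_max_current_na = 2.2,
  mn_threshold_mv = 140
)

#' Default configuration of the descending motor experiment
#'
#' All tunable parameters of the full pipeline in one serialisable list,
#' grouped by stage. Every random draw of an experiment is derived from
#' the single `seed`.
#'
#' @param ... Named overrides of top-level entries (applied after the
#'   defaults, recursively for list entries).
#' @return A named list of class `experiment_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    cortex = list(
      grid_size = 128,
      freq_mean_hz = 20,
      freq_sd_hz = 4,
      dt_s = 5e-4,
      fs_hz = 1000,
      kernel_fwhh_nodes = 11,
      kernel_extent_nodes = 37,
      s_major = 1.0,
      s_minor = wavedecode_defaults$s_minor,
      wave_orientation_deg = 60,
      coupling_gain = wavedecode_defaults$coupling_gain
    ),
    ptn = list(
      n_ptn = 200,
      wavelength_nodes = wavedecode_defaults$ptn_wavelength_nodes,
      sigma_nodes = wavedecode_defaults$ptn_sigma_nodes,
      psi = 0,
      max_current_na = wavedecode_defaults$ptn_max_current_na
    ),
    mn = list(
      n_mn = 100,
      fan_in = 60,
      threshold_mv = wavedecode_defaults$mn_threshold_mv,
      muap_tau_ms = 3,
      muap_duration_ms = 15
    ),
    run = list(
      duration_s = 30,
      settle_s = 1,
      offsets_deg = c(0, 30, 60, 90),
      seed = 1
    )
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  class(cfg) <- "experiment_config"
  cfg
}

#' Read / write an experiment configuration
#'
#' Configurations round-trip through flat YAML.
#'
#' @param path File path.
#' @return `load_config` returns an `experiment_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(default_config, cfg)
}

#' @param config An `experiment_config`.
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

# Independent sub-seeds derived from the global seed (kept below 2^31).
derive_seed <- function(seed, k) (seed * 1000L + k) %% 2147483647L

cortex_kernel_from_config <- function(cc) {
  coupling_kernel(extent = cc$kernel_extent_nodes,
                  sigma = cc$kernel_fwhh_nodes / (2 * sqrt(2 * log(2))),
                  s_major = cc$s_major, s_minor = cc$s_minor,
                  phi_k = cc$wave_orientation_deg * pi / 180,
                  gain = cc$coupling_gain)
}

#' Run the orientation-offset experiment end to end
#'
#' Simulates one cortical traveling-wave history with the coupling kernel
#' at the configured wave orientation, then decodes that same history with
#' PTN populations whose dendritic Gabor filters are rotated away from the
#' wave orientation by each configured offset. For every offset the PTN
#' spikes drive the motor-neuron pool through the random wiring, the pool
#' output is rendered as surface EMG, and LFP-EMG coherence is computed.
#' The PTN placement, wiring, motor pool and MUAP templates are shared
#' across offsets so that conditions differ only in filter orientation.
#'
#' @param config An [default_config()].
#' @param seed Overrides `config$run$seed` when given.
#' @return An object of class `run_report`: list with `summary` (data
#'   frame: offset, PTN and MN mean rates, EMG RMS, peak beta coherence),
#'   `ptn_rates`, `mn_rates` (matrices, unit x offset), `ptn_spikes`,
#'   `mn_spikes` (lists by offset), `emg`, `coherence` (lists by offset),
#'   `lfp`, and the `config`.
#' @export
run_offset_experiment <- function(config = default_config(), seed = NULL) {
  if (!is.null(seed)) config$run$seed <- seed
  seed <- config$run$seed
  cc <- config$cortex; pc <- config$ptn; mc <- config$mn; rc <- config$run
  kernel <- cortex_kernel_from_config(cc)
  wave_or <- cc$wave_orientation_deg * pi / 180

  set.seed(derive_seed(seed, 1))
  positions <- cbind(sample.int(cc$grid_size, pc$n_ptn, replace = TRUE),
                     sample.int(cc$grid_size, pc$n_ptn, replace = TRUE))
  filters <- lapply(rc$offsets_deg, function(off) {
    phase_gabor_kernel(pc$wavelength_nodes, pc$sigma_nodes,
                       wave_or + off * pi / 180, pc$psi, pc$max_current_na)
  })

  history <- simulate_cortex(
    n = cc$grid_size, duration = rc$duration_s, kernel = kernel,
    freq_mean_hz = cc$freq_mean_hz, freq_sd_hz = cc$freq_sd_hz,
    dt = cc$dt_s, fs = cc$fs_hz, seed = derive_seed(seed, 2),
    filters = filters, positions = positions)

  wiring <- wire_pool(pc$n_ptn, mc$n_mn, mc$fan_in,
                      seed = derive_seed(seed, 3))
  pool <- motor_pool(mc$n_mn, threshold = mc$threshold_mv,
                     seed = derive_seed(seed, 4))
  templates <- muap_templates(mc$n_mn, mc$muap_tau_ms, mc$muap_duration_ms,
                              fs = cc$fs_hz, seed = derive_seed(seed, 5))

  window <- rc$duration_s - rc$settle_s
  n_off <- length(rc$offsets_deg)
  ptn_rates <- matrix(0, pc$n_ptn, n_off)
  mn_rates <- matrix(0, mc$n_mn, n_off)
  ptn_spikes <- mn_spikes <- emg <- coh <- vector("list", n_off)
  for (j in seq_len(n_off)) {
    trains <- lapply(seq_len(pc$n_ptn), function(p) {
      simulate_soma(history$currents[[j]][p, ], fs = cc$fs_hz)
    })
    ptn_spikes[[j]] <- trains
    ptn_rates[, j] <- vapply(trains, function(s) {
      sum(s$times >= rc$settle_s) / window
    }, numeric(1))
    set.seed(derive_seed(seed, 10 + j))
    mns <- simulate_motor_pool(pool, wiring, trains, rc$duration_s)
    mn_spikes[[j]] <- mns
    mn_rates[, j] <- vapply(mns, function(s) {
      sum(s$times >= rc$settle_s) / window
    }, numeric(1))
    emg[[j]] <- synthesize_emg(mns, templates, rc$duration_s)
    coh[[j]] <- welch_coherence(history$lfp, emg[[j]])
  }
  summary <- data.frame(
    offset_deg = rc$offsets_deg,
    ptn_rate_hz = colMeans(ptn_rates),
    mn_rate_hz = colMeans(mn_rates),
    emg_rms = vapply(emg, function(e) stats::sd(e$values), numeric(1)),
    beta_coherence = vapply(coh, function(s) peak_coherence(s)$coherence,
                            numeric(1)))
  structure(list(summary = summary, ptn_rates = ptn_rates,
                 mn_rates = mn_rates, ptn_spikes = ptn_spikes,
                 mn_spikes = mn_spikes, emg = emg, coherence = coh,
                 lfp = history$lfp, positions = positions,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Deterministic and seeded fixtures for tests and demonstrations
#'
#' * `plane_wave_history`: a defect-free traveling plane wave,
#'   `theta(x, y, t) = 2*pi*(f*t - x'/lambda)`, as a `phase_history` with
#'   recorded phases (params: `n`, `wavelength`, `orientation`, `freq`,
#'   `duration`, `fs`).
#' * `poisson_train`: homogeneous Poisson spike train (params: `rate`,
#'   `duration`).
#' * `sinusoid_current`: sinusoidal injection current (params: `amp_na`,
#'   `freq`, `duration`, `fs`).
#' * `grating`: closure `f(x, y, t)` over [grating_amplitude()] (params:
#'   `wavelength_um`, `speed_um_s`, `orientation`).
#'
#' @param name Fixture name.
#' @param params Named list of parameters (see above; all optional).
#' @param seed Integer seed for the stochastic fixtures.
#' @return The fixture object.
#' @export
make_fixture <- function(name, params = list(), seed = 1) {
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default
  switch(
    name,
    plane_wave_history = {
      n <- p("n", 32); lambda <- p("wavelength", 8)
      orient <- p("orientation", 0); freq <- p("freq", 20)
      duration <- p("duration", 1); fs <- p("fs", 1000)
      nt <- round(duration * fs)
      X <- matrix(0:(n - 1), n, n); Y <- t(X)
      xr <- X * cos(orient) + Y * sin(orient)
      phases <- array(0, c(n, n, nt))
      for (s in seq_len(nt)) {
        phases[, , s] <- wrap_phase(2 * pi * (freq * (s - 1) / fs - xr / lambda))
      }
      h <- structure(list(lfp = NULL, phases = phases, currents = NULL,
                          times = (seq_len(nt) - 1) / fs, fs = fs,
                          dt = 1 / fs, duration = duration, n = n,
                          kernel = NULL, sheet = NULL),
                     class = "phase_history")
      h$lfp <- compute_lfp(h)
      h
    },
    poisson_train = {
      set.seed(seed)
      rate <- p("rate", 20); duration <- p("duration", 100)
      n <- stats::rpois(1, rate * duration)
      spike_train(sort(stats::runif(n, 0, duration)))
    },
    sinusoid_current = {
      amp <- p("amp_na", 1); freq <- p("freq", 20)
      duration <- p("duration", 2); fs <- p("fs", 1e4)
      tt <- seq(0, duration, by = 1 / fs)
      signal_trace(amp * sin(2 * pi * freq * tt), fs)
    },
    grating = {
      wl <- p("wavelength_um", 300); sp <- p("speed_um_s", 6000)
      orient <- p("orientation", 0)
      function(x, y, t) grating_amplitude(x, y, t, wl, sp, orient)
    },
    stop(sprintf("unknown fixture '%s'", name))
  )
}
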