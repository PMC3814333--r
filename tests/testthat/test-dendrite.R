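test_that("Gabor profile values: peak, symmetry, odd phase", {
  p <- gabor_profile(sigma_um = 100, wavelength_um = 300, psi = 0, peak = 0.2)
  expect_equal(gabor_value(p, 0, 0), 0.2)
  xs <- c(-250, -80, 40, 130); ys <- c(10, -60, 90, -200)
  expect_equal(gabor_value(p, xs, ys), gabor_value(p, -xs, -ys))

  podd <- gabor_profile(psi = pi / 2)
  expect_equal(gabor_value(podd, 0, 0), 0)
})

test_that("complement solver reconstructs the target Gabor", {
  grid <- density_grid(1200, 10)
  gab <- gabor_profile()
  exc <- gaussian_density(0.4, 115, "excitatory", grid)
  inh <- solve_complement_density(gab, exc)
  expect_s3_class(inh, "density_surface")
  expect_equal(inh$polarity, "inhibitory")
  target <- wavedecode:::gabor_on_grid(gab, grid)
  expect_lt(max(abs(exc$values - inh$values - target)), 0.01 * gab$peak)
  expect_lt(attr(inh, "clipped_mass"), 1)

  # nominated surface too small to dominate the Gabor lobes
  small <- gaussian_density(0.05, 50, "excitatory", grid)
  expect_error(solve_complement_density(gab, small), "clipped")

  # pure-Gaussian target nominated as itself: complement vanishes
  flat <- gabor_profile(sigma_um = 100, wavelength_um = 1e9, peak = 0.4)
  nom <- gaussian_density(0.4, 100, "excitatory", grid)
  comp <- solve_complement_density(flat, nom)
  expect_lt(max(comp$values), 1e-6)
})

test_that("excitatory- and inhibitory-nominated constructions give the same
           frequency response, peaked at 300 um", {
  grid <- density_grid(1200, 10)
  gab <- gabor_profile()
  exc <- gaussian_density(0.4, 115, "excitatory", grid)
  inh <- solve_complement_density(gab, exc)
  r1 <- surface_frequency_response(exc, inh)

  inh2 <- gaussian_density(0.3, 115, "inhibitory", grid)
  exc2 <- solve_complement_density(gab, inh2)
  r2 <- surface_frequency_response(exc2, inh2)

  expect_equal(r1$wavelength_um[which.max(r1$response)], 300)
  expect_equal(r2$wavelength_um[which.max(r2$response)], 300)
  expect_lt(max(abs(r1$response - r2$response)), 0.02)
})

test_that("receptor sampling: counts, uniformity, density consistency", {
  # uniform density 1/um^2 over 100 um x 100 um -> exactly 10,000 receptors
  g <- density_grid(100, 2)
  u <- wavedecode:::new_density_surface(matrix(1, 50, 50), g, "excitatory")
  expect_equal(density_mass(u), 1e4)
  r <- sample_receptors(u, seed = 1)
  expect_equal(nrow(r), 1e4)
  # uniformity over a 5 x 5 partition
  tab <- table(cut(r$x_um, seq(-50, 50, by = 20)),
               cut(r$y_um, seq(-50, 50, by = 20)))
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.01)

  # zero-mass surface gives an empty (not error) sample
  z <- wavedecode:::new_density_surface(matrix(0, 50, 50), g, "inhibitory")
  expect_equal(nrow(sample_receptors(z)), 0)

  # empirical histogram of many draws matches the source density
  g2 <- density_grid(400, 40)
  vals <- matrix(runif(100, 0.5, 2), 10, 10)
  s2 <- wavedecode:::new_density_surface(vals, g2, "excitatory")
  set.seed(2)
  big <- sample_receptors(s2)
  n_per_cell <- round(density_mass(s2))
  ix <- findInterval(big$x_um, seq(-200, 200, by = 40),
                     rightmost.closed = TRUE)
  iy <- findInterval(big$y_um, seq(-200, 200, by = 40),
                     rightmost.closed = TRUE)
  counts <- table(factor(ix, 1:10), factor(iy, 1:10))
  expected <- vals / sum(vals)
  pv <- stats::chisq.test(as.vector(counts), p = as.vector(expected))$p.value
  expect_gt(pv, 0.01)
})

test_that("standard receptor field has a physiological synapse count", {
  f <- receptor_field(seed = 3)
  total <- sum(f$counts)
  expect_gte(total, 60000)
  expect_lte(total, 100000)
  # counts equal the volumes under the densities
  expect_equal(unname(f$counts["excitatory"]),
               round(density_mass(f$surfaces$excitatory)))
})

test_that("moving grating: bounds, temporal frequency, periodicity", {
  x <- runif(20, -300, 300); y <- runif(20, -300, 300)
  a <- grating_amplitude(x, y, 0.123)
  expect_true(all(abs(a) <= 1))
  # wavelength 300 um at 6000 um/s -> 20 Hz at any fixed point
  expect_equal(grating_amplitude(x, y, 0.1), grating_amplitude(x, y, 0.1 + 1 / 20),
               tolerance = 1e-9)
  # orthogonal grating constant along the filter's modulation axis
  b1 <- grating_amplitude(-200, 50, 0.02, orientation = pi / 2)
  b2 <- grating_amplitude(200, 50, 0.02, orientation = pi / 2)
  expect_equal(b1, b2)
  expect_error(grating_amplitude(0, 0, 0, wavelength_um = -1))
})

test_that("Poisson bombardment: counts and degenerate rates", {
  one <- data.frame(x_um = 0, y_um = 0, polarity = "excitatory")
  ev <- poisson_bombardment(one, function(x, y, t) 20, duration = 100,
                            dt = 1e-3, seed = 4)
  expect_gt(length(ev[[1]]), 2000 - 3 * sqrt(2000))
  expect_lt(length(ev[[1]]), 2000 + 3 * sqrt(2000))

  ev0 <- poisson_bombardment(one, function(x, y, t) 0, duration = 1)
  expect_length(ev0[[1]], 0)
  expect_error(poisson_bombardment(one, function(x, y, t) -1, duration = 0.01),
               "negative")
})

test_that("conductance transient: unit peak, timing, superposition, leak", {
  pars <- dendrite_params()
  # single excitatory event at t = 0
  res <- integrate_dendrite(list(`1` = 0), duration = 0.01, params = pars,
                            polarity = "excitatory")
  tp <- with(pars, tau1_ms * tau2_ms / (tau1_ms - tau2_ms) * log(tau1_ms / tau2_ms))
  imax <- which.max(res$g_e$values)
  expect_equal(max(res$g_e$values), pars$g_e_nS, tolerance = 1e-3)
  expect_equal((imax - 1) * pars$dt_ms, tp, tolerance = pars$dt_ms)
  expect_equal(max(res$g_i$values), 0)

  # K coincident events give exactly K-fold the single-event transient
  ce <- numeric(100); ce[1] <- 5
  resK <- integrate_dendrite(list(excitatory = ce, inhibitory = numeric(100)),
                             duration = 0.01, params = pars)
  expect_equal(resK$g_e$values, 5 * res$g_e$values, tolerance = 1e-12)

  # no events: membrane stays at leak equilibrium
  res0 <- integrate_dendrite(list(excitatory = numeric(1000),
                                  inhibitory = numeric(1000)),
                             duration = 0.1, params = pars)
  expect_equal(res0$v$values[1000], pars$E_l_mV, tolerance = 1e-9)

  # membrane bookkeeping: C dV/dt equals the sum of the currents
  ce2 <- numeric(2000); ce2[c(100, 600, 1500)] <- 1
  ci2 <- numeric(2000); ci2[c(300, 900)] <- 2
  r <- integrate_dendrite(list(excitatory = ce2, inhibitory = ci2),
                          duration = 0.2, params = pars)
  lhs <- diff(r$v$values) / (pars$dt_ms * 1e-3) * pars$C_pF * 1e-3  # pA
  rhs <- (r$i_l$values + r$i_e$values + r$i_i$values)[-2000]
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("per-receptor firing averages 20 Hz under the standard grating", {
  set.seed(5)
  rec <- data.frame(x_um = runif(200, -300, 300),
                    y_um = runif(200, -300, 300),
                    polarity = "excitatory")
  rate_fn <- function(x, y, t) 20 * (1 + grating_amplitude(x, y, t))
  ev <- poisson_bombardment(rec, rate_fn, duration = 5, dt = 1e-3, seed = 6)
  mean_rate <- mean(lengths(ev)) / 5
  expect_equal(mean_rate, 20, tolerance = 0.05 * 20)
})

test_that("aggregated population Poisson path matches per-receptor draws", {
  grid <- density_grid(1200, 20)
  gab <- gabor_profile()
  f <- receptor_field(gab, grid = grid, seed = 7)
  # thin the field so the per-receptor path is tractable
  keep <- sort(sample.int(nrow(f$receptors), 1500))
  f$receptors <- f$receptors[keep, ]
  agg <- simulate_dendrite_response(f, duration = 2, seed = 8,
                                    aggregate = TRUE)
  per <- simulate_dendrite_response(f, duration = 2, seed = 8,
                                    aggregate = FALSE)
  expect_equal(mean(agg$g_e$values), mean(per$g_e$values), tolerance = 0.1)
  expect_equal(mean(agg$g_i$values), mean(per$g_i$values), tolerance = 0.1)
  # both oscillate at 20 Hz under the preferred grating
  sp <- welch_psd(signal_trace(agg$i_net$values, 1e4), window_s = 0.5)
  expect_equal(sp$freq[which.max(sp$power * (sp$freq > 1))], 20, tolerance = 2)
})

test_that("sampled-field frequency response peaks at the Gabor wavelength", {
  f <- receptor_field(seed = 9)
  fr <- field_frequency_response(f, seq(100, 1000, by = 20))
  expect_equal(fr$wavelength_um[which.max(fr$response)], 300, tolerance = 20)

  # single receptor: flat response across wavelengths
  one <- data.frame(x_um = 0, y_um = 0, polarity = "excitatory")
  fr1 <- field_frequency_response(one)
  expect_equal(max(fr1$response) - min(fr1$response), 0, tolerance = 1e-9)

  # orthogonal orientation: response at 300 um below 10% of the preferred peak
  s <- ifelse(f$receptors$polarity == "excitatory", 1, -1)
  zp <- Mod(sum(s * exp(2i * pi * f$receptors$x_um / 300)))
  zo <- Mod(sum(s * exp(2i * pi * f$receptors$y_um / 300)))
  expect_lt(zo, 0.1 * zp)

  expect_error(field_frequency_response(data.frame(x_um = numeric(0),
                                                   y_um = numeric(0),
                                                   polarity = character(0))),
               "empty")
})
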