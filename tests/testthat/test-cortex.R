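test_that("coupling kernel geometry: centre-surround profile and anisotropy", {
  k <- coupling_kernel(extent = 41, sigma = 4.67, s_major = 1, s_minor = 0.6,
                       phi_k = 0, gain = 1)
  half <- (k$extent - 1) / 2
  centre <- k$weights[half + 1, half + 1]
  expect_gt(centre, 0)

  # radial profile along the major axis has exactly two sign changes:
  # positive centre, one negative annulus, positive decaying tail
  prof <- k$weights[(half + 1):k$extent, half + 1]
  signs <- sign(prof[prof != 0])
  expect_equal(sum(diff(signs) != 0), 2)

  # surround strength attains s_major on the major axis and s_minor on the
  # minor axis: the negative lobes are deeper along the major axis
  expect_lt(min(k$weights[, half + 1]), min(k$weights[half + 1, ]))

  # isotropic kernel is rotation invariant (90 degree rotation is exact on
  # the grid)
  ki <- coupling_kernel(extent = 41, sigma = 4.67, s_major = 0.8,
                        s_minor = 0.8, phi_k = 0, gain = 1)
  expect_equal(ki$weights, t(ki$weights)[, ncol(ki$weights):1],
               tolerance = 1e-12)
  # anisotropic kernel at 90 degrees equals the 0-degree kernel rotated
  k90 <- coupling_kernel(extent = 41, sigma = 4.67, s_major = 1,
                         s_minor = 0.6, phi_k = pi / 2, gain = 1)
  expect_equal(k90$weights, t(k$weights)[, ncol(k$weights):1],
               tolerance = 1e-12)

  expect_error(coupling_kernel(sigma = 0), "sigma")
  expect_error(coupling_kernel(extent = 10), "odd")
})

test_that("kernel principal axis of the inhibitory lobes follows phi_k", {
  k <- coupling_kernel(extent = 41, sigma = 4.67, phi_k = 60 * pi / 180,
                       gain = 1)
  half <- (k$extent - 1) / 2
  neg <- pmax(-k$weights, 0)^2
  X <- matrix(-half:half, k$extent, k$extent)
  Y <- t(X)
  # principal axis of the squared negative lobes
  cxx <- sum(neg * X * X); cyy <- sum(neg * Y * Y); cxy <- sum(neg * X * Y)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) %% pi
  expect_equal(ang * 180 / pi, 60, tolerance = 3)
})

test_that("one Euler step equals the brute-force pairwise double sum", {
  sheet <- tiny_sheet(n = 8, seed = 3)
  k <- coupling_kernel(extent = 5, sigma = 1.2, gain = 2)
  stepped <- step_sheet(sheet, k, dt = 5e-4)
  expected <- sheet$phases +
    5e-4 * (2 * pi * sheet$freqs + brute_coupling(sheet$phases, k))
  expect_equal(stepped$phases, wavedecode:::wrap_phase(expected),
               tolerance = 1e-10)
})

test_that("uncoupled and synchronized limits of the sheet dynamics", {
  sheet <- tiny_sheet(n = 8, seed = 4)
  k0 <- coupling_kernel(extent = 5, sigma = 1.2, gain = 0)
  s <- sheet
  for (i in 1:100) s <- step_sheet(s, k0, dt = 5e-4)
  expect_equal(s$phases,
               wavedecode:::wrap_phase(sheet$phases + 2 * pi * sheet$freqs * 0.05),
               tolerance = 1e-8)

  # identical frequencies, uniform phases: synchronized fixed point
  su <- oscillator_sheet(8, freq_sd_hz = 0, phases = matrix(1.3, 8, 8),
                         freqs = matrix(20, 8, 8))
  k <- coupling_kernel(extent = 5, sigma = 1.2, gain = 5)
  s2 <- su
  for (i in 1:50) s2 <- step_sheet(s2, k, dt = 5e-4)
  expect_equal(max(abs(s2$phases - s2$phases[1, 1])), 0, tolerance = 1e-9)
})

test_that("two-oscillator phase locking matches the scalar ODE oracle", {
  # a kernel coupling each oscillator only to its right neighbour, on a
  # column-periodic pattern with period 2, reduces the sheet to the pair
  # dynamics d(dtheta)/dt = -2 K sin(dtheta)
  n <- 4
  K <- 0.8
  k <- coupling_kernel(extent = 3, sigma = 1, gain = 1)
  k$weights <- matrix(0, 3, 3)
  k$weights[3, 2] <- K  # couple only to the neighbour one row down
  th1 <- 0.3; th2 <- 2.1
  phases <- matrix(rep(c(th1, th2), times = n * n / 2), n, n)  # rows alternate
  sheet <- oscillator_sheet(n, freq_sd_hz = 0, phases = phases,
                            freqs = matrix(20, n, n))
  dt <- 1e-4
  s <- sheet
  for (i in 1:2000) s <- step_sheet(s, k, dt)
  # oracle: Euler on the scalar phase-difference equation
  dth <- th2 - th1
  for (i in 1:2000) dth <- dth - dt * 2 * K * sin(dth)
  measured <- (s$phases[2, 1] - s$phases[1, 1]) %% (2 * pi)
  expect_equal(measured, dth %% (2 * pi), tolerance = 1e-6)
  # positive coupling pulls the pair toward synchrony
  expect_lt(abs(measured), abs(th2 - th1))
})

test_that("mean instantaneous frequency equals the mean intrinsic frequency", {
  sheet <- tiny_sheet(n = 8, seed = 5)
  k <- coupling_kernel(extent = 5, sigma = 1.2, gain = 10)
  stepped <- step_sheet(sheet, k, dt = 5e-4)
  # unwrapped increment
  d <- stepped$phases - sheet$phases
  d <- d - 2 * pi * round((d - 5e-4 * 2 * pi * sheet$freqs) / (2 * pi))
  expect_equal(mean(d) / 5e-4 / (2 * pi), mean(sheet$freqs),
               tolerance = 1e-8)
})

test_that("phase-wrap invariance: shifting all phases by 2*pi changes nothing", {
  sheet <- tiny_sheet(n = 8, seed = 6)
  shifted <- sheet
  shifted$phases <- wavedecode:::wrap_phase(sheet$phases + 2 * pi)
  k <- coupling_kernel(extent = 5, sigma = 1.2, gain = 5)
  a <- step_sheet(sheet, k)
  b <- step_sheet(shifted, k)
  expect_equal(cos(a$phases), cos(b$phases), tolerance = 1e-12)
})

test_that("simulate_cortex is reproducible and agrees with step_sheet", {
  k <- coupling_kernel(extent = 9, sigma = 1.5, gain = 10)
  h1 <- simulate_cortex(n = 16, duration = 0.05, kernel = k, seed = 7,
                        record_phases = TRUE)
  h2 <- simulate_cortex(n = 16, duration = 0.05, kernel = k, seed = 7,
                        record_phases = TRUE)
  expect_identical(h1$lfp$values, h2$lfp$values)
  expect_identical(h1$phases, h2$phases)
  # sample count = duration * fs (+/- 1)
  expect_equal(dim(h1$phases)[3], 50)

  # the compiled stepper matches the pure-R reference path
  sheet <- oscillator_sheet(16, seed = 7)
  s <- sheet
  for (i in 1:20) s <- step_sheet(s, k, dt = 5e-4)
  h <- simulate_cortex(kernel = k, duration = 0.01, sheet = sheet,
                       record_phases = TRUE)
  expect_equal(h$sheet$phases, s$phases, tolerance = 1e-9)

  expect_error(simulate_cortex(n = 16, duration = 0.01,
                               kernel = coupling_kernel(extent = 37)),
               "extent")
})

test_that("LFP definition and degenerate values", {
  h <- make_fixture("plane_wave_history",
                    list(n = 16, wavelength = 8, duration = 0.2))
  # all phases equal at t where the wave phase is 0 everywhere? use direct:
  ph <- array(0, c(16, 16, 2))
  hh <- structure(list(phases = ph, fs = 1000, n = 16, duration = 2e-3),
                  class = "phase_history")
  expect_equal(compute_lfp(hh)$values, c(1, 1))
  expect_equal(compute_lfp(hh, normalize = "sum")$values, c(256, 256))

  # uniformly distributed phases: near-zero mean LFP (CLT bound)
  set.seed(1)
  ph2 <- array(runif(64 * 64 * 3, 0, 2 * pi), c(64, 64, 3))
  hh2 <- structure(list(phases = ph2, fs = 1000, n = 64, duration = 3e-3),
                   class = "phase_history")
  expect_true(all(abs(compute_lfp(hh2)$values) < 3 / sqrt(64 * 64)))

  # plane wave with an integer number of cycles sums to ~0
  expect_lt(max(abs(compute_lfp(h)$values)), 1e-10)
})

test_that("LFP spectrum: known tone, white noise, and error cases", {
  tt <- seq(0, 4, by = 1e-3)
  tone <- signal_trace(sin(2 * pi * 20 * tt), 1000)
  sp <- lfp_spectrum(tone)
  expect_equal(sp$freq[which.max(sp$power)], 20, tolerance = 2)

  set.seed(2)
  wn <- signal_trace(rnorm(30000), 1000)
  spw <- lfp_spectrum(wn)
  expect_lt(max(spw$power) / median(spw$power), 10)

  expect_error(lfp_spectrum(signal_trace(rnorm(100), 1000)), "window")
})

test_that("default cortex run shows beta-band waves aligned with the kernel", {
  k <- coupling_kernel(phi_k = 60 * pi / 180)
  h <- simulate_cortex(n = 64, duration = 6, kernel = k, seed = 11,
                       record_phases = TRUE)
  sp <- lfp_spectrum(signal_trace(h$lfp$values[2001:6000], 1000))
  pk <- sp$freq[which.max(sp$power)]
  expect_gte(pk, 12); expect_lte(pk, 30)

  # time-averaged 2-D spectrum peak along the kernel major axis (+/- one
  # spectral bin; at this grid and wavelength one bin is ~9 degrees)
  A <- 0
  for (s in seq(3000, 6000, by = 50)) {
    f <- cos(h$phases[, , s])
    A <- A + Mod(fft(f - mean(f)))^2
  }
  A[1, 1] <- 0
  ij <- arrayInd(which.max(A), dim(A))
  f1 <- ij[1] - 1; if (f1 > 32) f1 <- f1 - 64
  f2 <- ij[2] - 1; if (f2 > 32) f2 <- f2 - 64
  ang <- (atan2(f2, f1) %% pi) * 180 / pi
  expect_lt(min(abs(ang - 60), abs(ang - 60 + 180), abs(ang - 60 - 180)), 12)

  # heterogeneous frequencies: the LFP amplitude envelope waxes and wanes
  env <- abs(h$lfp$values[2001:6000])
  env <- stats::filter(env, rep(1 / 101, 101), sides = 2)
  env <- env[!is.na(env)]
  expect_gt(stats::sd(env) / mean(env), 0.1)

  # homogeneous frequencies, isotropic strong surround: stationary pattern
  ki <- coupling_kernel(s_major = 1, s_minor = 1)
  hh <- simulate_cortex(n = 64, duration = 4, kernel = ki, freq_sd_hz = 0,
                        seed = 12, record_phases = TRUE)
  R <- apply(exp(1i * hh$phases[, , 2001:4000]), 3, function(m) Mod(mean(m)))
  expect_lt(stats::var(R), 1e-3)
})
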