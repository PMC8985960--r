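# Demodulation, Kasai autocorrelation velocity estimation, cropping.

c_us <- 1540
f0 <- 20e6
fs <- 100e6

mk_rf <- function(values, acq = default_acq) {
  n_fast <- nrow(values)
  t_fast <- 2 * 13e-3 / c_us + (seq_len(n_fast) - 1) / fs
  structure(list(
    values = values,
    depth_axis = c_us * t_fast / 2 * 1e3,
    time_axis = (seq_len(ncol(values)) - 1) / acq$prf * 1e3,
    rf_sampling_rate = fs,
    geometry = default_geom,
    acquisition = acq,
    scatterers = list(positions = numeric(0), amplitudes = numeric(0),
                      seed = 0L),
    motion = NULL
  ), class = "rf_ensemble")
}

mk_iq <- function(values, acq = default_acq, dz = 0.01) {
  structure(list(
    values = values,
    depth_axis = 13 + (seq_len(nrow(values)) - 1) * dz,
    time_axis = (seq_len(ncol(values)) - 1) / acq$prf * 1e3,
    demod_frequency = f0,
    sampling_rate = fs,
    geometry = default_geom,
    acquisition = acq
  ), class = "iq_ensemble")
}

test_that("demodulating a tone at the carrier gives a flat baseband", {
  n <- 600
  t_fast <- (seq_len(n) - 1) / fs
  rf <- mk_rf(matrix(cos(2 * pi * f0 * (t_fast + 2 * 13e-3 / c_us)),
                     n, 4))
  iq <- demodulate(rf)
  mid <- 100:400
  expect_equal(Mod(iq$values[mid, 1]), rep(1, length(mid)),
               tolerance = 1e-3)
  expect_lt(diff(range(Arg(iq$values[mid, 1]))), 1e-4)
})

test_that("baseband magnitude of a pulse matches the Hilbert envelope oracle", {
  n <- 500
  t_fast <- (seq_len(n) - 1) / fs
  tc <- t_fast[260]
  sig_t <- 5e-8
  pulse <- exp(-(t_fast - tc)^2 / (2 * sig_t^2)) *
    cos(2 * pi * f0 * (t_fast - tc))
  rf <- mk_rf(matrix(pulse, n, 2))
  iq <- demodulate(rf, edge_trim = 0L)
  expect_equal(which.max(Mod(iq$values[, 1])), 260, tolerance = 1)
  # independent envelope oracle (discrete Hilbert quadrature)
  expect_equal(which.max(oracle_envelope(pulse)), 260, tolerance = 1)

  zero <- demodulate(mk_rf(matrix(0, n, 2)), edge_trim = 0L)
  expect_equal(max(Mod(zero$values)), 0)
})

test_that("demodulation rejects sub-Nyquist sampling", {
  rf <- mk_rf(matrix(0, 100, 2))
  rf$rf_sampling_rate <- 30e6
  expect_error(demodulate(rf), class = "sweimm_config_error")
})

test_that("Kasai estimator inverts the phase-displacement identity", {
  # constant inter-frame phase advance of 0.1632 rad at 20 MHz / 1540 m/s
  # corresponds to 1.0 um of motion toward the transducer per frame
  nz <- 50; nf <- 20
  phase <- outer(runif(nz, -pi, pi), 0.1632 * (0:(nf - 1)), `+`)
  iq <- mk_iq(matrix(exp(1i * phase), nz, nf))
  vf <- autocorrelation_velocity(iq, output_dz_mm = NULL)
  delta_um <- vf$values / default_acq$prf * 1e3
  expect_equal(mean(delta_um), c_us * 0.1632 / (4 * pi * f0) * 1e6,
               tolerance = 1e-9)
  expect_equal(mean(delta_um), 1.0, tolerance = 1e-4)
  expect_true(all(delta_um > 0))  # toward the transducer is positive
  expect_false(vf$flags$any_aliased)
  expect_equal(ncol(vf$values), nf - 1L)
})

test_that("sub-lambda/8 displacements are recovered within 1%", {
  lambda_um <- c_us / f0 * 1e6  # 77 um
  for (delta_um in c(2, 5, 9)) {
    phi <- 4 * pi * f0 * delta_um * 1e-6 / c_us
    iq <- mk_iq(matrix(exp(1i * outer(rep(0, 40), phi * (0:14), `+`)), 40))
    vf <- autocorrelation_velocity(iq, output_dz_mm = NULL)
    rec <- mean(vf$values) / default_acq$prf * 1e3
    expect_lt(abs(rec - delta_um) / delta_um, 0.01)
    expect_lt(delta_um, lambda_um / 8)
  }
})

test_that("static ensembles give zero velocity; pi phase steps are flagged", {
  iq <- mk_iq(matrix(complex(modulus = 1, argument = 0.3), 30, 10))
  vf <- autocorrelation_velocity(iq, output_dz_mm = NULL)
  expect_equal(max(abs(vf$values)), 0)

  alias <- mk_iq(matrix(exp(1i * pi * outer(rep(1, 30), 0:9)), 30, 10))
  vfa <- autocorrelation_velocity(alias, output_dz_mm = NULL)
  expect_true(vfa$flags$any_aliased)
})

test_that("axial kernel averaging reduces velocity variance under noise", {
  # uniform motion observed through additive white noise: longer kernels
  # average more independent noise realizations around the signal phasor
  set.seed(3)
  nz <- 400; nf <- 12
  phi <- 0.4
  signal <- matrix(exp(1i * outer(rep(0, nz), phi * (0:(nf - 1)), `+`)),
                   nz, nf)
  noise <- matrix(complex(real = rnorm(nz * nf), imaginary = rnorm(nz * nf)),
                  nz, nf)
  iqv <- signal + 0.7 * noise
  vars <- vapply(c(0.005, 0.1, 0.3), function(kl) {
    var(as.numeric(
      autocorrelation_velocity(mk_iq(iqv), kernel_length_mm = kl,
                               output_dz_mm = NULL)$values))
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("the RF chain reproduces the on-axis motion it was driven by", {
  tr <- clean_truth(1.0)
  rf <- simulate_rf_ensemble(default_geom, short_acq, tr,
                             n_scatterers = 1200)
  vf <- autocorrelation_velocity(demodulate(rf))
  est_trace <- focal_trace(vf, default_geom, 0.5)
  true_trace <- focal_trace(rf$motion, default_geom, 0.5)
  n <- min(length(est_trace$values), length(true_trace$values))
  expect_gt(cor(est_trace$values[1:n], true_trace$values[1:n]), 0.95)
})

test_that("cropping retains the requested depth band and time window", {
  vf <- sim_clean_field(1.0)
  cr <- crop_around_focus(vf, depth_halfwidth = 2, time_window = 40)
  expect_gte(min(cr$depth_axis), 12)
  expect_lte(max(cr$depth_axis), 16)
  expect_lte(length(cr$time_axis), 200L)  # 40 ms at 5 kHz
  expect_lte(max(cr$time_axis), 40)

  expect_warning(crop_around_focus(vf, depth_halfwidth = 50,
                                   time_window = 1e5),
                 class = "sweimm_crop_warning")
  far_geom <- fixture_geometry(focal_length = 40)
  vf_far <- velocity_field(vf$values, vf$depth_axis, vf$time_axis,
                           far_geom, default_acq)
  expect_error(crop_around_focus(vf_far), class = "sweimm_domain_error")
})
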