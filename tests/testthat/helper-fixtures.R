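# Shared fixtures built in code. Simulations default to noise-free so
# expected values are deterministic; tests that need noise say so.

default_geom <- fixture_geometry()
default_acq <- acquisition_config()
# shorter recording for tests whose speeds keep all arrivals under 40 ms
short_acq <- acquisition_config(n_frames = 200)

clean_truth <- function(sws, ...) {
  simulation_truth(true_sws = sws, noise_sigma = 0, ...)
}

sim_clean_field <- function(sws, acq = default_acq, ...) {
  simulate_velocity_field(default_geom, acq, clean_truth(sws, ...))
}

# hand-built wavefront candidate for assignment tests
mk_cand <- function(t, amp = 1, prom = 1) {
  structure(list(peak_time = t, window = c(t - 1, t + 1),
                 centroid_time = t, peak_amplitude = amp,
                 prominence = prom),
            class = "wavefront_candidate")
}

# hand-built velocity field on a regular grid
mk_field <- function(values, z = seq(10, 18, by = 0.05),
                     tt = (seq_len(ncol(values)) - 1) / 5,
                     geom = default_geom, acq = default_acq) {
  velocity_field(values, z, tt, geom, acq)
}

# brute-force Hilbert envelope oracle via explicit convolution quadrature
# (independent of the package's FFT analytic-signal helper)
oracle_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (m in seq_len(n)) {
      d <- k - m
      if (d %% 2 != 0) s <- s + 2 / (pi * d) * x[m]
    }
    h[k] <- s
  }
  sqrt(x^2 + h^2)
}
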