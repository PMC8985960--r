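# Analytic-signal envelope along a sampled series.
#
# The one-sided spectrum construction: zero the negative frequencies of the
# DFT, double the positive ones, keep DC (and Nyquist for even n) single.
# No installed package in this stack exposes a Hilbert transform, so this
# standard construction is implemented here.

analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(as.complex(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

envelope <- function(x) Mod(analytic_signal(x))

# Envelope used for wave-packet detection and centroid timing on velocity
# traces. Shear packets are low-pass (at most ~1 cycle), so the rectified
# amplitude is the appropriate envelope: the analytic-signal magnitude of a
# low-pass packet carries slowly decaying 1/t Hilbert tails that leak every
# packet's energy into its neighbors' windows and bias arrival times.
amp_envelope <- function(x) abs(x)

# Row-wise envelope of a depth x slow-time matrix (envelope along time).
envelope_rows <- function(values) {
  abs(values)
}

# Short moving-average smoother used only for peak detection, never for
# centroid timing (centroids use the raw squared envelope).
smooth_ma <- function(x, k = 5L) {
  if (k <= 1L || length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L)) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  expr
}
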