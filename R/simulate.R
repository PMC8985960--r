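#' Ground-truth parameters for the wavefield simulator
#'
#' Collects everything the forward model needs beyond fixture geometry and
#' acquisition settings: the true shear-wave speed, the shape and relative
#' amplitudes of the shear packets, geometric spreading, noise level and
#' the RNG seed. Identical parameters and seed give bit-identical output.
#'
#' @param true_sws True shear-wave speed, m/s.
#' @param packet_width Temporal FWHM of the shear packet, ms. The default
#'   makes the spatial wavelength about 2 mm at 1.5 m/s.
#' @param reflection_coefficients Length-4 amplitudes in (0, 1] for the four
#'   side-boundary reflections (gel/agarose-buffer interface).
#' @param top_bottom_amplitude Amplitude of the top/bottom-face reflections
#'   relative to the direct packet (which has amplitude 1). Kept small by
#'   default: a shear wave propagating along the beam axis is transversely
#'   polarized, so its on-axis axial-velocity signature is weak even though
#'   the reflection is clearly visible as a sloped band off the locus.
#' @param spreading_exponent Geometric-spreading exponent: side-packet
#'   amplitude falls as path^-exponent (0.5 = cylindrical).
#' @param noise_sigma Additive white-noise standard deviation as a fraction
#'   of the direct-packet peak.
#' @param rng_seed Integer seed for all simulator randomness.
#' @param sample_height Sample height in mm; sets the depth of the top face
#'   (bottom face sits at the container bottom).
#' @param broadening_per_mm Optional viscous-like dispersion: extra packet
#'   FWHM (ms) per mm of propagation path. 0 = nonviscous.
#' @param second_bounce If `TRUE`, add doubly reflected side packets
#'   (amplitude r_i^2, path 4 d_i) emulating late reverberation.
#' @param peak_displacement_um Peak inter-frame scatterer displacement in
#'   micrometers used by [simulate_rf_ensemble()] to scale motion.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(true_sws = 1.0,
                             packet_width = 1.33,
                             reflection_coefficients = rep(0.6, 4),
                             top_bottom_amplitude = 0.15,
                             spreading_exponent = 0.5,
                             noise_sigma = 0.05,
                             rng_seed = 1L,
                             sample_height = 5.1,
                             broadening_per_mm = 0,
                             second_bounce = FALSE,
                             peak_displacement_um = 1.0) {
  if (!is.numeric(true_sws) || length(true_sws) != 1L || true_sws <= 0)
    sweimm_error("sweimm_domain_error", "true_sws must be a positive speed")
  if (packet_width <= 0)
    sweimm_error("sweimm_domain_error", "packet_width must be positive")
  if (length(reflection_coefficients) != 4L ||
      any(reflection_coefficients < 0) || any(reflection_coefficients > 1))
    sweimm_error("sweimm_domain_error",
                 "reflection_coefficients must be 4 values in [0, 1]")
  if (noise_sigma < 0)
    sweimm_error("sweimm_domain_error", "noise_sigma must be >= 0")
  structure(list(
    true_sws = true_sws,
    packet_width = packet_width,
    reflection_coefficients = as.numeric(reflection_coefficients),
    top_bottom_amplitude = top_bottom_amplitude,
    spreading_exponent = spreading_exponent,
    noise_sigma = noise_sigma,
    rng_seed = as.integer(rng_seed),
    sample_height = sample_height,
    broadening_per_mm = broadening_per_mm,
    second_bounce = isTRUE(second_bounce),
    peak_displacement_um = peak_displacement_um
  ), class = "simulation_truth")
}

#' Construct an axial velocity field object
#'
#' Container for an M-mode axial particle-velocity map v(z, t): depth
#' samples along rows, slow-time frames along columns.
#'
#' @param values Numeric matrix, depth x slow time.
#' @param depth_axis Strictly increasing depths, mm from the transducer face.
#' @param time_axis Strictly increasing slow times, ms from the push end.
#' @param geometry A [fixture_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param flags Optional named list of quality flags.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(values, depth_axis, time_axis, geometry,
                           acquisition, flags = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(depth_axis) || ncol(values) != length(time_axis))
    sweimm_error("sweimm_domain_error",
                 "values must be length(depth_axis) x length(time_axis)")
  if (any(diff(depth_axis) <= 0) || any(diff(time_axis) <= 0))
    sweimm_error("sweimm_domain_error", "axes must be strictly increasing")
  if (!all(is.finite(values)))
    sweimm_error("sweimm_domain_error", "velocity values must be finite")
  structure(list(
    values = values,
    depth_axis = as.numeric(depth_axis),
    time_axis = as.numeric(time_axis),
    geometry = geometry,
    acquisition = acquisition,
    flags = flags
  ), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d depths x %d frames\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  depth %.2f..%.2f mm, time %.2f..%.2f ms\n",
              min(x$depth_axis), max(x$depth_axis),
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

# Gaussian packet evaluated at times t (ms) centered on t0 with FWHM w.
gaussian_packet <- function(t, t0, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(t - t0)^2 / (2 * sigma^2))
}

#' Simulate an axial velocity field by the image-source method
#'
#' Builds the on-axis (M-mode) velocity map a single-element system
#' observes after an ARF push at the focus:
#'
#' * a direct packet whose depth-time locus is `t = |z - z_f| / c`,
#' * top- and bottom-face reflections appearing as sloped bands
#'   (down-going and up-going respectively),
#' * four side-boundary packets constructed from lateral image sources at
#'   distance `2 d_i`, arriving on-axis at
#'   `t_i(z) = sqrt((2 d_i)^2 + (z - z_f)^2) / c`; at the focal depth each
#'   peaks at exactly `2 d_i / c`,
#' * optional doubly reflected side packets and additive white noise.
#'
#' @param geometry A [fixture_geometry()].
#' @param acquisition An [acquisition_config()].
#' @param truth A [simulation_truth()].
#' @param depth_range Length-2 depth window in mm (default focus +/- 4 mm).
#' @param dz Depth sampling interval, mm.
#' @return A [velocity_field()].
#' @export
simulate_velocity_field <- function(geometry, acquisition, truth,
                                    depth_range = NULL, dz = 0.05) {
  stopifnot(inherits(geometry, "fixture_geometry"),
            inherits(acquisition, "acquisition_config"),
            inherits(truth, "simulation_truth"))
  zf <- geometry$focal_length
  if (is.null(depth_range)) depth_range <- zf + c(-4, 4)
  z <- seq(depth_range[1], depth_range[2], by = dz)
  tt <- (seq_len(acquisition$n_frames) - 1L) / acquisition$prf * 1e3  # ms
  c0 <- truth$true_sws  # mm/ms
  w0 <- truth$packet_width

  z_bottom <- geometry$face_to_container_bottom
  z_top <- z_bottom - truth$sample_height

  field <- matrix(0, nrow = length(z), ncol = length(tt))
  add_packet <- function(arrival, amplitude, fwhm) {
    # arrival: per-depth arrival time (ms); amplitude scalar or per-depth
    field <<- field + amplitude *
      gaussian_packet(matrix(tt, length(z), length(tt), byrow = TRUE),
                      matrix(arrival, length(z), length(tt)),
                      matrix(fwhm, length(z), length(tt)))
  }

  # direct push packet, diverging axially from the focus
  add_packet(abs(z - zf) / c0, 1.0, w0 + truth$broadening_per_mm * abs(z - zf))

  # top-face reflection (down-going) and bottom-face reflection (up-going)
  if (truth$top_bottom_amplitude > 0) {
    path_top <- (zf - z_top) + (z - z_top)
    add_packet(path_top / c0, truth$top_bottom_amplitude,
               w0 + truth$broadening_per_mm * pmax(path_top, 0))
    path_bot <- (z_bottom - zf) + (z_bottom - z)
    add_packet(path_bot / c0, truth$top_bottom_amplitude,
               w0 + truth$broadening_per_mm * pmax(path_bot, 0))
  }

  # four side-boundary reflections via lateral image sources
  d2 <- two_way_paths(geometry)
  for (i in seq_len(4)) {
    r <- truth$reflection_coefficients[i]
    if (r <= 0) next
    path <- sqrt(d2[i]^2 + (z - zf)^2)
    add_packet(path / c0, r / d2[i]^truth$spreading_exponent,
               w0 + truth$broadening_per_mm * path)
    if (truth$second_bounce) {
      path2 <- sqrt((2 * d2[i])^2 + (z - zf)^2)
      add_packet(path2 / c0, r^2 / (2 * d2[i])^truth$spreading_exponent,
                 w0 + truth$broadening_per_mm * path2)
    }
  }

  # overlap diagnostics on the on-axis arrival schedule (direct + 4 sides)
  on_axis <- sort(c(0, d2 / c0))
  flags <- list(overlap = FALSE)
  if (any(diff(on_axis) < w0)) {
    flags$overlap <- TRUE
    sweimm_warning("sweimm_overlap_warning",
                   "successive on-axis arrivals closer than the packet width (%.2f ms); wavefronts may not separate",
                   w0)
  }

  if (truth$noise_sigma > 0) {
    field <- field + with_seed(truth$rng_seed,
      matrix(stats::rnorm(length(field), sd = truth$noise_sigma),
             nrow = nrow(field)))
  }

  velocity_field(field, z, tt, geometry, acquisition, flags = flags)
}

#' Simulate a speckle RF A-line ensemble
#'
#' Draws sub-resolution point scatterers uniformly over the imaged depth
#' window, synthesizes each frame's A-line as the sum of Gaussian-modulated
#' sinusoid echoes (50% fractional bandwidth), and advances scatterer
#' depths between frames by integrating the simulated axial velocity at
#' each scatterer's location. Electronic noise is added with standard
#' deviation `truth$noise_sigma` times the RMS of the noiseless RF.
#'
#' Motion amplitude is scaled so the largest inter-frame displacement is
#' `truth$peak_displacement_um` micrometers; displacements exceeding an
#' eighth of the pulse-echo wavelength raise an aliasing warning.
#'
#' @inheritParams simulate_velocity_field
#' @param n_scatterers Number of point scatterers; at least ~50 per axial
#'   resolution cell is recommended for fully developed speckle.
#' @param depth_range Length-2 depth window in mm (default focus +/- 3 mm,
#'   wide enough that the slope fit retains depth aperture after the
#'   demodulation edge trim).
#' @return An object of class `rf_ensemble` with fields `values`
#'   (fast-time samples x frames), `depth_axis` (mm), `time_axis` (frame
#'   times, ms), `rf_sampling_rate`, `geometry`, `acquisition`,
#'   `scatterers` (positions, amplitudes, seed) and `motion` (the
#'   underlying [velocity_field()]).
#' @export
simulate_rf_ensemble <- function(geometry, acquisition, truth,
                                 n_scatterers = 1500,
                                 depth_range = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  zf <- geometry$focal_length
  if (is.null(depth_range)) depth_range <- zf + c(-3, 3)
  c_us <- acquisition$compressional_sound_speed          # m/s
  fs <- acquisition$rf_sampling_rate
  f0 <- acquisition$center_frequency
  lambda_um <- c_us / f0 * 1e6

  # fast-time grid covering the two-way travel to the depth window
  t_start <- 2 * depth_range[1] * 1e-3 / c_us
  t_end <- 2 * depth_range[2] * 1e-3 / c_us
  t_fast <- seq(t_start, t_end, by = 1 / fs)
  depth_axis <- c_us * t_fast / 2 * 1e3                  # mm

  # noiseless motion field driving the scatterers
  motion_truth <- truth
  motion_truth$noise_sigma <- 0
  vf <- simulate_velocity_field(geometry, acquisition, motion_truth,
                                depth_range = depth_range)
  vmax <- max(abs(vf$values))
  disp_um <- if (vmax > 0) vf$values / vmax * truth$peak_displacement_um
             else vf$values
  if (max(abs(disp_um)) > lambda_um / 8)
    sweimm_warning("sweimm_aliasing_warning",
                   "per-frame displacement %.2f um exceeds lambda/8 = %.2f um; Doppler phase will alias",
                   max(abs(disp_um)), lambda_um / 8)

  scat <- with_seed(truth$rng_seed, list(
    positions = stats::runif(n_scatterers, depth_range[1], depth_range[2]),
    amplitudes = stats::rnorm(n_scatterers)
  ))
  scat$seed <- truth$rng_seed

  # cumulative depth trajectory per scatterer: positive velocity is motion
  # toward the transducer (depth decreases)
  row_of <- pmin(pmax(round((scat$positions - vf$depth_axis[1]) /
                              (vf$depth_axis[2] - vf$depth_axis[1])) + 1L, 1L),
                 length(vf$depth_axis))
  disp_mm <- disp_um[row_of, , drop = FALSE] * 1e-3
  traj <- matrix(scat$positions, n_scatterers, acquisition$n_frames) -
    cbind(0, t(apply(disp_mm[, -ncol(disp_mm), drop = FALSE], 1L, cumsum)))

  # pulse: Gaussian-modulated sinusoid, 50% fractional bandwidth (envelope
  # spectrum FWHM = 0.5 * f0)
  sigma_f <- 0.5 * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  halfwin <- ceiling(4 * sigma_t * fs)
  offs <- -halfwin:halfwin
  n_fast <- length(t_fast)

  values <- matrix(0, n_fast, acquisition$n_frames)
  for (n in seq_len(acquisition$n_frames)) {
    tau <- 2 * traj[, n] * 1e-3 / c_us
    ctr <- round((tau - t_start) * fs) + 1L
    idx <- outer(ctr, offs, `+`)
    tmat <- t_start + (idx - 1L) / fs
    dt <- tmat - tau
    val <- scat$amplitudes * exp(-dt^2 / (2 * sigma_t^2)) * cospi(2 * f0 * dt)
    keep <- idx >= 1L & idx <= n_fast
    acc <- rowsum(val[keep], idx[keep])
    aline <- numeric(n_fast)
    aline[as.integer(rownames(acc))] <- acc[, 1L]
    values[, n] <- aline
  }

  if (truth$noise_sigma > 0) {
    sd_n <- truth$noise_sigma * stats::sd(as.numeric(values))
    values <- values + with_seed(truth$rng_seed + 1L,
      matrix(stats::rnorm(length(values), sd = sd_n), nrow = n_fast))
  }

  structure(list(
    values = values,
    depth_axis = depth_axis,
    time_axis = (seq_len(acquisition$n_frames) - 1L) / acquisition$prf * 1e3,
    rf_sampling_rate = fs,
    geometry = geometry,
    acquisition = acquisition,
    scatterers = scat,
    motion = vf
  ), class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble> %d fast-time samples x %d frames (fs = %g MHz)\n",
              nrow(x$values), ncol(x$values), x$rf_sampling_rate / 1e6))
  invisible(x)
}

#' Simulate a longitudinal series of velocity fields
#'
#' Emulates repeated nondestructive measurements of the same sample over
#' days of culture: one independently seeded field per time point, each
#' with its own true SWS (e.g. a stiffness trajectory during matrix
#' remodeling). Seeds derive deterministically from the base seed.
#'
#' @param geometry,acquisition Fixture and acquisition settings.
#' @param base_truth A [simulation_truth()] supplying all parameters other
#'   than the per-time-point speed and seed.
#' @param sws_trajectory Named numeric vector of true speeds (m/s), names
#'   are time-point labels; or an unnamed numeric vector.
#' @return Named list of [velocity_field()] objects, one per time point.
#' @export
simulate_longitudinal_series <- function(geometry, acquisition, base_truth,
                                         sws_trajectory) {
  if (length(sws_trajectory) == 0)
    sweimm_error("sweimm_domain_error", "sws_trajectory must be non-empty")
  if (any(sws_trajectory <= 0))
    sweimm_error("sweimm_domain_error", "all trajectory speeds must be > 0")
  labels <- names(sws_trajectory)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_along(sws_trajectory))
  out <- vector("list", length(sws_trajectory))
  names(out) <- labels
  for (i in seq_along(sws_trajectory)) {
    tr <- base_truth
    tr$true_sws <- as.numeric(sws_trajectory[[i]])
    tr$rng_seed <- base_truth$rng_seed + i
    out[[i]] <- simulate_velocity_field(geometry, acquisition, tr)
  }
  out
}
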