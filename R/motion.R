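#' IQ-demodulate an RF ensemble
#'
#' Mixes each A-line down by the transducer center frequency and low-pass
#' filters the product (4th-order Butterworth at 0.75 x center frequency,
#' applied forward-backward for zero phase). The magnitude of the complex
#' baseband equals the RF envelope within filter ripple.
#'
#' @param rf An `rf_ensemble`.
#' @param decimation Integer keep-every-k fast-time decimation applied
#'   after filtering (1 = none).
#' @param edge_trim Number of fast-time samples dropped from each end of
#'   the depth axis after filtering: even the zero-phase filter rings at
#'   the window edges, and the ringing would otherwise masquerade as
#'   large spurious velocities at the extreme depths.
#' @return An object of class `iq_ensemble`: complex `values` (depth x
#'   frames), `depth_axis` (mm), `time_axis` (ms), `demod_frequency` (Hz),
#'   `sampling_rate` (Hz, after decimation), plus geometry/acquisition.
#' @export
demodulate <- function(rf, decimation = 1L, edge_trim = 40L) {
  stopifnot(inherits(rf, "rf_ensemble"))
  acq <- rf$acquisition
  f0 <- acq$center_frequency
  fs <- rf$rf_sampling_rate
  if (fs <= 2 * f0)
    sweimm_error("sweimm_config_error",
                 "RF sampling rate %g Hz violates Nyquist for f0 = %g Hz",
                 fs, f0)
  n_fast <- nrow(rf$values)
  t_fast <- 2 * rf$depth_axis * 1e-3 / acq$compressional_sound_speed
  mixer <- exp(-2i * pi * f0 * t_fast)
  bb <- rf$values * mixer  # recycles mixer down each column

  # zero-phase low pass; factor 2 restores the analytic-envelope amplitude
  bf <- signal::butter(4, min(0.75 * f0 / (fs / 2), 0.99))
  filt <- function(col) signal::filtfilt(bf, col)
  iq <- matrix(complex(real = apply(Re(bb), 2L, filt),
                       imaginary = apply(Im(bb), 2L, filt)),
               nrow = n_fast) * 2

  first <- min(edge_trim + 1L, n_fast)
  last <- max(n_fast - edge_trim, first)
  keep <- seq(first, last, by = as.integer(decimation))
  structure(list(
    values = iq[keep, , drop = FALSE],
    depth_axis = rf$depth_axis[keep],
    time_axis = rf$time_axis,
    demod_frequency = f0,
    sampling_rate = fs / decimation,
    geometry = rf$geometry,
    acquisition = acq
  ), class = "iq_ensemble")
}

#' @export
print.iq_ensemble <- function(x, ...) {
  cat(sprintf("<iq_ensemble> %d depths x %d frames (demod %g MHz)\n",
              nrow(x$values), ncol(x$values), x$demod_frequency / 1e6))
  invisible(x)
}

#' Lag-one autocorrelation (Kasai) axial velocity estimation
#'
#' For every depth sample and frame pair, the lag-one autocorrelation
#' `R(z, n) = conj(IQ(z, n)) * IQ(z, n + 1)` is averaged over a short
#' axial kernel; the inter-frame displacement is
#' `delta = c * arg(R) / (4 pi f0)` and velocity is `delta * PRF`.
#' Motion toward the transducer gives positive velocity. Phase steps at
#' +/- pi are aliased and flagged per sample, never unwrapped.
#'
#' @param iq An `iq_ensemble` from [demodulate()].
#' @param acquisition An [acquisition_config()]; defaults to the one
#'   carried by `iq`.
#' @param kernel_length_mm Axial averaging kernel length in mm; default
#'   1.5 pulse-echo wavelengths.
#' @param output_dz_mm Target depth sampling of the output field; rows of
#'   the RF-rate estimate are redundant after kernel averaging, so the
#'   field is thinned to approximately this spacing (`NULL` keeps the RF
#'   grid).
#' @return A [velocity_field()] with `n_frames - 1` slow-time samples
#'   (units mm/s); `$flags$aliased` holds the per-sample logical matrix.
#' @export
autocorrelation_velocity <- function(iq, acquisition = iq$acquisition,
                                     kernel_length_mm = NULL,
                                     output_dz_mm = 0.05) {
  stopifnot(inherits(iq, "iq_ensemble"))
  n_frames <- ncol(iq$values)
  if (n_frames < 2)
    sweimm_error("sweimm_domain_error", "need at least 2 frames")
  f0 <- iq$demod_frequency
  c_us <- acquisition$compressional_sound_speed
  lambda_mm <- c_us / f0 * 1e3
  if (is.null(kernel_length_mm)) kernel_length_mm <- 1.5 * lambda_mm

  R <- Conj(iq$values[, -n_frames, drop = FALSE]) *
    iq$values[, -1L, drop = FALSE]

  dz <- if (nrow(R) > 1) iq$depth_axis[2] - iq$depth_axis[1] else kernel_length_mm
  k <- max(1L, round(kernel_length_mm / dz))
  if (k > 1L && nrow(R) >= k) {
    kern <- rep(1, k)
    smooth_col <- function(col) {
      s <- stats::filter(col, kern, sides = 2L)
      s[is.na(s)] <- col[is.na(s)]
      as.numeric(s)
    }
    R <- matrix(complex(real = apply(Re(R), 2L, smooth_col),
                        imaginary = apply(Im(R), 2L, smooth_col)),
                nrow = nrow(R))
  }

  phase <- Arg(R)
  aliased <- abs(phase) >= pi * (1 - 1e-9)
  delta_mm <- c_us * 1e3 * phase / (4 * pi * f0)   # mm per frame interval
  vel <- delta_mm * acquisition$prf                # mm/s

  depth <- iq$depth_axis
  if (!is.null(output_dz_mm) && nrow(vel) > 2) {
    step <- max(1L, round(output_dz_mm / dz))
    keep <- seq(1L, nrow(vel), by = step)
    vel <- vel[keep, , drop = FALSE]
    aliased <- aliased[keep, , drop = FALSE]
    depth <- depth[keep]
  }

  velocity_field(vel, depth, iq$time_axis[-n_frames],
                 iq$geometry, acquisition,
                 flags = list(aliased = aliased,
                              any_aliased = any(aliased)))
}

#' Crop a velocity field around the ultrasound focus
#'
#' Removes depths away from the focus (coupling-medium noise) and late
#' slow times (reverberation), without resampling.
#'
#' @param field A [velocity_field()].
#' @param depth_halfwidth Half-width of the retained depth band, mm.
#' @param time_window Retained slow-time window `[0, time_window]`, ms.
#' @return The cropped [velocity_field()].
#' @export
crop_around_focus <- function(field, depth_halfwidth = 2, time_window = 40) {
  stopifnot(inherits(field, "velocity_field"))
  zf <- field$geometry$focal_length
  if (zf < min(field$depth_axis) || zf > max(field$depth_axis))
    sweimm_error("sweimm_domain_error",
                 "focus depth %.2f mm outside field depth axis", zf)
  keep_z <- abs(field$depth_axis - zf) <= depth_halfwidth
  # half-open window: 40 ms at 5 kHz keeps exactly 200 slow-time samples
  keep_t <- field$time_axis >= 0 & field$time_axis < time_window
  if (!any(keep_z) || !any(keep_t))
    sweimm_error("sweimm_domain_error", "empty crop")
  if (all(keep_z) && all(keep_t)) {
    sweimm_warning("sweimm_crop_warning",
                   "crop window contains the whole field; returning it unchanged")
    return(field)
  }
  velocity_field(field$values[keep_z, keep_t, drop = FALSE],
                 field$depth_axis[keep_z], field$time_axis[keep_t],
                 field$geometry, field$acquisition, flags = field$flags)
}
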