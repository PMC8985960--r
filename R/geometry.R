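#' Fixture geometry of the transducer/sample assembly
#'
#' Describes the measurement fixture: a focused single-element transducer
#' whose focal point sits inside an approximately cubic hydrogel sample, at
#' known one-way lateral distances from the four side boundaries. The
#' staggered distances are what make the four boundary reflections arrive
#' at distinct times and therefore separable.
#'
#' Internal unit convention: distances in mm, times in ms, so speeds come
#' out directly in m/s (1 mm/ms = 1 m/s).
#'
#' @param one_way_distances Numeric length-4, strictly ascending, positive.
#'   One-way focal-point-to-boundary distances in mm.
#' @param focal_length Transducer focal length in mm.
#' @param face_to_container_bottom Distance from the transducer face to the
#'   bottom of the sample container, mm.
#' @param sample_width,sample_length Lateral sample dimensions, mm.
#' @return An object of class `fixture_geometry`.
#' @examples
#' geom <- fixture_geometry()
#' two_way_paths(geom)
#' @export
fixture_geometry <- function(one_way_distances = c(3.0, 6.2, 9.2, 12.0),
                             focal_length = 14.0,
                             face_to_container_bottom = 15.8,
                             sample_width = 15.0,
                             sample_length = 15.4) {
  one_way_distances <- as.numeric(one_way_distances)
  if (length(one_way_distances) != 4L)
    sweimm_error("sweimm_invalid_geometry",
                 "exactly 4 one-way distances required, got %d",
                 length(one_way_distances))
  if (any(!is.finite(one_way_distances)) || any(one_way_distances <= 0))
    sweimm_error("sweimm_invalid_geometry",
                 "one-way distances must be finite and strictly positive")
  if (any(diff(one_way_distances) <= 0))
    sweimm_error("sweimm_invalid_geometry",
                 "one-way distances must be strictly ascending")
  for (v in list(focal_length, face_to_container_bottom,
                 sample_width, sample_length))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      sweimm_error("sweimm_invalid_geometry",
                   "scalar geometry fields must be positive numbers")
  structure(list(
    one_way_distances = one_way_distances,
    focal_length = focal_length,
    face_to_container_bottom = face_to_container_bottom,
    sample_width = sample_width,
    sample_length = sample_length
  ), class = "fixture_geometry")
}

#' @export
print.fixture_geometry <- function(x, ...) {
  cat("<fixture_geometry>\n")
  cat("  one-way boundary distances:",
      paste(format(x$one_way_distances), collapse = ", "), "mm\n")
  cat("  focal length:", x$focal_length, "mm;",
      "face-to-bottom:", x$face_to_container_bottom, "mm\n")
  cat("  sample:", x$sample_width, "x", x$sample_length, "mm\n")
  invisible(x)
}

#' Acquisition parameters of the pulse-echo tracking sequence
#'
#' @param center_frequency Transducer center frequency, Hz.
#' @param prf Pulse repetition frequency of the tracking A-lines, Hz.
#' @param n_frames Number of tracking A-lines (slow-time frames).
#' @param rf_sampling_rate Fast-time RF sampling rate, Hz.
#' @param push_cycles Number of sinusoid cycles in the ARF push.
#' @param push_duration Push duration in seconds; must agree with
#'   `push_cycles / center_frequency` within 5%.
#' @param compressional_sound_speed Speed of sound used for the pulse-echo
#'   depth mapping, m/s.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(center_frequency = 20e6,
                               prf = 5000,
                               n_frames = 400,
                               rf_sampling_rate = 100e6,
                               push_cycles = 2000,
                               push_duration = 1e-4,
                               compressional_sound_speed = 1540) {
  if (prf <= 0)
    sweimm_error("sweimm_invalid_acquisition", "prf must be positive")
  if (n_frames < 2)
    sweimm_error("sweimm_invalid_acquisition", "n_frames must be >= 2")
  if (rf_sampling_rate <= 2 * center_frequency)
    sweimm_error("sweimm_invalid_acquisition",
                 "rf_sampling_rate must exceed 2 x center_frequency")
  nominal <- push_cycles / center_frequency
  if (abs(push_duration - nominal) > 0.05 * nominal)
    sweimm_error("sweimm_invalid_acquisition",
                 "push_duration (%g s) disagrees with push_cycles/center_frequency (%g s) by more than 5%%",
                 push_duration, nominal)
  structure(list(
    center_frequency = center_frequency,
    prf = prf,
    n_frames = as.integer(n_frames),
    rf_sampling_rate = rf_sampling_rate,
    push_cycles = push_cycles,
    push_duration = push_duration,
    compressional_sound_speed = compressional_sound_speed
  ), class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n")
  cat(sprintf("  f0 = %g MHz, fs = %g MHz, PRF = %g kHz, %d frames\n",
              x$center_frequency / 1e6, x$rf_sampling_rate / 1e6,
              x$prf / 1e3, x$n_frames))
  cat(sprintf("  push: %g cycles (%g ms); c = %g m/s\n",
              x$push_cycles, x$push_duration * 1e3,
              x$compressional_sound_speed))
  invisible(x)
}

#' Two-way reflected-path lengths
#'
#' Each shear wave travels from the focus to a side boundary and back, so
#' the path length for boundary i is twice the one-way distance.
#'
#' @param geometry A [fixture_geometry()].
#' @return Numeric length-4 vector of two-way path lengths in mm, ascending.
#' @export
two_way_paths <- function(geometry) {
  stopifnot(inherits(geometry, "fixture_geometry"))
  2 * geometry$one_way_distances
}

#' Predicted arrival times of the four boundary reflections
#'
#' For an assumed shear-wave speed, each reflection is expected back at the
#' focus at t_i = (2 d_i) / sws. Used to seed the wavefront search.
#'
#' @param geometry A [fixture_geometry()].
#' @param sws Assumed shear-wave speed in m/s; must be positive.
#' @return Numeric length-4 vector of arrival times in ms, ascending.
#' @export
predict_arrival_times <- function(geometry, sws) {
  if (!is.numeric(sws) || length(sws) != 1L || !is.finite(sws) || sws <= 0)
    sweimm_error("sweimm_domain_error",
                 "sws must be a single positive speed in m/s")
  two_way_paths(geometry) / sws
}

#' Time-of-flight shear-wave speed from four arrival times
#'
#' The per-path speed for boundary i is the two-way distance over the
#' arrival time, s_i = (2 d_i)/t_i; the reported SWS is the arithmetic mean
#' of the four s_i (an average of ratios, not total distance over total
#' time). Averaging over four independent paths suppresses the effect of a
#' small transducer positioning offset on any single path.
#'
#' @param geometry A [fixture_geometry()].
#' @param arrival_times Numeric length-4, positive, strictly ascending
#'   arrival times in ms.
#' @return A list of class `sws_estimate` fragment with elements
#'   `per_path_speeds` (m/s), `mean_sws` (m/s), `speed_variance`
#'   ((m/s)^2, sample variance) and `arrival_times` (ms).
#' @examples
#' geom <- fixture_geometry()
#' compute_sws(geom, predict_arrival_times(geom, 1.2))$mean_sws
#' @export
compute_sws <- function(geometry, arrival_times) {
  arrival_times <- as.numeric(arrival_times)
  if (length(arrival_times) != 4L || any(!is.finite(arrival_times)) ||
      any(arrival_times <= 0))
    sweimm_error("sweimm_invalid_wavefront",
                 "arrival_times must be 4 positive times in ms")
  if (any(diff(arrival_times) <= 0))
    sweimm_error("sweimm_invalid_wavefront",
                 "arrival_times must be strictly ascending")
  s <- two_way_paths(geometry) / arrival_times  # mm/ms == m/s
  list(
    per_path_speeds = s,
    mean_sws = mean(s),
    speed_variance = stats::var(s),
    arrival_times = arrival_times
  )
}

# ---- structured configuration ------------------------------------------

#' Read a fixture/acquisition configuration file
#'
#' YAML file with nested sections `geometry` and `acquisition` (both
#' optional; omitted fields take the package defaults) and, optionally,
#' `simulation` (see [simulation_truth()]). Unknown sections or keys are
#' rejected rather than silently ignored.
#'
#' @param path Path to a YAML configuration file.
#' @return List with elements `geometry` ([fixture_geometry()]),
#'   `acquisition` ([acquisition_config()]) and `simulation`
#'   ([simulation_truth()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    sweimm_error("sweimm_config_error", "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known_sections <- c("geometry", "acquisition", "simulation")
  extra <- setdiff(names(cfg), known_sections)
  if (length(extra) > 0)
    sweimm_error("sweimm_config_error",
                 "unknown config section(s): %s", paste(extra, collapse = ", "))
  build <- function(section, constructor) {
    args <- cfg[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(constructor)))
    if (length(bad) > 0)
      sweimm_error("sweimm_config_error",
                   "unknown key(s) in section '%s': %s",
                   section, paste(bad, collapse = ", "))
    do.call(constructor, args)
  }
  list(
    geometry = build("geometry", fixture_geometry),
    acquisition = build("acquisition", acquisition_config),
    simulation = build("simulation", simulation_truth)
  )
}
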