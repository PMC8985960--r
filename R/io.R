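# HDF5 container i/o and the results CSV schema.
#
# Layout: one group per object type ("rf_ensemble", "iq_ensemble",
# "velocity_field") holding datasets "values" (complex IQ is split into
# "values_real"/"values_imag" since HDF5 has no portable native complex
# type), "depth_axis_mm", "time_axis_ms", plus type-specific datasets;
# every fixture-geometry and acquisition field is a group attribute, as is
# the "format_version" string.

CONTAINER_VERSION <- "1.0"

geom_attrs <- function(geometry) {
  list(geometry_one_way_distances_mm = geometry$one_way_distances,
       geometry_focal_length_mm = geometry$focal_length,
       geometry_face_to_container_bottom_mm = geometry$face_to_container_bottom,
       geometry_sample_width_mm = geometry$sample_width,
       geometry_sample_length_mm = geometry$sample_length)
}

acq_attrs <- function(acq) {
  list(acquisition_center_frequency_hz = acq$center_frequency,
       acquisition_prf_hz = acq$prf,
       acquisition_n_frames = acq$n_frames,
       acquisition_rf_sampling_rate_hz = acq$rf_sampling_rate,
       acquisition_push_cycles = acq$push_cycles,
       acquisition_push_duration_s = acq$push_duration,
       acquisition_compressional_sound_speed_m_s = acq$compressional_sound_speed)
}

attrs_to_geom <- function(a) {
  fixture_geometry(
    one_way_distances = as.numeric(a$geometry_one_way_distances_mm),
    focal_length = as.numeric(a$geometry_focal_length_mm),
    face_to_container_bottom = as.numeric(a$geometry_face_to_container_bottom_mm),
    sample_width = as.numeric(a$geometry_sample_width_mm),
    sample_length = as.numeric(a$geometry_sample_length_mm))
}

attrs_to_acq <- function(a) {
  acquisition_config(
    center_frequency = as.numeric(a$acquisition_center_frequency_hz),
    prf = as.numeric(a$acquisition_prf_hz),
    n_frames = as.integer(a$acquisition_n_frames),
    rf_sampling_rate = as.numeric(a$acquisition_rf_sampling_rate_hz),
    push_cycles = as.numeric(a$acquisition_push_cycles),
    push_duration = as.numeric(a$acquisition_push_duration_s),
    compressional_sound_speed = as.numeric(a$acquisition_compressional_sound_speed_m_s))
}

#' Write an ensemble or velocity field to an HDF5 container
#'
#' @param path Destination file; overwritten if it exists.
#' @param object An `rf_ensemble`, `iq_ensemble` or [velocity_field()].
#' @return Invisibly, `path`.
#' @export
write_container <- function(path, object) {
  type <- class(object)[1]
  if (!type %in% c("rf_ensemble", "iq_ensemble", "velocity_field"))
    sweimm_error("sweimm_format_error",
                 "cannot serialize an object of class '%s'", type)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, type)
  g <- function(name) paste0(type, "/", name)

  if (type == "iq_ensemble") {
    rhdf5::h5write(Re(object$values), path, g("values_real"))
    rhdf5::h5write(Im(object$values), path, g("values_imag"))
  } else {
    rhdf5::h5write(object$values, path, g("values"))
  }
  rhdf5::h5write(object$depth_axis, path, g("depth_axis_mm"))
  rhdf5::h5write(object$time_axis, path, g("time_axis_ms"))
  if (type == "rf_ensemble") {
    rhdf5::h5write(object$scatterers$positions, path,
                   g("scatterer_positions_mm"))
    rhdf5::h5write(object$scatterers$amplitudes, path,
                   g("scatterer_amplitudes"))
  }

  extras <- switch(type,
    rf_ensemble = list(rf_sampling_rate_hz = object$rf_sampling_rate,
                       scatterer_seed = object$scatterers$seed),
    iq_ensemble = list(demod_frequency_hz = object$demod_frequency,
                       sampling_rate_hz = object$sampling_rate),
    velocity_field = list())
  attrs <- c(list(format_version = CONTAINER_VERSION),
             geom_attrs(object$geometry), acq_attrs(object$acquisition),
             extras)
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, type)
  for (nm in names(attrs)) rhdf5::h5writeAttribute(attrs[[nm]], gid, nm)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an object back from an HDF5 container
#'
#' Dispatches on the stored group name; checks the format version (major
#' version must match the reader's).
#'
#' @param path Container written by [write_container()].
#' @return The stored `rf_ensemble`, `iq_ensemble` or [velocity_field()].
#' @export
read_container <- function(path) {
  if (!file.exists(path))
    sweimm_error("sweimm_format_error", "no such file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  type <- intersect(groups,
                    c("rf_ensemble", "iq_ensemble", "velocity_field"))
  if (length(type) != 1L)
    sweimm_error("sweimm_format_error",
                 "container must hold exactly one known object group, found: %s",
                 paste(groups, collapse = ", "))
  a <- rhdf5::h5readAttributes(path, type)
  ver <- as.character(a$format_version)
  if (length(ver) == 0 ||
      strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
        strsplit(CONTAINER_VERSION, ".", fixed = TRUE)[[1]][1])
    sweimm_error("sweimm_version_error",
                 "container format version '%s' incompatible with reader '%s'",
                 if (length(ver)) ver else "<missing>", CONTAINER_VERSION)

  in_group <- ls$name[ls$group == paste0("/", type)]
  need <- if (type == "iq_ensemble") c("values_real", "values_imag")
          else "values"
  for (ds in c(need, "depth_axis_mm", "time_axis_ms"))
    if (!ds %in% in_group)
      sweimm_error("sweimm_format_error",
                   "container is missing dataset '%s/%s'", type, ds)

  g <- function(name) rhdf5::h5read(path, paste0(type, "/", name))
  geometry <- attrs_to_geom(a)
  acquisition <- attrs_to_acq(a)
  depth_axis <- as.numeric(g("depth_axis_mm"))
  time_axis <- as.numeric(g("time_axis_ms"))

  if (type == "velocity_field") {
    velocity_field(g("values"), depth_axis, time_axis, geometry, acquisition)
  } else if (type == "rf_ensemble") {
    structure(list(
      values = g("values"),
      depth_axis = depth_axis,
      time_axis = time_axis,
      rf_sampling_rate = as.numeric(a$rf_sampling_rate_hz),
      geometry = geometry,
      acquisition = acquisition,
      scatterers = list(positions = as.numeric(g("scatterer_positions_mm")),
                        amplitudes = as.numeric(g("scatterer_amplitudes")),
                        seed = as.integer(a$scatterer_seed)),
      motion = NULL
    ), class = "rf_ensemble")
  } else {
    structure(list(
      values = matrix(complex(real = g("values_real"),
                              imaginary = g("values_imag")),
                      nrow = length(depth_axis)),
      depth_axis = depth_axis,
      time_axis = time_axis,
      demod_frequency = as.numeric(a$demod_frequency_hz),
      sampling_rate = as.numeric(a$sampling_rate_hz),
      geometry = geometry,
      acquisition = acquisition
    ), class = "iq_ensemble")
  }
}

# ---- results records ----------------------------------------------------

#' Flatten an SWS estimate into a one-row result record
#'
#' @param sample_id Sample identifier string.
#' @param estimate An `sws_estimate` from [estimate_sws()].
#' @param timestamp_label Label for longitudinal series (e.g. "24h").
#' @param config_hash Provenance string for the configuration used.
#' @param seed Seed used for any simulation that produced the input.
#' @return One-row `data.frame` matching the documented CSV schema.
#' @export
result_record <- function(sample_id, estimate, timestamp_label = "",
                          config_hash = "", seed = NA_integer_) {
  stopifnot(inherits(estimate, "sws_estimate"))
  flags <- paste(names(Filter(isTRUE, estimate$flags)), collapse = ";")
  df <- data.frame(
    sample_id = as.character(sample_id),
    timestamp_label = as.character(timestamp_label),
    mean_sws = estimate$mean_sws,
    s_1 = estimate$per_path_speeds[1], s_2 = estimate$per_path_speeds[2],
    s_3 = estimate$per_path_speeds[3], s_4 = estimate$per_path_speeds[4],
    t_1 = estimate$arrival_times[1], t_2 = estimate$arrival_times[2],
    t_3 = estimate$arrival_times[3], t_4 = estimate$arrival_times[4],
    variance = estimate$speed_variance,
    initial_estimate = estimate$initial_estimate,
    flags = flags,
    config_hash = as.character(config_hash),
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  df
}

#' Write result records to CSV
#' @param records A `data.frame` of stacked [result_record()] rows.
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a results CSV written by [write_results_csv()]
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character",
                                 timestamp_label = "character",
                                 flags = "character",
                                 config_hash = "character"))
}
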