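# Core time-of-flight SWS estimation: focal trace extraction, wavefront
# candidate detection, two-stage boundary assignment (nearest-prediction
# then variance minimization), time-to-centroid arrival timing.

#' Extract the slow-time velocity trace at the focus
#'
#' Averages the velocity field over a thin depth band centered on the
#' focal depth; with `depth_halfwidth = 0` the single nearest row is
#' returned.
#'
#' @param field A [velocity_field()].
#' @param geometry A [fixture_geometry()].
#' @param depth_halfwidth Half-width of the averaging band, mm.
#' @return An object of class `focal_trace` with `values` and `time_axis`.
#' @export
focal_trace <- function(field, geometry, depth_halfwidth = 0.5) {
  stopifnot(inherits(field, "velocity_field"))
  zf <- geometry$focal_length
  if (depth_halfwidth < 0)
    sweimm_error("sweimm_domain_error", "depth_halfwidth must be >= 0")
  if (depth_halfwidth == 0) {
    rows <- which.min(abs(field$depth_axis - zf))
  } else {
    rows <- which(abs(field$depth_axis - zf) <= depth_halfwidth)
    if (length(rows) == 0)
      sweimm_error("sweimm_domain_error",
                   "no depth samples within %.2f mm of the %.2f mm focus",
                   depth_halfwidth, zf)
  }
  structure(list(
    values = colMeans(field$values[rows, , drop = FALSE]),
    time_axis = field$time_axis,
    n_rows = length(rows)
  ), class = "focal_trace")
}

#' @export
print.focal_trace <- function(x, ...) {
  cat(sprintf("<focal_trace> %d slow-time samples (%d depth rows averaged)\n",
              length(x$values), x$n_rows))
  invisible(x)
}

# topographic prominence of local maxima of y (small-n quadratic scan is
# fine: traces have a few hundred samples)
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    higher_l <- which(left > y[p])
    lmin <- if (length(higher_l) == 0) min(left) else
      min(left[max(higher_l):p])
    right <- y[p:length(y)]
    higher_r <- which(right > y[p])
    rmin <- if (length(higher_r) == 0) min(right) else
      min(right[1:min(higher_r)])
    y[p] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect reflected-wavefront candidates on a focal trace
#'
#' Local maxima of the slow-time envelope with topographic prominence of
#' at least `min_prominence` times the global envelope maximum become
#' candidates. Each gets a window extending to where the envelope falls
#' below 20% of its peak (capped at +/- `window_cap_ms`) and a
#' time-to-centroid arrival estimate. Samples before `t_min` — the
#' direct/push packet region — are excluded.
#'
#' @param trace A `focal_trace`.
#' @param min_prominence Prominence threshold as a fraction of the global
#'   envelope maximum.
#' @param t_min Earliest admissible candidate time, ms (typically half the
#'   first predicted arrival).
#' @param window_cap_ms Maximum half-width of a candidate window, ms.
#' @return List of `wavefront_candidate` objects sorted by peak time, each
#'   with `peak_time`, `window`, `centroid_time`, `peak_amplitude`,
#'   `prominence`.
#' @export
detect_candidates <- function(trace, min_prominence = 0.1, t_min = 0,
                              window_cap_ms = 1.5) {
  stopifnot(inherits(trace, "focal_trace"))
  n <- length(trace$values)
  if (n < 16)
    sweimm_error("sweimm_domain_error", "trace too short (%d samples)", n)
  env <- amp_envelope(trace$values)
  # smoothing length ~1 ms: matched to the shear-packet scale set by the
  # 0.1 ms push plus medium dispersion, it suppresses sample-to-sample
  # noise maxima without displacing packet peaks (centroids use raw env)
  dt0 <- trace$time_axis[2] - trace$time_axis[1]
  env_s <- smooth_ma(env, max(3L, round(1 / dt0)))
  admissible <- trace$time_axis >= t_min
  if (!any(admissible))
    sweimm_error("sweimm_no_wavefront", "no samples at or after t_min")
  gmax <- max(env_s[admissible])
  # detectability guard: a genuine reflected packet stands well above the
  # median envelope level, whereas the maxima of pure noise sit within a
  # small factor of it
  if (gmax < 3 * stats::median(env_s[admissible]))
    sweimm_error("sweimm_no_wavefront",
                 "no packet stands above the trace noise floor")

  interior <- 2:(n - 1)
  peaks <- interior[env_s[interior] > env_s[interior - 1] &
                    env_s[interior] >= env_s[interior + 1]]
  peaks <- peaks[admissible[peaks]]
  if (length(peaks) > 0) {
    prom <- peak_prominence(env_s, peaks)
    keep <- prom >= min_prominence * gmax
    peaks <- peaks[keep]; prom <- prom[keep]
  }
  if (length(peaks) == 0)
    sweimm_error("sweimm_no_wavefront", "no wavefront candidates detected")

  dt <- trace$time_axis[2] - trace$time_axis[1]
  cap <- max(1L, round(window_cap_ms / dt))
  cands <- lapply(seq_along(peaks), function(j) {
    p <- peaks[j]; pkv <- env_s[p]
    lo <- p; hi <- p
    while (lo > 1L && p - lo < cap && env_s[lo - 1L] >= 0.2 * pkv &&
           admissible[lo - 1L]) lo <- lo - 1L
    while (hi < n && hi - p < cap && env_s[hi + 1L] >= 0.2 * pkv)
      hi <- hi + 1L
    window <- c(trace$time_axis[lo], trace$time_axis[hi])
    structure(list(
      peak_time = trace$time_axis[p],
      window = window,
      centroid_time = time_to_centroid(trace, window),
      peak_amplitude = env[p],
      prominence = prom[j] / gmax
    ), class = "wavefront_candidate")
  })
  cands[order(vapply(cands, `[[`, numeric(1), "peak_time"))]
}

#' Time-to-centroid arrival time of a wave packet
#'
#' Energy-weighted temporal centroid of the squared envelope over a
#' window: `t_c = sum(t * E) / sum(E)` with `E = envelope^2`. Less
#' sensitive than time-to-peak to packet-shape distortion.
#'
#' @param trace A `focal_trace`.
#' @param window Length-2 time window (ms) within the trace support.
#' @return Centroid time in ms.
#' @export
time_to_centroid <- function(trace, window) {
  stopifnot(inherits(trace, "focal_trace"), length(window) == 2L)
  sel <- trace$time_axis >= window[1] & trace$time_axis <= window[2]
  if (!any(sel))
    sweimm_error("sweimm_domain_error", "window outside trace support")
  E <- amp_envelope(trace$values)[sel]^2
  if (sum(E) == 0)
    sweimm_error("sweimm_domain_error", "all-zero window")
  sum(trace$time_axis[sel] * E) / sum(E)
}

# wavefront_set constructor with invariant checks
wavefront_set <- function(candidates) {
  times <- vapply(candidates, `[[`, numeric(1), "centroid_time")
  if (length(candidates) != 4L || any(diff(times) <= 0))
    sweimm_error("sweimm_assignment_error",
                 "a wavefront set needs 4 candidates with ascending centroid times")
  structure(list(candidates = candidates, arrival_times = times),
            class = "wavefront_set")
}

#' Stage 1: assign candidates to boundaries by predicted arrival time
#'
#' For each boundary in ascending-distance order, selects the unassigned
#' candidate whose centroid time is nearest the predicted arrival.
#'
#' @param candidates List of candidates from [detect_candidates()].
#' @param predicted_times Length-4 predicted arrivals (ms), ascending.
#' @return A `wavefront_set`.
#' @export
stage1_assign <- function(candidates, predicted_times) {
  if (length(candidates) < 4L)
    sweimm_error("sweimm_assignment_error",
                 "need at least 4 candidates, have %d", length(candidates))
  stopifnot(length(predicted_times) == 4L)
  times <- vapply(candidates, `[[`, numeric(1), "centroid_time")
  chosen <- integer(4)
  avail <- rep(TRUE, length(candidates))
  for (i in 1:4) {
    j <- which(avail)[which.min(abs(times[avail] - predicted_times[i]))]
    chosen[i] <- j
    avail[j] <- FALSE
  }
  if (any(diff(times[chosen]) <= 0))
    sweimm_error("sweimm_assignment_error",
                 "stage-1 assignment is not strictly ascending in time")
  wavefront_set(candidates[chosen])
}

#' Stage 2: refine the assignment by minimizing per-path speed variance
#'
#' Exhaustively searches the Cartesian product of, per boundary, the
#' `k_alternatives` candidates nearest (in centroid time) the stage-1
#' choice. Combinations that reuse a candidate or are not strictly
#' ascending are discarded; the combination minimizing the sample variance
#' of the four per-path speeds `s_i = 2 d_i / t_i` wins, with variance
#' ties broken by proximity to the stage-1 arrival times. The returned
#' variance never exceeds the stage-1 variance.
#'
#' @param candidates Full candidate list from [detect_candidates()].
#' @param stage1_set `wavefront_set` from [stage1_assign()].
#' @param geometry A [fixture_geometry()].
#' @param k_alternatives Per-boundary neighborhood size (default 3).
#' @return List with `set` (the refined `wavefront_set`) and `estimate`
#'   (the [compute_sws()] result for its arrival times plus
#'   `n_combinations_searched`).
#' @export
stage2_refine <- function(candidates, stage1_set, geometry,
                          k_alternatives = 3L) {
  stopifnot(inherits(stage1_set, "wavefront_set"))
  times <- vapply(candidates, `[[`, numeric(1), "centroid_time")
  neighborhoods <- lapply(stage1_set$arrival_times, function(t1) {
    order(abs(times - t1))[seq_len(min(k_alternatives, length(times)))]
  })
  grid <- expand.grid(neighborhoods, KEEP.OUT.ATTRS = FALSE)
  d2 <- two_way_paths(geometry)

  best <- NULL
  n_valid <- 0L
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    if (anyDuplicated(idx)) next
    tsel <- times[idx]
    if (any(tsel <= 0) || any(diff(tsel) <= 0)) next
    n_valid <- n_valid + 1L
    v <- stats::var(d2 / tsel)
    tie <- sum(abs(tsel - stage1_set$arrival_times))
    if (is.null(best) || v < best$v - 1e-15 ||
        (abs(v - best$v) <= 1e-15 && tie < best$tie)) {
      best <- list(idx = idx, v = v, tie = tie)
    }
  }
  if (is.null(best))
    sweimm_error("sweimm_refinement_error",
                 "no valid wavefront combination in the stage-2 search space")
  set <- wavefront_set(candidates[best$idx])
  est <- compute_sws(geometry, set$arrival_times)
  est$n_combinations_searched <- n_valid
  list(set = set, estimate = est)
}

# run a pipeline stage, tagging errors with the stage name while keeping
# their condition class
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, sweimm_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    e$stage <- stage
    stop(e)
  })
}

#' End-to-end shear-wave speed estimation from a velocity field
#'
#' Full pipeline: crop around the focus, f-k directional filtering, the
#' regression-based initial speed estimate, boundary-arrival prediction,
#' focal-trace extraction, wavefront candidate detection, stage-1
#' nearest-prediction assignment, time-to-centroid arrival timing, stage-2
#' variance-minimizing refinement, and the time-of-flight average
#' [compute_sws()]. If the initial slope fit fails, a grid of initial
#' speeds (0.3 to 2 m/s, step 0.1) is scanned and the one minimizing the
#' stage-2 variance is used (flagged in the result).
#'
#' @param field A [velocity_field()].
#' @param geometry A [fixture_geometry()]; defaults to the one carried by
#'   the field.
#' @param acquisition An [acquisition_config()]; defaults likewise.
#' @param options Named list overriding pipeline defaults:
#'   `crop_halfwidth` (mm, 2), `trace_halfwidth` (mm, 0.5),
#'   `min_prominence` (0.1), `k_alternatives` (3), `window_cap_ms` (1.5),
#'   `initial_speed` (m/s, `NULL` = fit it).
#' @return An object of class `sws_estimate`: `mean_sws`,
#'   `per_path_speeds`, `arrival_times`, `speed_variance`,
#'   `initial_estimate`, `n_candidates_considered`, `flags`,
#'   `wavefront_set`, `diagnostics`.
#' @export
estimate_sws <- function(field, geometry = field$geometry,
                         acquisition = field$acquisition,
                         options = list()) {
  opt <- utils::modifyList(list(
    crop_halfwidth = 2, slope_halfwidth = 4, trace_halfwidth = 0.5,
    min_prominence = 0.1, k_alternatives = 3L, window_cap_ms = 1.5,
    initial_speed = NULL
  ), options)
  flags <- list(fallback_initial = FALSE,
                overlap = isTRUE(field$flags$overlap),
                aliasing = isTRUE(field$flags$any_aliased))

  cropped <- with_stage("crop", crop_around_focus(
    field, depth_halfwidth = opt$crop_halfwidth,
    time_window = max(field$time_axis)))

  run_selection <- function(c0) {
    predicted <- predict_arrival_times(geometry, c0)
    # trace window adapted to the slowest predicted arrival to exclude
    # late reverberation while covering slow media
    t_max <- min(max(cropped$time_axis), 1.3 * predicted[4] + 2)
    keep_t <- cropped$time_axis <= t_max
    sub <- velocity_field(cropped$values[, keep_t, drop = FALSE],
                          cropped$depth_axis, cropped$time_axis[keep_t],
                          geometry, acquisition, flags = cropped$flags)
    trace <- with_stage("focal_trace",
                        focal_trace(sub, geometry, opt$trace_halfwidth))
    cands <- with_stage("detect_candidates", detect_candidates(
      trace, min_prominence = opt$min_prominence,
      t_min = predicted[1] / 2, window_cap_ms = opt$window_cap_ms))
    s1 <- with_stage("stage1_assign", stage1_assign(cands, predicted))
    s2 <- with_stage("stage2_refine",
                     stage2_refine(cands, s1, geometry, opt$k_alternatives))
    list(predicted = predicted, trace = trace, candidates = cands,
         stage1 = s1, refined = s2)
  }

  initial <- opt$initial_speed
  if (is.null(initial)) {
    # the slope fit benefits from the widest available depth aperture, so
    # it gets its own crop (depth only), independent of the trace crop
    wide <- withCallingHandlers(
      with_stage("crop", crop_around_focus(
        field, depth_halfwidth = opt$slope_halfwidth,
        time_window = max(field$time_axis))),
      sweimm_crop_warning = function(w) invokeRestart("muffleWarning"))
    component <- with_stage("directional_filter",
                            filtered_component_for_slope(wide, "down"))
    initial <- tryCatch(
      as.numeric(initial_sws_slope(component, geometry)),
      sweimm_error = function(e) NULL)
  }

  # A credible four-boundary assignment must use the strongest admissible
  # candidate: by the spreading law the nearest side boundary returns the
  # largest reflected packet, so a set that skips the trace's dominant
  # peak is a self-consistent arrangement of noise or harmonics (e.g. the
  # half-speed alias that pairs every second packet with a noise peak).
  includes_strongest <- function(s) {
    amps <- vapply(s$candidates, `[[`, numeric(1), "peak_amplitude")
    sel_t <- s$refined$set$arrival_times
    strongest_t <- s$candidates[[which.max(amps)]]$centroid_time
    any(abs(sel_t - strongest_t) < 1e-9)
  }

  sel <- NULL
  if (!is.null(initial)) {
    # a mis-seeded selection (slope fit captured by the wrong structure)
    # falls through to the grid fallback rather than aborting
    sel <- tryCatch(with_stage("selection", run_selection(initial)),
                    sweimm_error = function(e) NULL)
    if (!is.null(sel) && !includes_strongest(sel)) sel <- NULL
  }
  if (is.null(sel)) {
    # fallback: scan a physiological speed grid; among seeds whose
    # refined set contains the dominant candidate, keep the lowest
    # stage-2 variance
    flags$fallback_initial <- TRUE
    results <- list()
    for (c0 in seq(0.3, 2.0, by = 0.1)) {
      cand <- tryCatch(run_selection(c0), sweimm_error = function(e) NULL)
      if (!is.null(cand)) {
        results[[length(results) + 1L]] <-
          list(sel = cand, c0 = c0,
               ok = includes_strongest(cand),
               v = cand$refined$estimate$speed_variance)
      }
    }
    if (length(results) == 0)
      sweimm_error("sweimm_no_wavefront",
                   "[stage initial_estimate] no initial speed on the fallback grid yields a valid wavefront assignment")
    ok <- which(vapply(results, `[[`, logical(1), "ok"))
    if (length(ok) == 0) ok <- seq_along(results)
    best <- results[[ok[which.min(
      vapply(results[ok], `[[`, numeric(1), "v"))]]]
    sel <- best$sel
    initial <- best$c0
  }

  # the recording must contain the slowest selected arrival with margin
  flags$window_truncated <-
    max(sel$refined$set$arrival_times) + 1 > max(cropped$time_axis)

  est <- sel$refined$estimate
  structure(list(
    mean_sws = est$mean_sws,
    per_path_speeds = est$per_path_speeds,
    arrival_times = est$arrival_times,
    speed_variance = est$speed_variance,
    initial_estimate = initial,
    n_candidates_considered = length(sel$candidates),
    flags = flags,
    wavefront_set = sel$refined$set,
    diagnostics = list(
      predicted_times = sel$predicted,
      stage1_times = sel$stage1$arrival_times,
      n_combinations_searched = est$n_combinations_searched
    )
  ), class = "sws_estimate")
}

#' @export
print.sws_estimate <- function(x, ...) {
  cat("<sws_estimate>\n")
  cat(sprintf("  mean SWS: %.3f m/s (variance %.2e (m/s)^2)\n",
              x$mean_sws, x$speed_variance))
  cat("  per-path speeds:",
      paste(sprintf("%.3f", x$per_path_speeds), collapse = ", "), "m/s\n")
  cat("  arrival times:",
      paste(sprintf("%.2f", x$arrival_times), collapse = ", "), "ms\n")
  cat(sprintf("  initial estimate: %.3f m/s%s\n", x$initial_estimate,
              if (x$flags$fallback_initial) " (fallback grid)" else ""))
  invisible(x)
}
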