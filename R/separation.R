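# f-k directional wave separation and the regression-based initial SWS
# estimate.
#
# Sign convention for the 2D DFT quadrants: R's fft uses the kernel
# exp(-2*pi*i*(p*m/M + q*n/N)), so a down-going wave exp(2*pi*i*(k*z - f*t))
# (depth increasing with time, i.e. propagating away from the transducer)
# lands where the signed depth-frequency and time-frequency indices have
# OPPOSITE signs; an up-going wave lands where they share a sign.

# 1D Tukey (cosine-tapered) window; alpha = total tapered fraction
tukey_window <- function(n, alpha = 0.2) {
  if (alpha <= 0) return(rep(1, n))
  w <- rep(1, n)
  edge <- floor(alpha * (n - 1) / 2)
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * (0:edge) / edge))
    w[1:(edge + 1)] <- ramp
    w[n:(n - edge)] <- ramp
  }
  w
}

# Apply a separable 2D Tukey taper to a velocity field. Used ahead of f-k
# filtering inside the pipeline: a packet truncated mid-amplitude at the
# crop boundary is a periodic discontinuity to the DFT and leaks energy
# into both direction quadrants; tapering the edges removes the leak. The
# time taper is specified in ms (it must stay short so early arrivals at
# high speeds are not swallowed).
taper_field <- function(field, alpha_z = 0.2, taper_t_ms = 2) {
  wz <- tukey_window(nrow(field$values), alpha_z)
  duration <- diff(range(field$time_axis))
  wt <- tukey_window(ncol(field$values),
                     min(1, 2 * taper_t_ms / duration))
  velocity_field(field$values * outer(wz, wt), field$depth_axis,
                 field$time_axis, field$geometry, field$acquisition,
                 flags = field$flags)
}

# Taper, directionally filter, and divide the taper back out (clipped so
# heavily shaded edges stay suppressed). The unshading matters: a packet
# peaking inside the taper ramp would otherwise have its apparent peak
# time dragged toward the window interior, tilting the slope fit.
filtered_component_for_slope <- function(field, direction = "down",
                                         alpha_z = 0.2, taper_t_ms = 2) {
  wz <- tukey_window(nrow(field$values), alpha_z)
  duration <- diff(range(field$time_axis))
  wt <- tukey_window(ncol(field$values), min(1, 2 * taper_t_ms / duration))
  W <- outer(wz, wt)
  tapered <- velocity_field(field$values * W, field$depth_axis,
                            field$time_axis, field$geometry,
                            field$acquisition, flags = field$flags)
  comp <- directional_filter(tapered, direction)
  comp$field$values <- comp$field$values / pmax(W, 0.25)
  comp
}

# signed frequency index for an axis of length n: 0, 1, ..., -1 ordering
signed_freq <- function(n) {
  idx <- seq_len(n) - 1L
  ifelse(idx <= n / 2, idx, idx - n)
}

# smooth one-sided step along signed frequencies: 0 on the negative side,
# 1 on the positive, raised-cosine transition of total width `width` bins
# centered on 0. Satisfies w(-f) = 1 - w(f), which keeps the mask
# Hermitian-symmetric and the filtered field real.
freq_step <- function(f, width) {
  w <- ifelse(f < -width / 2, 0,
       ifelse(f > width / 2, 1,
              0.5 * (1 + sin(pi * f / width))))
  w
}

#' Directionally filter a velocity field in the f-k domain
#'
#' Separates the field into the component propagating away from the
#' transducer (`"down"`, depth increasing with time — e.g. the top-surface
#' reflection) or toward it (`"up"` — e.g. the bottom-face reflection), by
#' zeroing the complementary quadrant pair of the 2D spectrum with a
#' raised-cosine taper (width 5% of each axis' band). The operation is
#' linear and the two complementary components tile the spectrum, so their
#' energies sum to the input energy away from the tapered DC/Nyquist ridge.
#'
#' @param field A [velocity_field()] with at least 8 samples per axis.
#' @param direction `"up"` (toward the transducer) or `"down"` (away).
#' @return An object of class `directional_component`: `field` (the
#'   filtered [velocity_field()]), `direction`, and
#'   `retained_energy_fraction`.
#' @export
directional_filter <- function(field, direction = c("down", "up")) {
  stopifnot(inherits(field, "velocity_field"))
  direction <- match.arg(direction)
  M <- nrow(field$values); N <- ncol(field$values)
  if (M < 8 || N < 8)
    sweimm_error("sweimm_domain_error",
                 "directional filtering needs >= 8 samples on each axis")

  wz <- freq_step(signed_freq(M), width = 0.05 * M)
  wt <- freq_step(signed_freq(N), width = 0.05 * N)
  Wz <- matrix(wz, M, N)
  Wt <- matrix(wt, M, N, byrow = TRUE)
  mask <- if (direction == "down") Wz * (1 - Wt) + (1 - Wz) * Wt
          else Wz * Wt + (1 - Wz) * (1 - Wt)

  S <- stats::fft(field$values)
  filtered <- Re(stats::fft(S * mask, inverse = TRUE)) / (M * N)

  e_in <- sum(field$values^2)
  out <- velocity_field(filtered, field$depth_axis, field$time_axis,
                        field$geometry, field$acquisition,
                        flags = field$flags)
  structure(list(
    field = out,
    direction = direction,
    retained_energy_fraction = if (e_in > 0) sum(filtered^2) / e_in else 0
  ), class = "directional_component")
}

#' @export
print.directional_component <- function(x, ...) {
  cat(sprintf("<directional_component> %s-going, %.1f%% of input energy\n",
              x$direction, 100 * x$retained_energy_fraction))
  invisible(x)
}

# Collect every detectable envelope peak of every depth row as a
# (depth, peak time, local centroid time, amplitude) point. All packets a
# row contains are kept: deciding which points form the reflected
# wavefront is the line-search's job, not a per-row heuristic's.
collect_row_peaks <- function(values, depth_axis, time_axis,
                              packet_cap_ms = 0.75) {
  dt <- time_axis[2] - time_axis[1]
  cap <- max(1L, round(packet_cap_ms / dt))
  env <- envelope_rows(values)
  med_level <- stats::median(env)
  n_t <- length(time_axis)
  out <- vector("list", nrow(values))
  for (i in seq_len(nrow(values))) {
    row <- smooth_ma(env[i, ])
    interior <- 2:(n_t - 1)
    pks <- interior[row[interior] > row[interior - 1] &
                    row[interior] >= row[interior + 1]]
    pks <- pks[row[pks] > 3 * med_level]
    if (length(pks) == 0) next
    pts <- lapply(pks, function(pk) {
      pkv <- row[pk]
      lo <- pk; hi <- pk
      while (lo > 1L && pk - lo < cap && row[lo - 1L] >= 0.2 * pkv)
        lo <- lo - 1L
      while (hi < n_t && hi - pk < cap && row[hi + 1L] >= 0.2 * pkv)
        hi <- hi + 1L
      w <- lo:hi
      c(z = depth_axis[i], t_peak = time_axis[pk],
        t_centroid = sum(time_axis[w] * env[i, w]^2) / sum(env[i, w]^2),
        amp = pkv)
    })
    out[[i]] <- do.call(rbind, pts)
  }
  as.data.frame(do.call(rbind, out[!vapply(out, is.null, logical(1))]))
}

# Deterministic consensus line search over peak points: every pair of
# high-amplitude points at least 1 mm apart in depth proposes a line
# t = a + b z with b restricted to plausible shear slopes; the line whose
# 0.35 ms inlier band captures the most squared amplitude wins, provided
# its inliers span at least `min_span_mm` of depth (a slope measured over
# less is numerically meaningless).
consensus_line <- function(pts, slope_range = c(0.2, 4), thr_ms = 0.35,
                           max_seed_points = 80L, min_span_mm = 1.2) {
  o <- order(pts$amp, decreasing = TRUE)
  seed <- pts[o[seq_len(min(max_seed_points, nrow(pts)))], ]
  best <- NULL
  n <- nrow(seed)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dz <- seed$z[j] - seed$z[i]
    if (abs(dz) < 1) next
    b <- (seed$t_peak[j] - seed$t_peak[i]) / dz
    if (b < slope_range[1] || b > slope_range[2]) next
    a <- seed$t_peak[i] - b * seed$z[i]
    r <- abs(pts$t_peak - (a + b * pts$z))
    inl <- r <= thr_ms
    if (!any(inl) || diff(range(pts$z[inl])) < min_span_mm) next
    score <- sum(pts$amp[inl]^2)
    if (is.null(best) || score > best$score)
      best <- list(a = a, b = b, score = score)
  }
  best
}

#' Initial SWS estimate from the slope of the filtered wavefield
#'
#' Fits the depth-time slope of the dominant collinear wave packet in a
#' directionally filtered field — the axial propagation locus of the
#' down-going shear wavefield (top-surface reflection and, below the
#' focus, the diverging push packet, which share the same axial speed in
#' an isotropic medium). Because the filtered field also contains the
#' near-flat loci of the laterally reflected side-boundary packets, the
#' fit is a two-stage robust regression: a deterministic consensus
#' (RANSAC-style) line search over every detectable row envelope peak
#' selects the wavefront, then weighted least squares on the inliers'
#' arrival statistics (envelope-energy centroids by default, weights =
#' squared peak amplitude) refines the slope. The speed is `|1/slope|`.
#'
#' @param component A `directional_component` from [directional_filter()].
#' @param geometry A [fixture_geometry()].
#' @param rows Depth rows entering the fit: `"flanks"` (default) excludes
#'   a 0.5 mm band around the focus, where the push packet's apex and the
#'   side packets' hyperbola vertices carry no direction information;
#'   `"above_focus"` uses only rows above the focus; `"all"` uses every
#'   row.
#' @param statistic Arrival statistic refit on the inliers: `"centroid"`
#'   (default) or `"peak"`.
#' @return Speed in m/s with attribute `diagnostics` (number of points,
#'   inliers, slope, consensus score).
#' @export
initial_sws_slope <- function(component, geometry,
                              rows = c("flanks", "above_focus", "all"),
                              statistic = c("centroid", "peak")) {
  stopifnot(inherits(component, "directional_component"))
  rows <- match.arg(rows)
  statistic <- match.arg(statistic)
  vf <- component$field
  zf <- geometry$focal_length
  sel <- switch(rows,
    flanks = abs(vf$depth_axis - zf) > 0.5,
    above_focus = vf$depth_axis < zf - 0.5,
    all = rep(TRUE, length(vf$depth_axis)))
  if (sum(sel) < 8)
    sweimm_error("sweimm_no_wavefront",
                 "fewer than 8 depth rows available for the slope fit")
  pts <- collect_row_peaks(vf$values[sel, , drop = FALSE],
                           vf$depth_axis[sel], vf$time_axis)
  if (nrow(pts) == 0 || length(unique(pts$z)) < 8)
    sweimm_error("sweimm_no_wavefront",
                 "fewer than 8 rows with a detectable wavefront")
  line <- consensus_line(pts)
  if (is.null(line))
    sweimm_error("sweimm_implausible_speed",
                 "no depth-time wavefront with a plausible shear slope found")
  tstat <- if (statistic == "peak") pts$t_peak else pts$t_centroid
  n_inl <- NA_integer_
  for (k in 1:2) {
    r <- abs(tstat - (line$a + line$b * pts$z))
    inl <- r <= 0.35
    n_inl <- sum(inl)
    if (n_inl < 8)
      sweimm_error("sweimm_no_wavefront",
                   "fewer than 8 inlier rows on the fitted wavefront")
    fit <- stats::lm(tstat[inl] ~ pts$z[inl], weights = pts$amp[inl]^2)
    line$a <- stats::coef(fit)[[1]]
    line$b <- stats::coef(fit)[[2]]
  }
  speed <- abs(1 / line$b)
  if (!is.finite(speed) || speed > 10)
    sweimm_error("sweimm_implausible_speed",
                 "fitted wavefront slope implies %.3g m/s (> 10 m/s)", speed)
  structure(speed, diagnostics = list(
    n_points = nrow(pts),
    n_inliers = n_inl,
    slope_ms_per_mm = line$b,
    consensus_score = line$score,
    retained_energy_fraction = component$retained_energy_fraction
  ))
}

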