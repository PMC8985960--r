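# Focal trace, candidate detection, centroid timing, two-stage boundary
# assignment, and the end-to-end pipeline.

mk_trace <- function(values, dt = 0.2) {
  structure(list(values = values,
                 time_axis = (seq_along(values) - 1) * dt,
                 n_rows = 1L),
            class = "focal_trace")
}

gauss_tr <- function(tt, t0, sigma = 0.55, amp = 1) {
  amp * exp(-(tt - t0)^2 / (2 * sigma^2))
}

test_that("focal trace averages the depth band around the focus", {
  z <- seq(10, 18, by = 0.05)
  tt <- (0:99) / 5
  const_depth <- mk_field(outer(rep(1, length(z)), sin(tt)), z = z, tt = tt)
  trc <- focal_trace(const_depth, default_geom, 0.5)
  expect_equal(trc$values, sin(tt))

  trc0 <- focal_trace(const_depth, default_geom, 0)
  expect_equal(trc0$n_rows, 1L)
  expect_equal(trc0$values, sin(tt))

  coarse <- mk_field(matrix(1, 4, 100), z = c(10, 12, 16, 18), tt = tt)
  expect_error(focal_trace(coarse, default_geom, 0.5),
               class = "sweimm_domain_error")
})

test_that("candidate detection finds the four boundary packets", {
  vf <- sim_clean_field(1.0)
  trc <- focal_trace(vf, default_geom, 0.5)
  cands <- detect_candidates(trc, min_prominence = 0.1, t_min = 3)
  expect_gte(length(cands), 4L)
  peaks <- vapply(cands, `[[`, numeric(1), "peak_time")
  for (t0 in c(6.0, 12.4, 18.4, 24.0))
    expect_lte(min(abs(peaks - t0)), 0.2 + 1e-9)
  # candidate invariants
  for (cd in cands) {
    expect_lt(cd$window[1], cd$peak_time + 1e-9)
    expect_gt(cd$window[2], cd$peak_time - 1e-9)
    expect_gte(cd$centroid_time, cd$window[1])
    expect_lte(cd$centroid_time, cd$window[2])
  }
})

test_that("an injected spurious peak becomes one extra candidate", {
  tt <- (0:249) * 0.2
  base <- gauss_tr(tt, 6) + gauss_tr(tt, 12.4, amp = 0.8) +
    gauss_tr(tt, 18.4, amp = 0.6) + gauss_tr(tt, 24, amp = 0.5)
  spur <- base + gauss_tr(tt, 9, amp = 0.4)
  n_base <- length(detect_candidates(mk_trace(base), 0.1, t_min = 3))
  n_spur <- length(detect_candidates(mk_trace(spur), 0.1, t_min = 3))
  expect_equal(n_base, 4L)
  expect_equal(n_spur, 5L)

  expect_error(detect_candidates(mk_trace(rep(1, 100)), 0.1),
               class = "sweimm_no_wavefront")
  expect_error(detect_candidates(mk_trace(rep(0, 10)), 0.1),
               class = "sweimm_domain_error")
})

test_that("time-to-centroid matches symmetry, skew, and delta cases", {
  tt <- (0:249) * 0.2
  sym <- mk_trace(gauss_tr(tt, 12.4))
  expect_equal(time_to_centroid(sym, c(9, 15.8)), 12.4, tolerance = 0.2)

  # right-skewed packet: centroid strictly later than the peak; frozen
  # against a hand-computed discrete centroid of the same samples
  skew <- gauss_tr(tt, 10, sigma = 0.4) + 0.6 * gauss_tr(tt, 11.5, sigma = 1)
  w <- tt >= 7 & tt <= 15
  oracle <- sum(tt[w] * skew[w]^2) / sum(skew[w]^2)
  tc <- time_to_centroid(mk_trace(skew), c(7, 15))
  expect_equal(tc, oracle)
  expect_gt(tc, tt[which.max(skew)])

  delta <- rep(0, 100); delta[31] <- 1
  expect_equal(time_to_centroid(mk_trace(delta), c(0, 19.8)), 30 * 0.2)

  expect_error(time_to_centroid(mk_trace(delta), c(10, 15)),
               class = "sweimm_domain_error")
  expect_error(time_to_centroid(mk_trace(delta), c(50, 60)),
               class = "sweimm_domain_error")
})

test_that("stage-1 assigns each boundary its nearest candidate", {
  cands <- lapply(c(6.1, 12.3, 18.5, 23.9), mk_cand)
  set1 <- stage1_assign(cands, c(6.0, 12.4, 18.4, 24.0))
  expect_equal(set1$arrival_times, c(6.1, 12.3, 18.5, 23.9))

  # a spurious intermediate peak is left unassigned
  cands5 <- lapply(c(6.1, 9.0, 12.3, 18.5, 23.9), mk_cand)
  set2 <- stage1_assign(cands5, c(6.0, 12.4, 18.4, 24.0))
  expect_equal(set2$arrival_times, c(6.1, 12.3, 18.5, 23.9))

  expect_error(stage1_assign(lapply(c(6, 12, 18), mk_cand),
                             c(6.0, 12.4, 18.4, 24.0)),
               class = "sweimm_assignment_error")
})

test_that("stage-2 refinement matches brute-force enumeration", {
  # randomized candidate sets; independent brute force over the same
  # neighborhood-restricted combination space
  brute_force <- function(cands, s1, k) {
    times <- vapply(cands, `[[`, numeric(1), "centroid_time")
    nb <- lapply(s1$arrival_times, function(t1)
      order(abs(times - t1))[seq_len(min(k, length(times)))])
    d2 <- two_way_paths(default_geom)
    best_v <- Inf
    for (i1 in nb[[1]]) for (i2 in nb[[2]])
      for (i3 in nb[[3]]) for (i4 in nb[[4]]) {
        idx <- c(i1, i2, i3, i4)
        if (anyDuplicated(idx)) next
        tsel <- times[idx]
        if (any(diff(tsel) <= 0)) next
        best_v <- min(best_v, var(d2 / tsel))
      }
    best_v
  }
  set.seed(77)
  n_checked <- 0
  for (rep in 1:60) {
    k_cand <- sample(5:9, 1)
    times <- sort(runif(k_cand, 4, 30))
    if (any(diff(times) < 0.3)) next
    cands <- lapply(times, mk_cand)
    pred <- predict_arrival_times(default_geom, runif(1, 0.8, 1.4))
    s1 <- tryCatch(stage1_assign(cands, pred), error = function(e) NULL)
    if (is.null(s1)) next
    s2 <- stage2_refine(cands, s1, default_geom, k_alternatives = 3)
    expect_equal(s2$estimate$speed_variance,
                 brute_force(cands, s1, 3), tolerance = 1e-12)
    # refinement never increases the variance
    v1 <- var(two_way_paths(default_geom) / s1$arrival_times)
    expect_lte(s2$estimate$speed_variance, v1 + 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("stage-2 swaps a mistaken spurious peak back out", {
  # stage 1 with a poor prediction grabs the 9 ms peak for boundary 2;
  # the true 12.4 ms packet is among the alternatives
  cands <- lapply(c(6.0, 9.0, 12.4, 18.4, 24.0), mk_cand)
  bad_pred <- c(6.0, 9.3, 18.4, 24.0)
  s1 <- stage1_assign(cands, bad_pred)
  expect_equal(s1$arrival_times[2], 9.0)
  s2 <- stage2_refine(cands, s1, default_geom, k_alternatives = 3)
  expect_equal(s2$set$arrival_times, c(6.0, 12.4, 18.4, 24.0))
  v1 <- var(two_way_paths(default_geom) / s1$arrival_times)
  expect_lt(s2$estimate$speed_variance, v1)

  # degenerate neighborhood: k = 1 reproduces stage 1
  s2k1 <- stage2_refine(cands, s1, default_geom, k_alternatives = 1)
  expect_equal(s2k1$set$arrival_times, s1$arrival_times)

  # a clean already-optimal set is a fixed point
  clean <- lapply(c(6.0, 12.4, 18.4, 24.0), mk_cand)
  s1c <- stage1_assign(clean, c(6.0, 12.4, 18.4, 24.0))
  s2c <- stage2_refine(clean, s1c, default_geom, 3)
  expect_equal(s2c$set$arrival_times, s1c$arrival_times)
})

test_that("the pipeline recovers known speeds end to end", {
  est1 <- estimate_sws(sim_clean_field(1.0))
  expect_equal(est1$mean_sws, 1.0, tolerance = 0.02)
  # the cell-gel range reported for collagen concentrations 1-3 mg/ml
  for (c0 in c(0.47, 1.47)) {
    est <- estimate_sws(sim_clean_field(c0))
    expect_lt(abs(est$mean_sws - c0) / c0, 0.03)
  }
  # estimator consistency: the mean equals the printed formula applied to
  # the selected arrival times, exactly
  ref <- compute_sws(default_geom, est1$arrival_times)
  expect_identical(est1$mean_sws, ref$mean_sws)
  expect_identical(est1$per_path_speeds, ref$per_path_speeds)
})

test_that("recovered speed is strictly monotone along a true-SWS grid", {
  grid <- seq(0.6, 1.6, by = 0.25)
  ests <- vapply(grid, function(c0) estimate_sws(sim_clean_field(c0))$mean_sws,
                 numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("pure noise yields a classed error, not a number", {
  set.seed(42)
  z <- seq(10, 18, by = 0.05)
  tt <- (0:399) / 5
  noise <- mk_field(matrix(rnorm(length(z) * length(tt)), length(z)),
                    z = z, tt = tt)
  expect_error(estimate_sws(noise), class = "sweimm_no_wavefront")
})
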