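# Optical-mapping electrophysiology metrics.
#
# Activation time per pixel is the time of the maximum forward-difference
# voltage derivative, (dVm/dt)max, with optional sub-frame parabolic
# refinement. Conduction velocities come from least-squares regression of
# activation time on distance along rays through the stimulation site;
# APD80 is the time from activation to 80% repolarization (signal back down
# to 20% of its local amplitude); ERP is found by an S1-S2 protocol with
# decreasing coupling intervals.

#' Condition an optical movie
#'
#' Optional moving-average temporal smoothing and Gaussian spatial
#' smoothing, followed by per-pixel min-max amplitude normalization to
#' \[0, 1\]. Pixels with constant signal cannot be normalized and are
#' removed from the mask.
#'
#' @param movie An [optical_movie()].
#' @param temporal_smooth_ms Moving-average window in ms (0 = off).
#' @param spatial_smooth_px Gaussian sigma in pixels (0 = off).
#' @return A conditioned `optical_movie`.
#' @export
condition_signals <- function(movie, temporal_smooth_ms = 0, spatial_smooth_px = 0) {
  stopifnot(inherits(movie, "optical_movie"))
  if (temporal_smooth_ms < 0 || spatial_smooth_px < 0) {
    cq_stop("smoothing windows must be >= 0")
  }
  d <- dim(movie$frames)
  V <- matrix(movie$frames, d[1])

  if (temporal_smooth_ms > 0) {
    wlen <- max(1L, round(temporal_smooth_ms * movie$fs / 1000))
    if (wlen %% 2L == 0L) wlen <- wlen + 1L
    if (wlen > 1L) {
      Vs <- stats::filter(V, rep(1 / wlen, wlen), sides = 2)
      half <- (wlen - 1L) %/% 2L
      # shrink the window at the edges instead of dropping frames
      for (i in seq_len(half)) {
        Vs[i, ] <- colMeans(V[seq_len(i + half), , drop = FALSE])
        Vs[d[1] - i + 1L, ] <- colMeans(V[(d[1] - i + 1L - half):d[1], , drop = FALSE])
      }
      V <- unclass(Vs)
    }
  }
  if (spatial_smooth_px > 0) {
    A <- array(V, d)
    for (f in seq_len(d[1])) A[f, , ] <- gauss_blur_mat(A[f, , ], spatial_smooth_px)
    V <- matrix(A, d[1])
  }
  lo <- apply(V, 2L, min); hi <- apply(V, 2L, max)
  rng <- hi - lo
  flat <- rng <= .Machine$double.eps * pmax(abs(hi), 1)
  rng[flat] <- 1
  V <- sweep(sweep(V, 2L, lo), 2L, rng, "/")
  out <- movie
  out$frames <- array(V, d)
  out$mask <- movie$mask & !matrix(flat, d[2], d[3])
  out
}

#' Per-pixel activation map from (dVm/dt)max
#'
#' For each masked pixel the activation time is the time of the maximum
#' forward-difference derivative within the analysis window (ties broken
#' toward the earliest). With `refine = "parabolic"` (default) a parabola
#' through the three derivative samples around the maximum gives a
#' sub-frame estimate of the continuous derivative peak (derivative samples
#' are timestamped at frame midpoints). With `refine = "none"` the
#' activation sample is the first frame at the risen level. Pixels whose
#' maximum derivative does not exceed `noise_floor_k` times the SD of the
#' baseline (pre-window) derivative are reported missing.
#'
#' @param movie An [optical_movie()].
#' @param window_ms Length-2 analysis window in ms (default: whole record).
#' @param noise_floor_k Upstroke validity multiple of the baseline
#'   derivative SD (default 5).
#' @param baseline_ms Length-2 baseline window for the noise floor; default
#'   everything before `window_ms[1]`, or the first 5% of frames when the
#'   window spans the whole recording.
#' @param refine `"parabolic"` or `"none"`.
#' @return An `activation_map`: list with `act_ms` (matrix, NA = missing),
#'   `upstroke` (max derivative, units/s), `fs`, `dx`, `stim_xy`.
#' @export
activation_map <- function(movie, window_ms = NULL, noise_floor_k = 5,
                           baseline_ms = NULL, refine = c("parabolic", "none")) {
  stopifnot(inherits(movie, "optical_movie"))
  refine <- match.arg(refine)
  d <- dim(movie$frames)
  t_ms <- (seq_len(d[1]) - 1L) / movie$fs * 1000
  if (is.null(window_ms)) window_ms <- range(t_ms)
  V <- matrix(movie$frames, d[1])
  D <- diff(V)                       # D[j, ] spans frames j -> j+1
  mid_ms <- (t_ms[-1] + t_ms[-d[1]]) / 2

  in_win <- mid_ms >= window_ms[1] & mid_ms <= window_ms[2]
  if (sum(in_win) < 3L) cq_stop("analysis window covers fewer than 3 frames")
  if (is.null(baseline_ms)) {
    baseline_ms <- if (window_ms[1] > t_ms[1]) c(t_ms[1], window_ms[1]) else
      c(t_ms[1], t_ms[max(3L, ceiling(d[1] * 0.05))])
  }
  in_base <- mid_ms >= baseline_ms[1] & mid_ms <= baseline_ms[2]

  Dw <- D[in_win, , drop = FALSE]
  widx <- which(in_win)
  jrel <- max.col(t(Dw), ties.method = "first")
  j <- widx[jrel]                    # global derivative index of the max
  n_px <- ncol(V)
  px <- seq_len(n_px)
  dmax <- Dw[cbind(jrel, px)]

  sd_base <- apply(D[in_base, , drop = FALSE], 2L, stats::sd)
  ok <- movie$mask[cbind(rep(seq_len(d[2]), d[3]) , rep(seq_len(d[3]), each = d[2]))] &
    (sd_base == 0 | dmax > noise_floor_k * sd_base) & dmax > 0

  if (refine == "parabolic") {
    jm <- pmax(j - 1L, 1L); jp <- pmin(j + 1L, nrow(D))
    ym <- D[cbind(jm, px)]; y0 <- dmax; yp <- D[cbind(jp, px)]
    den <- ym - 2 * y0 + yp
    delta <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (ym - yp) / den, 0)
    delta <- pmin(pmax(delta, -0.5), 0.5)
    act <- mid_ms[j] + delta * 1000 / movie$fs
  } else {
    act <- t_ms[j + 1L]
  }
  act[!ok] <- NA_real_
  upstroke <- dmax * movie$fs
  upstroke[!ok] <- NA_real_
  structure(
    list(act_ms = matrix(act, d[2], d[3]),
         upstroke = matrix(upstroke, d[2], d[3]),
         fs = movie$fs, dx = movie$dx, stim_xy = movie$stim_xy,
         window_ms = window_ms),
    class = "activation_map"
  )
}

# Fit activation time against absolute distance along one ray through the
# stimulation site. Returns the fit or raises a fit error.
fit_ray <- function(act, stim_xy, dx, angle, halfwidth_px, exclude_px,
                    min_points) {
  nr <- nrow(act$act_ms); nc <- ncol(act$act_ms)
  dy <- matrix(seq_len(nr), nr, nc) - stim_xy[1]
  dxm <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - stim_xy[2]
  e <- c(cos(angle), sin(angle))
  s <- e[1] * dxm + e[2] * dy          # px along ray
  p <- -e[2] * dxm + e[1] * dy         # px across ray
  sel <- abs(p) <= halfwidth_px & abs(s) >= exclude_px & is.finite(act$act_ms)
  if (sum(sel) < min_points) {
    cq_stop(sprintf("only %d valid pixels on ray at %.2f rad (need %d)",
                    sum(sel), angle, min_points),
            class = "cardioquant_fit_error")
  }
  dist_m <- abs(s[sel]) * dx * 1e-3
  t_ms <- act$act_ms[sel]
  fit <- stats::lm(t_ms ~ dist_m)
  slope <- unname(stats::coef(fit)[2])            # ms per m
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((t_ms - mean(t_ms))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  sigma <- sqrt(ss_res / max(1L, stats::df.residual(fit)))
  if (!is.finite(slope) || slope <= 0 || r2 < 0.5) {
    cq_stop(sprintf(
      "degenerate or non-monotone activation along ray at %.2f rad (slope %.3g ms/m, R2 %.2f)",
      angle, slope, r2),
      class = "cardioquant_fit_error",
      data = list(slope = slope, r_squared = r2, n = sum(sel)))
  }
  list(cv = 1000 / slope, slope_ms_per_m = slope, r_squared = r2,
       n = sum(sel), residual_sd_ms = sigma, angle = angle)
}

# Estimate the fast-axis orientation from the activation-time ellipse:
# t^2 is a quadratic form in the displacement, fitted by least squares;
# the eigenvector with the smallest coefficient is the fastest direction.
estimate_axis_angle <- function(act, stim_xy, dx) {
  nr <- nrow(act$act_ms); nc <- ncol(act$act_ms)
  dy <- (matrix(seq_len(nr), nr, nc) - stim_xy[1]) * dx * 1e-3
  dxm <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - stim_xy[2]) * dx * 1e-3
  sel <- is.finite(act$act_ms) & (abs(dy) > 0 | abs(dxm) > 0)
  if (sum(sel) < 6L) cq_stop("too few valid pixels to estimate the fiber axis",
                             class = "cardioquant_fit_error")
  t2 <- (act$act_ms[sel] - min(act$act_ms[sel], na.rm = TRUE))
  # use times relative to the map minimum (stimulus delay removed)
  t2 <- t2^2
  X <- cbind(dxm[sel]^2, 2 * dxm[sel] * dy[sel], dy[sel]^2)
  cf <- stats::coef(stats::lm(t2 ~ X - 1))
  M <- matrix(c(cf[1], cf[2], cf[2], cf[3]), 2L)
  ev <- eigen(M, symmetric = TRUE)
  fast <- ev$vectors[, which.min(abs(ev$values))]
  atan2(fast[2], fast[1])
}

#' Longitudinal and transverse conduction velocity
#'
#' Fits activation time versus distance by least squares along the ray
#' through the stimulation site at the fiber axis angle (longitudinal) and
#' its perpendicular (transverse); CV = 1/slope converted to m/s. If
#' `axis_angle` is not supplied it is estimated as the orientation of the
#' fastest direction (major axis of the activation-time ellipse), and the
#' faster of the two rays is then reported as longitudinal.
#'
#' @param act An [activation_map()].
#' @param stim_xy Stimulation site `c(row, col)`; defaults to the map's.
#' @param dx Pixel pitch (mm/pixel); defaults to the map's.
#' @param axis_angle Fiber axis angle in radians, or `NULL` to estimate.
#' @param halfwidth_px Half-width of the pixel band around each ray.
#' @param exclude_px Pixels closer than this to the stimulus are excluded.
#' @param min_points Minimum valid pixels per ray (default 5).
#' @return A `cv_estimate`: list with `cv_long`, `cv_trans` (m/s),
#'   `axis_angle`, `angle_supplied` and per-direction `fits` diagnostics.
#' @export
conduction_velocity <- function(act, stim_xy = act$stim_xy, dx = act$dx,
                                axis_angle = NULL, halfwidth_px = 0.6,
                                exclude_px = 1.5, min_points = 5L) {
  stopifnot(inherits(act, "activation_map"))
  supplied <- !is.null(axis_angle)
  if (!supplied) axis_angle <- estimate_axis_angle(act, stim_xy, dx)
  f1 <- fit_ray(act, stim_xy, dx, axis_angle, halfwidth_px, exclude_px, min_points)
  f2 <- fit_ray(act, stim_xy, dx, axis_angle + pi / 2, halfwidth_px, exclude_px, min_points)
  if (!supplied && f2$cv > f1$cv) {
    tmp <- f1; f1 <- f2; f2 <- tmp
    axis_angle <- axis_angle + pi / 2
  }
  structure(
    list(cv_long = f1$cv, cv_trans = f2$cv, axis_angle = axis_angle,
         angle_supplied = supplied, fits = list(long = f1, trans = f2)),
    class = "cv_estimate"
  )
}

#' Action potential duration at 80% repolarization
#'
#' APD80 is the time from activation until the signal first falls back to
#' 20% of its local action-potential amplitude, with linear interpolation
#' between samples. Amplitude is measured from the pre-upstroke baseline to
#' the post-activation peak.
#'
#' @param trace Numeric voltage trace for one pixel.
#' @param fs Sampling rate (frames/s).
#' @param act_time_ms Activation time in ms from trace start.
#' @param search_ms How far after activation to search (default: trace end).
#' @return APD80 in ms, or `NA` if the signal never repolarizes to 20%.
#' @examples
#' fs <- 10000; t <- seq(0, 100, by = 1000 / fs)
#' v <- ifelse(t >= 10 & t < 50, 1, 0)     # square pulse, D = 40 ms
#' apd80(v, fs, act_time_ms = 10)
#' @export
apd80 <- function(trace, fs, act_time_ms, search_ms = NULL) {
  check_positive(fs, "fs")
  t_ms <- (seq_along(trace) - 1L) / fs * 1000
  if (act_time_ms < t_ms[1] || act_time_ms > t_ms[length(t_ms)]) {
    cq_stop("`act_time_ms` lies outside the trace")
  }
  if (is.null(search_ms)) search_ms <- t_ms[length(t_ms)] - act_time_ms
  after <- which(t_ms >= act_time_ms & t_ms <= act_time_ms + search_ms)
  if (length(after) < 2L) return(NA_real_)
  before <- which(t_ms < act_time_ms)
  baseline <- if (length(before)) min(trace[before]) else min(trace[after[1]], 0)
  peak_rel <- which.max(trace[after])
  peak <- trace[after[peak_rel]]
  if (peak <= baseline) return(NA_real_)
  thr <- baseline + 0.2 * (peak - baseline)
  seg <- after[peak_rel:length(after)]
  below <- which(trace[seg] <= thr)
  if (!length(below)) return(NA_real_)
  i2 <- seg[below[1]]
  if (below[1] == 1L) return(t_ms[i2] - act_time_ms)
  i1 <- i2 - 1L
  frac <- (trace[i1] - thr) / (trace[i1] - trace[i2])
  t20 <- t_ms[i1] + frac * (t_ms[i2] - t_ms[i1])
  t20 - act_time_ms
}

#' Per-pixel APD80 map for a movie
#'
#' @param movie An [optical_movie()].
#' @param act An [activation_map()] for the same movie.
#' @param search_ms Search window after activation (ms).
#' @return Matrix of APD80 values (ms), NA where undefined.
#' @export
apd80_map <- function(movie, act, search_ms = NULL) {
  stopifnot(inherits(movie, "optical_movie"), inherits(act, "activation_map"))
  d <- dim(movie$frames)
  out <- matrix(NA_real_, d[2], d[3])
  for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    a <- act$act_ms[r, c]
    if (is.finite(a)) out[r, c] <- apd80(movie$frames[, r, c], movie$fs, a, search_ms)
  }
  out
}

#' Effective refractory period from an S1-S2 protocol
#'
#' Decrements the S1-S2 coupling interval from `s2_start_ms` by `step_ms`
#' until the first loss of capture; the ERP is the shortest coupling
#' interval that still captured. Capture at `s2_min_ms` (ERP below range)
#' or loss of capture already at `s2_start_ms` raise range errors.
#'
#' @param stimulate `function(s2_interval_ms) -> logical`, e.g. from
#'   [make_s1s2_runner()]; must report whether a propagated S2 activation
#'   occurred.
#' @param s2_start_ms First (longest) coupling interval tested, ms.
#' @param s2_min_ms Shortest coupling interval tested, ms.
#' @param step_ms Decrement step, ms (default 2).
#' @return ERP in ms (within one step above the true value).
#' @export
erp_s1s2 <- function(stimulate, s2_start_ms, s2_min_ms, step_ms = 2) {
  check_positive(step_ms, "step_ms")
  if (s2_start_ms <= s2_min_ms) cq_stop("`s2_start_ms` must exceed `s2_min_ms`")
  intervals <- seq(s2_start_ms, s2_min_ms, by = -step_ms)
  last_captured <- NA_real_
  for (s2 in intervals) {
    if (isTRUE(stimulate(s2))) {
      last_captured <- s2
    } else {
      if (is.na(last_captured)) {
        cq_stop(sprintf("no capture at the longest coupling interval (%g ms)", s2),
                class = "cardioquant_range_error")
      }
      return(last_captured)
    }
  }
  cq_stop(sprintf("still capturing at the shortest coupling interval (%g ms); ERP below range",
                  s2_min_ms),
          class = "cardioquant_range_error")
}

#' One-stop electrophysiology summary for a mapped heart
#'
#' Conditions the movie, computes the activation map, ray-regression
#' conduction velocities and the median pixelwise APD80, and optionally
#' attaches an ERP measured elsewhere.
#'
#' @param movie An [optical_movie()].
#' @param axis_angle Optional fiber axis angle (radians).
#' @param temporal_smooth_ms,spatial_smooth_px Conditioning parameters.
#' @param erp_ms Optional ERP (ms) from [erp_s1s2()].
#' @param ... Passed to [conduction_velocity()].
#' @return An `ep_summary`: list with `cv_long`, `cv_trans`, `apd80`,
#'   `erp`, `axis_angle`, `fit_diagnostics` and the intermediate
#'   `activation`. Supports [generics::tidy()] and [generics::glance()].
#' @export
ep_summary <- function(movie, axis_angle = NULL, temporal_smooth_ms = 0,
                       spatial_smooth_px = 0, erp_ms = NULL, ...) {
  cond <- condition_signals(movie, temporal_smooth_ms, spatial_smooth_px)
  act <- activation_map(cond)
  cv <- conduction_velocity(act, axis_angle = axis_angle, ...)
  apd <- apd80_map(cond, act)
  structure(
    list(cv_long = cv$cv_long, cv_trans = cv$cv_trans,
         apd80 = stats::median(apd, na.rm = TRUE),
         erp = if (is.null(erp_ms)) NA_real_ else erp_ms,
         axis_angle = cv$axis_angle,
         fit_diagnostics = cv$fits, activation = act),
    class = "ep_summary"
  )
}

#' @export
print.ep_summary <- function(x, ...) {
  cat("Optical-mapping EP summary\n")
  cat(sprintf("  CV longitudinal: %.3f m/s\n  CV transverse:   %.3f m/s\n",
              x$cv_long, x$cv_trans))
  cat(sprintf("  APD80 (median):  %.1f ms\n", x$apd80))
  if (is.finite(x$erp)) cat(sprintf("  ERP:             %.0f ms\n", x$erp))
  invisible(x)
}
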