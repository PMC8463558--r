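# Synthetic optical-mapping movie generator.
#
# Kinematic model: a point stimulus launches an anisotropic elliptical
# wavefront; the arrival time at a pixel with displacement (u, v) from the
# stimulus (u along the fiber axis, v across, in meters) is
#   t(p) = sqrt((u / cv_long)^2 + (v / cv_trans)^2).
# Every pixel then follows a stereotyped optical action potential: logistic
# upstroke whose maximum slope sits exactly at the arrival time, a plateau,
# and an exponential repolarization that reaches 20% of amplitude at
# activation + APD. Refractoriness is binary: a second stimulus captures
# and propagates iff its coupling interval is at least the ERP.

#' Ground-truth parameters for a synthetic optical-mapping movie
#'
#' @param cv_long,cv_trans Longitudinal / transverse conduction velocity in
#'   m/s; `cv_long >= cv_trans > 0`.
#' @param fiber_angle Fiber (fast-axis) angle in radians, measured from the
#'   +x (column) axis toward +y (row).
#' @param apd Action potential duration (APD80) in ms.
#' @param erp Effective refractory period in ms.
#' @param stim_xy Stimulation site as `c(row, col)`, 1-based; `NULL` (the
#'   default) places the stimulus at the grid centre when a movie is made.
#' @param dx Pixel pitch in mm/pixel.
#' @param fs Frame rate in frames/s.
#' @param noise_sd Additive Gaussian noise SD in normalized-voltage units.
#' @param tau_up Logistic upstroke time constant in ms.
#' @param seed Integer seed.
#' @return A list of class `wave_truth`.
#' @export
wave_truth <- function(cv_long = 0.5, cv_trans = 0.25, fiber_angle = 0,
                       apd = 40, erp = 60, stim_xy = NULL,
                       dx = 0.1, fs = 2000, noise_sd = 0, tau_up = 0.7,
                       seed = 1L) {
  check_positive(cv_trans, "cv_trans")
  if (cv_long < cv_trans) cq_stop("`cv_long` must be >= `cv_trans`")
  check_positive(apd, "apd"); check_positive(erp, "erp")
  check_positive(dx, "dx"); check_positive(fs, "fs")
  check_positive(tau_up, "tau_up")
  if (noise_sd < 0) cq_stop("`noise_sd` must be >= 0")
  structure(
    list(cv_long = cv_long, cv_trans = cv_trans, fiber_angle = fiber_angle,
         apd = apd, erp = erp,
         stim_xy = if (is.null(stim_xy)) NULL else as.integer(stim_xy),
         dx = dx,
         fs = fs, noise_sd = noise_sd, tau_up = tau_up,
         seed = as.integer(seed)),
    class = "wave_truth"
  )
}

# Closed-form elliptical arrival time (ms) for every pixel of an
# n_rows x n_cols grid.
wave_arrival_times <- function(truth, n_rows, n_cols) {
  r0 <- truth$stim_xy[1]; c0 <- truth$stim_xy[2]
  dy <- (matrix(seq_len(n_rows), n_rows, n_cols) - r0) * truth$dx * 1e-3      # m
  dxm <- (matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE) - c0) * truth$dx * 1e-3
  a <- truth$fiber_angle
  u <- cos(a) * dxm + sin(a) * dy   # along fiber
  v <- -sin(a) * dxm + cos(a) * dy  # across fiber
  1000 * sqrt((u / truth$cv_long)^2 + (v / truth$cv_trans)^2)               # ms
}

# Stereotyped optical action potential, s = time since activation (ms).
# Maximum slope of the upstroke is exactly at s = 0.
ap_shape <- function(s, apd, tau_up, plateau_frac = 0.3) {
  plateau <- plateau_frac * apd
  tau_r <- (apd - plateau) / log(5)
  repol <- ifelse(s <= plateau, 1, exp(-(pmax(s, plateau) - plateau) / tau_r))
  stats::plogis(s / tau_up) * repol
}

#' Generate a synthetic optical-mapping movie
#'
#' @param truth A [wave_truth()] object.
#' @param n_rows,n_cols Grid size in pixels.
#' @param duration_ms Recording length in ms.
#' @param s2_interval_ms Optional S1-S2 coupling interval (ms). The S2
#'   stimulus at the same site elicits a propagated second wave iff
#'   `s2_interval_ms >= truth$erp` (binary refractoriness).
#' @param stim_time_ms S1 stimulus time (ms from recording start), leaving
#'   a pre-stimulus baseline for noise-floor estimation.
#' @return An `optical_movie`: list with `frames` (`n_frames x n_rows x
#'   n_cols`, normalized 0..1 before noise), `fs`, `dx`, `stim_xy`, `mask`,
#'   `stim_time_ms`, `truth` and `act_truth_ms` (S1 arrival-time matrix,
#'   ms from recording start).
#' @examples
#' mv <- make_optical_movie(wave_truth(seed = 2), 32, 32, duration_ms = 60)
#' dim(mv$frames)
#' @export
make_optical_movie <- function(truth, n_rows, n_cols, duration_ms,
                               s2_interval_ms = NULL, stim_time_ms = 5) {
  stopifnot(inherits(truth, "wave_truth"))
  check_positive(n_rows, "n_rows"); check_positive(n_cols, "n_cols")
  check_positive(duration_ms, "duration_ms")
  if (is.null(truth$stim_xy)) {
    truth$stim_xy <- c((n_rows + 1L) %/% 2L, (n_cols + 1L) %/% 2L)
  }
  if (truth$stim_xy[1] < 1 || truth$stim_xy[1] > n_rows ||
      truth$stim_xy[2] < 1 || truth$stim_xy[2] > n_cols) {
    cq_stop("stimulation site lies outside the grid")
  }
  arr <- wave_arrival_times(truth, n_rows, n_cols)
  act1 <- stim_time_ms + arr
  n_frames <- max(2L, round(duration_ms * truth$fs / 1000))
  t_ms <- (seq_len(n_frames) - 1L) / truth$fs * 1000
  n_px <- n_rows * n_cols

  S1 <- matrix(t_ms, n_frames, n_px) -
    matrix(as.vector(act1), n_frames, n_px, byrow = TRUE)
  V <- ap_shape(S1, truth$apd, truth$tau_up)
  captured <- FALSE
  if (!is.null(s2_interval_ms)) {
    captured <- s2_interval_ms >= truth$erp
    if (captured) {
      act2 <- act1 + s2_interval_ms
      S2 <- matrix(t_ms, n_frames, n_px) -
        matrix(as.vector(act2), n_frames, n_px, byrow = TRUE)
      V <- pmax(V, ap_shape(S2, truth$apd, truth$tau_up))
    }
  }
  V <- V / max(V)
  if (truth$noise_sd > 0) {
    V <- V + withr::with_seed(truth$seed,
                              matrix(stats::rnorm(length(V), 0, truth$noise_sd),
                                     nrow(V), ncol(V)))
  }
  frames <- array(V, dim = c(n_frames, n_rows, n_cols))
  optical_movie(frames, fs = truth$fs, dx = truth$dx, stim_xy = truth$stim_xy,
                stim_time_ms = stim_time_ms, truth = truth,
                act_truth_ms = act1, s2_interval_ms = s2_interval_ms,
                s2_captured = captured)
}

#' Construct an optical-mapping movie object
#'
#' Container for a voltage movie with its acquisition metadata; use this for
#' movies from real recordings, or let [make_optical_movie()] build one.
#'
#' @param frames 3-D voltage array, `n_frames x n_rows x n_cols`.
#' @param fs Frame rate (frames/s).
#' @param dx Pixel pitch (mm/pixel).
#' @param stim_xy Stimulation site `c(row, col)`, 1-based.
#' @param mask Logical matrix of valid pixels (default all valid).
#' @param stim_time_ms Stimulus time in ms (default 0).
#' @param ... Extra fields stored on the object (e.g. generator truth).
#' @return A list of class `optical_movie`.
#' @export
optical_movie <- function(frames, fs, dx, stim_xy,
                          mask = NULL, stim_time_ms = 0, ...) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  check_positive(fs, "fs"); check_positive(dx, "dx")
  nr <- dim(frames)[2]; nc <- dim(frames)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(dim(mask) == c(nr, nc))
  if (!mask[stim_xy[1], stim_xy[2]]) cq_stop("stimulation site must be inside the mask")
  structure(
    c(list(frames = frames, fs = fs, dx = dx, stim_xy = as.integer(stim_xy),
           mask = mask, stim_time_ms = stim_time_ms), list(...)),
    class = "optical_movie"
  )
}

#' S1-S2 protocol runner backed by the synthetic generator
#'
#' Returns a closure suitable for [erp_s1s2()]: for a given S1-S2 coupling
#' interval it generates a movie, and reports capture if a propagated second
#' upstroke is detected at probe pixels at least `capture_radius_mm` from
#' the stimulation site (second-window maximum derivative exceeding half the
#' S1 upstroke derivative at the same pixel).
#'
#' @param truth A [wave_truth()] object.
#' @param n_rows,n_cols Grid size.
#' @param capture_radius_mm Minimum probe distance from the stimulus (mm).
#' @return `function(s2_interval_ms) -> logical`.
#' @export
make_s1s2_runner <- function(truth, n_rows = 24L, n_cols = 24L,
                             capture_radius_mm = 1) {
  force(n_rows); force(n_cols); force(capture_radius_mm)
  if (is.null(truth$stim_xy)) {
    truth$stim_xy <- c((n_rows + 1L) %/% 2L, (n_cols + 1L) %/% 2L)
  }
  function(s2_interval_ms) {
    stim_time <- 5
    arr <- wave_arrival_times(truth, n_rows, n_cols)
    duration <- stim_time + s2_interval_ms + max(arr) + truth$apd + 20
    mv <- make_optical_movie(truth, n_rows, n_cols, duration_ms = duration,
                             s2_interval_ms = s2_interval_ms,
                             stim_time_ms = stim_time)
    r0 <- truth$stim_xy[1]; c0 <- truth$stim_xy[2]
    dist_mm <- sqrt(outer((seq_len(n_rows) - r0)^2, (seq_len(n_cols) - c0)^2, "+")) * truth$dx
    probes <- which(dist_mm >= capture_radius_mm & dist_mm <= capture_radius_mm + 1)
    if (length(probes) == 0L) cq_stop("no probe pixels beyond the capture radius")
    t_ms <- (seq_len(dim(mv$frames)[1]) - 1L) / truth$fs * 1000
    V <- matrix(mv$frames, dim(mv$frames)[1])[, probes, drop = FALSE]
    D <- diff(V)
    td <- t_ms[-1]
    s1_arr <- stim_time + arr[probes]
    cap <- logical(length(probes))
    for (j in seq_along(probes)) {
      w1 <- td >= stim_time & td <= s1_arr[j] + 5
      w2 <- td >= s1_arr[j] + s2_interval_ms - 2
      if (!any(w2)) next
      cap[j] <- max(D[w2, j]) > 0.5 * max(D[w1, j])
    }
    mean(cap) > 0.5
  }
}
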