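# ECG interval measurement and paired cohort comparison.
#
# The QRS end is strictly the time at which the S wave crosses the
# isoelectric line (linear interpolation between samples); the murine
# J wave, which immediately follows the S wave, is therefore excluded from
# the QRS by construction. The isoelectric level is the median of a pre-P
# baseline window. PR runs from P onset to QRS onset.

#' Detect R-peak beat anchors
#'
#' Deterministic energy-based detector: the squared first difference is
#' smoothed with a short moving average, regions above a fraction of the
#' maximum energy are candidate beats, and the anchor is the voltage
#' maximum within each region.
#'
#' @param trace An `ecg_trace` (see [ecg_trace()] / [make_ecg()]).
#' @param energy_window_ms Moving-average window for the energy (ms).
#' @param threshold_frac Energy threshold as a fraction of the maximum.
#' @param min_gap_ms Minimum gap between anchors; default 25% of the median
#'   candidate spacing (merges split regions).
#' @return Integer vector of anchor sample indices (1-based).
#' @export
detect_beats <- function(trace, energy_window_ms = 3, threshold_frac = 0.3,
                         min_gap_ms = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  v <- trace$samples
  fs <- trace$fs
  if (length(v) < fs * 0.05) cq_stop("trace too short for beat detection",
                                     class = "cardioquant_detection_error")
  d <- c(0, diff(v))
  wlen <- max(1L, round(energy_window_ms * fs / 1000))
  e <- as.numeric(stats::filter(d^2, rep(1 / wlen, wlen), sides = 2))
  e[is.na(e)] <- 0
  emax <- max(e)
  if (emax <= 0 || stats::sd(v) == 0) {
    cq_stop("no beats found: trace has no energy",
            class = "cardioquant_detection_error")
  }
  above <- e > threshold_frac * emax
  # contiguous suprathreshold regions
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts, ends)[r$values, , drop = FALSE]
  if (nrow(regions) == 0L) {
    cq_stop("no beats found above the energy threshold",
            class = "cardioquant_detection_error")
  }
  anchors <- apply(regions, 1L, function(rg) {
    rg[1] - 1L + which.max(v[rg[1]:rg[2]])
  })
  anchors <- sort(unique(anchors))
  if (length(anchors) > 1L) {
    gap <- if (is.null(min_gap_ms)) 0.25 * stats::median(diff(anchors)) else
      min_gap_ms * fs / 1000
    keep <- c(TRUE, diff(anchors) > gap)
    # within a merged group keep the largest peak
    grp <- cumsum(keep)
    anchors <- vapply(split(anchors, grp), function(ix) ix[which.max(v[ix])],
                      numeric(1))
    anchors <- as.integer(sort(anchors))
  }
  anchors
}

#' Average beats into a template
#'
#' Fixed windows (55% of the beat period before the anchor, 45% after) are
#' extracted around each anchor and averaged sample-wise. If fewer than `n`
#' anchors have a full window, all available ones are averaged and
#' `n_averaged` records how many.
#'
#' @param trace An `ecg_trace`.
#' @param anchors Anchor indices from [detect_beats()].
#' @param n Number of beats to average (default 100).
#' @return A `beat_template`: list with `samples`, `fs`, `n_averaged`,
#'   `rr_ms` (median anchor spacing) and `r_index` (anchor position within
#'   the template).
#' @export
average_beats <- function(trace, anchors, n = 100L) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (length(anchors) < 1L) cq_stop("no anchors to average",
                                    class = "cardioquant_detection_error")
  fs <- trace$fs
  v <- trace$samples
  rr <- if (length(anchors) > 1L) stats::median(diff(anchors)) else
    round(0.8 * length(v))
  pre <- round(0.55 * rr); post <- round(0.45 * rr)
  usable <- anchors[anchors - pre >= 1L & anchors + post <= length(v)]
  if (length(usable) == 0L) cq_stop("no anchor has a full averaging window",
                                    class = "cardioquant_detection_error")
  usable <- usable[seq_len(min(n, length(usable)))]
  seg <- vapply(usable, function(a) v[(a - pre):(a + post)],
                numeric(pre + post + 1L))
  structure(
    list(samples = rowMeans(seg), fs = fs, n_averaged = length(usable),
         rr_ms = rr / fs * 1000, r_index = pre + 1L),
    class = "beat_template"
  )
}

# Backward scan from a peak: latest run of `m` consecutive samples within
# `thr` of the isoelectric level; returns the index of the last baseline
# sample (the onset).
scan_onset <- function(v, peak_idx, iso, thr, m, lo = 1L) {
  run <- 0L
  for (i in seq(peak_idx - 1L, lo)) {
    if (abs(v[i] - iso) <= thr) {
      run <- run + 1L
      if (run >= m) return(i + run - 1L)
    } else {
      run <- 0L
    }
    if (i == lo) break
  }
  NA_integer_
}

#' Measure PR and QRS intervals from an averaged beat
#'
#' QRS onset is the first sustained departure from the isoelectric level
#' before the R peak (threshold `k_onset` baseline SDs); the QRS end is the
#' first crossing of the isoelectric line after the S nadir, linearly
#' interpolated between samples, so a J wave following the S wave never
#' extends the QRS. PR runs from the analogously detected P onset to QRS
#' onset. The isoelectric level is the median of a pre-P baseline window
#' (up to 20% of the beat period ending at P onset).
#'
#' @param template A `beat_template` from [average_beats()].
#' @param k_onset Departure threshold in baseline-SD multiples (default 4).
#' @param s_search_frac S-nadir search window after R as a fraction of the
#'   beat period (default 0.35).
#' @return A one-row tibble (class `interval_set`) with `pr`, `qrs` (ms) and
#'   `heart_rate` (beats/min); fiducial sample positions are attached as the
#'   `fiducials` attribute. A missing S-wave crossing yields `qrs = NA` with
#'   a diagnostic attribute.
#' @export
measure_intervals <- function(template, k_onset = 4, s_search_frac = 0.35) {
  stopifnot(inherits(template, "beat_template"))
  v <- template$samples
  fs <- template$fs
  nper <- round(template$rr_ms * fs / 1000)

  iso0 <- stats::median(v[seq_len(max(3L, round(0.12 * length(v))))])
  base_seg <- v[seq_len(max(3L, round(0.12 * length(v))))]
  sd_b <- stats::sd(base_seg)
  amp <- max(v) - iso0
  thr <- max(k_onset * sd_b, 1e-9, 1e-6 * amp)
  m <- max(2L, round(0.4e-3 * fs))

  r_idx <- which.max(v)
  qrs_on <- scan_onset(v, r_idx, iso0, thr, m)
  if (is.na(qrs_on)) {
    cq_stop("QRS onset not detectable above the noise floor",
            class = "cardioquant_detection_error")
  }
  # P wave: largest positive deflection before the QRS onset
  p_lo <- max(1L, qrs_on - round(0.6 * nper))
  p_hi <- max(p_lo + 1L, qrs_on - m)
  p_idx <- p_lo - 1L + which.max(v[p_lo:p_hi])
  p_on <- scan_onset(v, p_idx, iso0, thr, m, lo = p_lo)
  if (is.na(p_on) || v[p_idx] - iso0 < thr) p_on <- NA_integer_

  # refined isoelectric level: pre-P baseline window
  if (!is.na(p_on)) {
    b_lo <- max(1L, p_on - round(0.2 * nper))
    iso <- stats::median(v[b_lo:p_on])
  } else {
    iso <- iso0
  }

  # S nadir after R, then first isoelectric crossing
  s_hi <- min(length(v), r_idx + round(s_search_frac * nper))
  s_idx <- r_idx - 1L + which.min(v[r_idx:s_hi])
  qrs_ms <- NA_real_
  diag <- NULL
  if (v[s_idx] >= iso) {
    diag <- "no S wave below the isoelectric line"
  } else {
    seg <- s_idx:length(v)
    cross <- which(v[seg] >= iso)
    if (!length(cross)) {
      diag <- "S wave never crosses the isoelectric line in the search window"
    } else {
      i2 <- seg[cross[1]]
      i1 <- i2 - 1L
      frac <- (iso - v[i1]) / (v[i2] - v[i1])
      end_t <- (i1 - 1L + frac) / fs * 1000
      qrs_ms <- end_t - (qrs_on - 1L) / fs * 1000
    }
  }
  pr_ms <- if (is.na(p_on)) NA_real_ else (qrs_on - p_on) / fs * 1000

  out <- tibble::tibble(
    pr = pr_ms, qrs = qrs_ms,
    heart_rate = 60000 / template$rr_ms
  )
  attr(out, "fiducials") <- c(p_onset = p_on, qrs_onset = qrs_on,
                              r_peak = r_idx, s_nadir = s_idx)
  attr(out, "isoelectric_mv") <- iso
  if (!is.null(diag)) attr(out, "diagnostic") <- diag
  class(out) <- c("interval_set", class(out))
  out
}

#' Measure ECG intervals from a raw trace
#'
#' Convenience wrapper: [detect_beats()], [average_beats()] over up to
#' `n_average` beats, then [measure_intervals()].
#'
#' @param trace An `ecg_trace`.
#' @param n_average Beats to average (default 100).
#' @param ... Passed to [measure_intervals()].
#' @return An `interval_set` tibble; the template is attached as attribute.
#' @export
ecg_intervals <- function(trace, n_average = 100L, ...) {
  anchors <- detect_beats(trace)
  tpl <- average_beats(trace, anchors, n = n_average)
  out <- measure_intervals(tpl, ...)
  attr(out, "template") <- tpl
  out
}

#' Robust QRS shortening
#'
#' A serial-ECG pair shows robust shortening when the QRS interval decreases
#' by at least `threshold_ms` (default 25 ms): `pre - post >= threshold_ms`.
#' Vectorized over pairs.
#'
#' @param pre_qrs_ms,post_qrs_ms QRS durations in ms (positive).
#' @param threshold_ms Shortening threshold in ms (default 25).
#' @return Logical vector.
#' @examples
#' robust_shortening(165, 130)   # TRUE: 35 ms decrease
#' robust_shortening(149, 139)   # FALSE: 10 ms decrease
#' @export
robust_shortening <- function(pre_qrs_ms, post_qrs_ms, threshold_ms = 25) {
  if (any(pre_qrs_ms <= 0) || any(post_qrs_ms <= 0)) {
    cq_stop("QRS durations must be positive")
  }
  (pre_qrs_ms - post_qrs_ms) >= threshold_ms
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ties among the absolute differences get
#' mid-ranks. For fewer than `exact_below` non-zero pairs the exact null
#' distribution of the signed-rank statistic is computed by dynamic
#' programming over all sign assignments (valid with mid-ranks); otherwise a
#' normal approximation with continuity and tie correction is used. The
#' two-sided p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y Paired numeric vectors (equal length), or differences in `x`
#'   with `y = NULL`.
#' @param exact_below Use the exact distribution when the number of non-zero
#'   differences is below this (default 20).
#' @return A list of class `cq_wilcoxon` with `statistic` (W, the positive
#'   rank sum), `p_value`, `n_used`, `method`.
#' @export
paired_wilcoxon <- function(x, y = NULL, exact_below = 20L) {
  d <- if (is.null(y)) as.numeric(x) else {
    if (length(x) != length(y)) cq_stop("`x` and `y` must have equal length")
    as.numeric(x) - as.numeric(y)
  }
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                          method = "degenerate"), class = "cq_wilcoxon"))
  }
  r <- rank(abs(d))                   # mid-ranks for ties
  w <- sum(r[d > 0])
  if (n < exact_below) {
    # DP over the distribution of the positive rank sum; ranks doubled so
    # mid-ranks (.5) become integers
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    cnt <- c(1, rep(0, total))        # cnt[s+1] = #assignments with sum s
    for (rk in r2) {
      shifted <- c(rep(0, rk), cnt[seq_len(total + 1L - rk)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank (DP over sign assignments)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  structure(list(statistic = w, p_value = p, n_used = n, method = method),
            class = "cq_wilcoxon")
}

#' @export
print.cq_wilcoxon <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat(sprintf("  W = %g, n = %d, two-sided p = %.5g\n",
              x$statistic, x$n_used, x$p_value))
  invisible(x)
}

#' Paired pre/post QRS cohort comparison
#'
#' Assembles the per-subject deltas, flags robust shortening
#' (>= `threshold_ms`), and tests pre vs post with the two-sided paired
#' Wilcoxon signed-rank test.
#'
#' @param pre,post Paired QRS durations in ms (by subject).
#' @param threshold_ms Robust-shortening threshold (default 25).
#' @param subject Optional subject identifiers.
#' @return A `paired_ecg_comparison`: list with `table` (tibble: subject,
#'   pre, post, delta = pre - post, robust), `p_value`, `n`, `n_robust`,
#'   `n_shortened`, `mean_pre`, `sd_pre`, `mean_post`, `sd_post`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
compare_qrs <- function(pre, post, threshold_ms = 25, subject = NULL) {
  if (length(pre) != length(post)) cq_stop("`pre` and `post` must be paired")
  if (is.null(subject)) subject <- seq_along(pre)
  delta <- pre - post
  tab <- tibble::tibble(
    subject = subject, pre = pre, post = post, delta = delta,
    robust = robust_shortening(pre, post, threshold_ms)
  )
  wt <- paired_wilcoxon(pre, post)
  structure(
    list(table = tab, p_value = wt$p_value, statistic = wt$statistic,
         method = wt$method, n = length(pre),
         n_robust = sum(tab$robust), n_shortened = sum(delta > 0),
         n_lengthened = sum(delta < 0),
         mean_pre = mean(pre), sd_pre = stats::sd(pre),
         mean_post = mean(post), sd_post = stats::sd(post),
         threshold_ms = threshold_ms),
    class = "paired_ecg_comparison"
  )
}

#' @export
print.paired_ecg_comparison <- function(x, ...) {
  cat(sprintf("Paired QRS comparison, n = %d\n", x$n))
  cat(sprintf("  pre:  %.0f +/- %.0f ms\n  post: %.0f +/- %.0f ms\n",
              x$mean_pre, x$sd_pre, x$mean_post, x$sd_post))
  cat(sprintf("  shortened: %d, lengthened: %d, robust (>= %g ms): %d\n",
              x$n_shortened, x$n_lengthened, x$threshold_ms, x$n_robust))
  cat(sprintf("  two-sided Wilcoxon signed-rank p = %.4g\n", x$p_value))
  invisible(x)
}
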