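# Synthetic ECG generator.
#
# Beats are rendered from a piecewise-linear template: a triangular P wave,
# a QRS complex whose S wave crosses the isoelectric line exactly `qrs` ms
# after QRS onset, an optional murine J wave immediately after the S wave,
# and a T wave. Piecewise linearity makes every fiducial exactly
# recoverable from the noise-free template.

#' Ground-truth parameters for a synthetic ECG
#'
#' @param heart_rate Beats per minute (default 600, murine).
#' @param pr PR interval in ms (P onset to QRS onset).
#' @param qrs QRS duration in ms (QRS onset to the S-wave isoelectric
#'   crossing; the J wave is not part of the QRS).
#' @param has_j_wave Include a murine J wave after the S wave?
#' @param n_beats Number of beats.
#' @param fs Sampling rate in samples/s (default 4000).
#' @param noise_sd Additive Gaussian noise SD in mV.
#' @param jitter_sd_ms SD of per-beat timing jitter in ms (default 0).
#' @param amplitudes Named list overriding `p`, `r`, `s`, `j`, `t` wave
#'   amplitudes in mV.
#' @param seed Integer seed.
#' @return A list of class `ecg_truth`.
#' @export
ecg_truth <- function(heart_rate = 600, pr = 38, qrs = 12, has_j_wave = TRUE,
                      n_beats = 120L, fs = 4000, noise_sd = 0.01,
                      jitter_sd_ms = 0, amplitudes = list(), seed = 1L) {
  check_positive(heart_rate, "heart_rate")
  check_positive(pr, "pr"); check_positive(qrs, "qrs"); check_positive(fs, "fs")
  if (n_beats < 0) cq_stop("`n_beats` must be >= 0")
  if (noise_sd < 0 || jitter_sd_ms < 0) cq_stop("noise and jitter SDs must be >= 0")
  period <- 60000 / heart_rate
  if (pr + qrs >= period) cq_stop("`pr` + `qrs` must be shorter than the beat period")
  amp <- utils::modifyList(list(p = 0.15, r = 1.0, s = 0.5, j = 0.25, t = 0.2),
                           amplitudes)
  structure(
    list(heart_rate = heart_rate, pr = pr, qrs = qrs,
         has_j_wave = isTRUE(has_j_wave), n_beats = as.integer(n_beats),
         fs = fs, noise_sd = noise_sd, jitter_sd_ms = jitter_sd_ms,
         amplitudes = amp, seed = as.integer(seed)),
    class = "ecg_truth"
  )
}

# Piecewise-linear beat template. Returns knots (ms, mV) and fiducials
# relative to the beat start.
ecg_beat_knots <- function(truth) {
  period <- 60000 / truth$heart_rate
  a <- truth$amplitudes
  p_onset <- 0.10 * period
  p_dur <- min(0.35 * truth$pr, 0.12 * period)
  qrs_on <- p_onset + truth$pr
  r_peak <- qrs_on + 0.25 * truth$qrs
  s_nadir <- qrs_on + 0.75 * truth$qrs
  qrs_end <- qrs_on + truth$qrs
  j_dur <- if (truth$has_j_wave) min(8, 0.8 * truth$qrs) else 0
  t_on <- qrs_end + j_dur + 0.05 * period
  t_dur <- 0.22 * period
  if (t_on + t_dur >= period) {
    cq_stop("beat morphology does not fit in the beat period; lower pr/qrs or heart_rate")
  }
  knots_t <- c(0, p_onset, p_onset + p_dur / 2, p_onset + p_dur,
               qrs_on, r_peak, s_nadir, qrs_end)
  knots_v <- c(0, 0, a$p, 0, 0, a$r, -a$s, 0)
  if (truth$has_j_wave) {
    knots_t <- c(knots_t, qrs_end + 0.4 * j_dur, qrs_end + j_dur)
    knots_v <- c(knots_v, a$j, 0)
  }
  knots_t <- c(knots_t, t_on, t_on + t_dur / 2, t_on + t_dur, period)
  knots_v <- c(knots_v, 0, a$t, 0, 0)
  list(
    t = knots_t, v = knots_v, period = period,
    fiducials = c(p_onset = p_onset, qrs_onset = qrs_on, r_peak = r_peak,
                  s_nadir = s_nadir, qrs_end = qrs_end, j_dur = j_dur)
  )
}

#' Generate a synthetic ECG trace
#'
#' @param truth An [ecg_truth()] object.
#' @return An `ecg_trace`: list with `samples` (mV), `fs`, `truth`,
#'   `r_times_ms` (ground-truth R-peak times), `template` (one noise-free
#'   beat) and `fiducials` (ms relative to beat start).
#' @examples
#' ecg <- make_ecg(ecg_truth(n_beats = 10, noise_sd = 0))
#' length(ecg$samples) / ecg$fs   # seconds
#' @export
make_ecg <- function(truth) {
  stopifnot(inherits(truth, "ecg_truth"))
  kn <- ecg_beat_knots(truth)
  fs <- truth$fs
  n_per_beat <- round(kn$period * fs / 1000)
  n_total <- truth$n_beats * n_per_beat
  if (n_total == 0L) {
    return(structure(list(samples = numeric(0), fs = fs, truth = truth,
                          r_times_ms = numeric(0), template = numeric(0),
                          fiducials = kn$fiducials),
                     class = "ecg_trace"))
  }
  tt <- (seq_len(n_per_beat) - 1L) / fs * 1000
  template <- stats::approx(kn$t, kn$v, xout = tt, rule = 2)$y

  samples <- numeric(n_total)
  withr::with_seed(truth$seed, {
    jitter <- if (truth$jitter_sd_ms > 0) {
      round(stats::rnorm(truth$n_beats, 0, truth$jitter_sd_ms) * fs / 1000)
    } else rep(0L, truth$n_beats)
    starts <- (seq_len(truth$n_beats) - 1L) * n_per_beat + jitter
    for (b in seq_len(truth$n_beats)) {
      idx <- starts[b] + seq_len(n_per_beat)
      keep <- idx >= 1L & idx <= n_total
      samples[idx[keep]] <- samples[idx[keep]] + template[keep]
    }
    if (truth$noise_sd > 0) {
      samples <- samples + stats::rnorm(n_total, 0, truth$noise_sd)
    }
  })
  r_times <- (starts / fs * 1000) + kn$fiducials[["r_peak"]]
  structure(
    list(samples = samples, fs = fs, truth = truth, r_times_ms = r_times,
         template = template, fiducials = kn$fiducials,
         period_ms = kn$period),
    class = "ecg_trace"
  )
}

#' Construct an ECG trace object from raw samples
#'
#' @param samples Voltage samples in mV.
#' @param fs Sampling rate in samples/s.
#' @param lead_label Lead name (default "II").
#' @return An `ecg_trace`.
#' @export
ecg_trace <- function(samples, fs, lead_label = "II") {
  check_positive(fs, "fs")
  if (!all(is.finite(samples))) cq_stop("`samples` must be finite")
  structure(list(samples = as.numeric(samples), fs = fs,
                 lead_label = lead_label),
            class = "ecg_trace")
}
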