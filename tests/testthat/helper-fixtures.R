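# Shared helpers: small deterministic fixtures built in code.

mouse_ecg <- function(qrs = 12, pr = 38, heart_rate = 600, noise_sd = 0,
                      n_beats = 20L, has_j_wave = TRUE, fs = 4000, seed = 1L) {
  make_ecg(ecg_truth(heart_rate = heart_rate, pr = pr, qrs = qrs,
                     has_j_wave = has_j_wave, n_beats = n_beats,
                     fs = fs, noise_sd = noise_sd, seed = seed))
}

small_movie <- function(cv_long = 0.5, cv_trans = 0.25, noise_sd = 0,
                        n = 40L, fiber_angle = 0, seed = 1L, fs = 2000,
                        duration_ms = 70, ...) {
  tr <- wave_truth(cv_long = cv_long, cv_trans = cv_trans,
                   fiber_angle = fiber_angle, stim_xy = c(n %/% 2L, n %/% 2L),
                   noise_sd = noise_sd, fs = fs, seed = seed, ...)
  make_optical_movie(tr, n, n, duration_ms = duration_ms)
}

# exhaustive signed-rank oracle: two-sided p over all 2^n sign assignments
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
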