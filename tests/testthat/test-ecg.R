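test_that("beat detection finds every R peak deterministically", {
  # 60 bpm, 10 s, noise-free: exactly 10 anchors at the generated R times
  e <- make_ecg(ecg_truth(heart_rate = 60, pr = 160, qrs = 100,
                          has_j_wave = FALSE, n_beats = 10, fs = 1000,
                          noise_sd = 0, seed = 2))
  an <- detect_beats(e)
  expect_length(an, 10L)
  truth_samples <- round(e$r_times_ms * e$fs / 1000) + 1L
  expect_lte(max(abs(an - truth_samples)), 1L)

  expect_identical(detect_beats(e), an)
  expect_error(detect_beats(ecg_trace(rep(0, 4000), fs = 4000)),
               class = "cardioquant_detection_error")
})

test_that("beat averaging reduces noise by the square root of the count", {
  e0 <- mouse_ecg(noise_sd = 0, n_beats = 104)
  anchors <- detect_beats(e0)

  # identical noise-free beats: template equals a single segment
  tpl1 <- average_beats(e0, anchors, n = 1)
  tpl100 <- average_beats(e0, anchors, n = 100)
  expect_equal(tpl100$n_averaged, 100L)
  expect_equal(tpl1$samples, tpl100$samples, tolerance = 1e-12)

  # additive white noise sd sigma, n = 100 -> residual SD ~ sigma / 10
  sigma <- 0.05
  resid_sd <- withr::with_seed(21, {
    vapply(1:50, function(i) {
      noisy <- ecg_trace(e0$samples + stats::rnorm(length(e0$samples), 0, sigma),
                         fs = e0$fs)
      tpl <- average_beats(noisy, anchors, n = 100)
      stats::sd(tpl$samples - tpl100$samples)
    }, numeric(1))
  })
  expect_lt(abs(mean(resid_sd) - sigma / 10) / (sigma / 10), 0.2)
})

test_that("QRS measurement follows the S-wave crossing rule and excludes the J wave", {
  for (qrs in c(8, 12, 16, 20)) {
    e <- mouse_ecg(qrs = qrs, heart_rate = 450, noise_sd = 0)
    iv <- measure_intervals(average_beats(e, detect_beats(e)))
    expect_lt(abs(iv$qrs - qrs), 1000 / e$fs + 1e-9)   # within 1 sample at 4 kHz
    expect_lt(abs(iv$pr - 38), 1000 / e$fs + 1e-9)
  }

  # human-scale morphologies at 1 kHz
  for (qrs in c(80, 140, 200)) {
    e <- make_ecg(ecg_truth(heart_rate = 60, pr = 160, qrs = qrs,
                            has_j_wave = FALSE, fs = 1000, n_beats = 12,
                            noise_sd = 0, seed = 3))
    iv <- measure_intervals(average_beats(e, detect_beats(e)))
    expect_lt(abs(iv$qrs - qrs), 1000 / e$fs + 1e-9)
    expect_lt(abs(iv$pr - 160), 1000 / e$fs + 1e-9)
  }

  # the J wave does not change the measured QRS
  ej <- mouse_ecg(qrs = 12, has_j_wave = TRUE, noise_sd = 0)
  en <- mouse_ecg(qrs = 12, has_j_wave = FALSE, noise_sd = 0)
  ivj <- measure_intervals(average_beats(ej, detect_beats(ej)))
  ivn <- measure_intervals(average_beats(en, detect_beats(en)))
  expect_equal(ivj$qrs, ivn$qrs, tolerance = 1e-9)

  # a constant DC offset leaves the intervals unchanged
  tpl <- average_beats(ej, detect_beats(ej))
  tpl_dc <- tpl
  tpl_dc$samples <- tpl$samples + 0.7
  iv_dc <- measure_intervals(tpl_dc)
  expect_equal(iv_dc$qrs, ivj$qrs, tolerance = 1e-9)
  expect_equal(iv_dc$pr, ivj$pr, tolerance = 1e-9)

  # heart rate comes from the anchor spacing
  expect_equal(ivj$heart_rate, 600, tolerance = 0.01)
})

test_that("robust shortening is exact at the 25 ms boundary and monotone", {
  expect_true(robust_shortening(165, 130))    # 35 ms decrease
  expect_false(robust_shortening(149, 139))   # 10 ms decrease
  expect_false(robust_shortening(150, 150))
  expect_true(robust_shortening(150, 125))    # exactly at threshold
  expect_false(robust_shortening(150, 126))
  deltas <- seq(-10, 40, by = 5)
  flags <- robust_shortening(150 + deltas, rep(150, length(deltas)))
  expect_true(all(diff(as.integer(flags)) >= 0))  # monotone in pre - post
  expect_error(robust_shortening(-1, 10), class = "cardioquant_param_error")
})

test_that("the signed-rank test matches exhaustive enumeration and wilcox.test", {
  # brute-force oracle over all sign assignments, n <= 8
  withr::with_seed(7, {
    for (n in c(5, 6, 7, 8)) {
      for (rep in 1:5) {
        d <- round(stats::rnorm(n, 0.3, 1), 2)
        d <- d[d != 0]
        if (length(d) < 2) next
        expect_equal(paired_wilcoxon(d)$p_value, brute_wilcoxon_p(d),
                     tolerance = 1e-12)
      }
    }
  })

  # n = 6, all differences positive: exact two-sided p = 2/64
  expect_equal(paired_wilcoxon(c(3, 4, 5, 6, 7, 8), rep(0, 6))$p_value,
               2 / 64)

  # agrees with the reference implementation when no ties are present
  withr::with_seed(31, {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    expect_equal(paired_wilcoxon(x, y)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    x2 <- stats::rnorm(30); y2 <- stats::rnorm(30)
    expect_equal(paired_wilcoxon(x2, y2)$p_value,
                 stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                                    correct = TRUE)$p.value,
                 tolerance = 1e-9)
  })

  # identical pairs: p = 1 with a warning
  expect_warning(res <- paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$p_value, 1)
})

test_that("paired cohort comparison assembles deltas, flags and the test", {
  cmp <- compare_qrs(c(165, 149, 140), c(130, 139, 150),
                     subject = c("G", "mean", "x"))
  expect_equal(cmp$table$delta, c(35, 10, -10))
  expect_equal(cmp$table$robust, c(TRUE, FALSE, FALSE))
  expect_equal(cmp$n_shortened, 2L)
  expect_equal(cmp$n_lengthened, 1L)
  g <- glance(cmp)
  expect_equal(g$n_robust, 1L)
  expect_true(g$p_value > 0 && g$p_value <= 1)
  expect_equal(tidy(cmp), cmp$table)
})

test_that("the full interval pipeline is deterministic", {
  e <- mouse_ecg(noise_sd = 0.02, n_beats = 110, seed = 14)
  iv1 <- ecg_intervals(e, n_average = 100)
  iv2 <- ecg_intervals(e, n_average = 100)
  expect_identical(iv1$qrs, iv2$qrs)
  expect_identical(iv1$pr, iv2$pr)
  expect_equal(attr(iv1, "template")$n_averaged, 100L)
})
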