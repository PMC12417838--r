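# Synthetic generator: spectral law, determinism, oscillations, recordings,
# infiltration tables.

test_that("colored noise follows the prescribed spectral law", {
  fs <- 500
  # chi = 0 is white: flat Welch spectrum, unit variance in expectation
  x <- generate_colored_noise(fs * 60, fs, exponent = 0, offset = 0, seed = 3)
  ps <- psd_of(x, fs)
  sel <- ps$freqs >= 1 & ps$freqs <= 200
  expect_lt(sd(log10(ps$psd[1, sel])), 0.25)      # flat within MC wobble
  expect_equal(mean(ps$psd[1, sel]), 1, tolerance = 0.05)  # density 10^b = 1
  # offset chosen for unit variance: one-sided density 2/fs over [0, fs/2]
  xu <- generate_colored_noise(fs * 60, fs, 0, offset = log10(2 / fs),
                               seed = 3, floor_hz = 0)
  expect_equal(var(xu), 1, tolerance = 0.05)
  # chi = 2: log-log OLS oracle recovers the slope
  y <- generate_colored_noise(fs * 120, fs, exponent = 2, offset = 0, seed = 4)
  ps2 <- psd_of(y, fs)
  ab <- loglog_ols(ps2$freqs, ps2$psd[1, ], c(1, 200))
  expect_equal(unname(ab["slope"]), -2, tolerance = 0.1)
})

test_that("colored noise is bit-identical under a repeated seed", {
  a <- generate_colored_noise(1000, 500, 1.5, -0.2, seed = 11)
  b <- generate_colored_noise(1000, 500, 1.5, -0.2, seed = 11)
  expect_identical(a, b)
  expect_error(generate_colored_noise(0, 500, 1), "positive")
  expect_error(generate_colored_noise(1000, 500, -1), ">= 0")
})

test_that("band oscillations add power only in their band", {
  fs <- 500
  x <- withr::with_seed(5, rnorm(fs * 30))
  expect_identical(add_band_oscillation(x, c(8, 12), 0, fs), x)
  y <- add_band_oscillation(x, c(8, 12), 1, fs, seed = 6)
  bp_x <- band_powers(remove_line_noise(psd_of(x, fs)))
  bp_y <- band_powers(remove_line_noise(psd_of(y, fs)))
  expect_gt(bp_y$rel_alpha, bp_x$rel_alpha)
  # power outside the band unchanged (exact spectral masking)
  expect_equal(bp_y$abs_high_gamma, bp_x$abs_high_gamma, tolerance = 0.02)
  expect_error(add_band_oscillation(x, c(10, 400), 1, fs), "Nyquist")
})

test_that("generate_recording honors channel counts, labels and determinism", {
  cfg1 <- synth_config(sampling_rate = 250, duration = 4,
                       channels_per_compartment = c(
                         tumoral = 1, close_peritumoral = 1,
                         far_peritumoral = 1, healthy = 1),
                       n_patients = 1, seed = 2)
  gen <- generate_recording(cfg1)
  expect_equal(nrow(gen$recording$samples), 4)
  expect_setequal(gen$recording$channel_meta$label,
                  c("tumoral", "close_peritumoral", "far_peritumoral",
                    "healthy"))
  expect_equal(nrow(gen$ground_truth), 4)
  gen2 <- generate_recording(cfg1)
  expect_identical(gen$recording$samples, gen2$recording$samples)
  # default configuration carries the full cohort's channel counts
  expect_equal(sum(synth_config()$channels_per_compartment), 710)
})

test_that("generated unit-variance noise satisfies Parseval through Welch", {
  fs <- 500
  x <- generate_colored_noise(fs * 60, fs, exponent = 0,
                              offset = log10(2 / fs), seed = 9,
                              floor_hz = 0)
  ps <- psd_of(x, fs)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(sum(ps$psd[1, ]) * df, 1, tolerance = 0.05)
  expect_equal(sum(ps$psd[1, ]) * df, var(x), tolerance = 0.05)
})

test_that("infiltration tables hit the requested correlation and strata", {
  feats <- withr::with_seed(8, data.frame(
    channel_id = sprintf("ch%03d", 1:260),
    label = rep(c("close_peritumoral", "far_peritumoral"), 130),
    abs_beta = rlnorm(260),
    stringsAsFactors = FALSE))
  tbl <- generate_infiltration_table(feats, effect_feature = "abs_beta",
                                     effect_size = -0.5, n_biopsies = 200,
                                     seed = 13)
  expect_equal(nrow(tbl), 200)
  expect_true(all(tbl$count >= 0 & tbl$count == round(tbl$count)))
  low <- tbl$stratum == "low"
  m <- merge(tbl[low, ], feats, by = "channel_id")
  rho <- cor(m$abs_beta, m$count, method = "spearman")
  expect_lt(abs(rho - (-0.5)), 0.15)
  # null effect: small realized correlation
  tbl0 <- generate_infiltration_table(feats, effect_feature = "abs_beta",
                                      effect_size = 0, n_biopsies = 200,
                                      seed = 14)
  m0 <- merge(tbl0[tbl0$stratum == "low", ], feats, by = "channel_id")
  expect_lt(abs(cor(m0$abs_beta, m0$count, method = "spearman")), 0.2)
  expect_error(generate_infiltration_table(feats, effect_size = -2,
                                           n_biopsies = 10), "correlation")
  expect_error(generate_infiltration_table(feats[1:5, ], n_biopsies = 26),
               "exceeds")
})
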