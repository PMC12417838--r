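# Welch spectra, line-noise masking, band powers, normalization.

test_that("Welch PSD satisfies the spectral identities", {
  fs <- 2000
  n <- fs * 120
  # unit sinusoid integrates to a^2/2 = 0.5
  ps <- psd_of(sin(2 * pi * 10 * seq_len(n) / fs), fs)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(sum(ps$psd[1, ]) * df, 0.5, tolerance = 0.01)
  # unit-variance white noise: Parseval within 5%
  x <- withr::with_seed(2, rnorm(fs * 30))
  ps2 <- psd_of(x, fs)
  expect_equal(sum(ps2$psd[1, ]) * df, var(x), tolerance = 0.05)
  # all-zero channel: an all-zero spectrum
  ps3 <- psd_of(rep(0, fs * 10), fs)
  expect_true(all(ps3$psd == 0))
})

test_that("line-noise masking excludes harmonic bins and protects band powers", {
  fs <- 500
  x <- generate_colored_noise(fs * 40, fs, 2, seed = 21)
  tt <- seq_len(fs * 40) / fs
  noisy <- x + 2 * sin(2 * pi * 50 * tt) + 0.5 * sin(2 * pi * 100 * tt)
  ps_clean <- remove_line_noise(psd_of(x, fs))
  ps_noisy <- remove_line_noise(psd_of(noisy, fs))
  # mask is false exactly near the harmonics
  f <- ps_noisy$freqs
  near <- abs(f %% 50) <= 1 | abs(f %% 50 - 50) <= 1
  expect_equal(!ps_noisy$retained_bin_mask, near & f >= 49)
  # with harmonics masked, band powers match the tone-free case within 2%
  bp_c <- band_powers(ps_clean)
  bp_n <- band_powers(ps_noisy)
  for (b in names(default_bands()))
    expect_equal(bp_n[[paste0("abs_", b)]], bp_c[[paste0("abs_", b)]],
                 tolerance = 0.02)
  # a spectrum whose bins all sit outside the notch is untouched
  spec_odd <- structure(list(freqs = seq(1, 55, by = 2),
                             psd = matrix(1, 1, 28),
                             retained_bin_mask = rep(TRUE, 28),
                             channel_meta = data.frame(channel_id = "c1"),
                             missing = FALSE, sampling_rate = 120),
                        class = "ecog_psd")
  expect_equal(remove_line_noise(spec_odd, 50, 0.45)$retained_bin_mask,
               spec_odd$retained_bin_mask)
})

test_that("band powers follow analytic expectations and gain invariance", {
  # constructed flat spectrum over 0.5-100 Hz: relatives proportional to width
  freqs <- seq(0, 250, by = 0.5)
  psd <- matrix(ifelse(freqs >= 0.5 & freqs <= 100, 1, 0), nrow = 1)
  spec <- structure(list(freqs = freqs, psd = psd,
                         retained_bin_mask = rep(TRUE, length(freqs)),
                         channel_meta = data.frame(channel_id = "ch01"),
                         missing = FALSE, sampling_rate = 500),
                    class = "ecog_psd")
  bp <- band_powers(spec)
  widths <- vapply(default_bands(), function(b)
    min(b[2], 100.5) - b[1], numeric(1))
  rels <- unlist(bp[paste0("rel_", names(default_bands()))])
  expect_equal(unname(rels / widths), rep(unname(rels[1] / widths[1]), 6),
               tolerance = 0.02)
  expect_true(sum(rels) <= 1)
  # all power inside alpha: relative alpha 1, others 0
  psd2 <- matrix(ifelse(freqs >= 8 & freqs < 12, 1, 0), nrow = 1)
  spec2 <- spec; spec2$psd <- psd2
  bp2 <- band_powers(spec2)
  expect_equal(bp2$rel_alpha, 1)
  expect_equal(bp2$rel_delta + bp2$rel_beta + bp2$rel_theta, 0)
  # scaling a channel leaves every relative power unchanged
  fs <- 500
  x <- generate_colored_noise(fs * 20, fs, 2, seed = 3)
  b1 <- band_powers(remove_line_noise(psd_of(x, fs)))
  b2 <- band_powers(remove_line_noise(psd_of(7.3 * x, fs)))
  for (b in names(default_bands()))
    expect_equal(b2[[paste0("rel_", b)]], b1[[paste0("rel_", b)]],
                 tolerance = 1e-10)
  # default band table is the canonical six
  expect_equal(names(default_bands()),
               c("delta", "theta", "alpha", "beta", "low_gamma", "high_gamma"))
  expect_equal(default_bands()$beta, c(12, 29))
})

test_that("per-patient normalization scales to unit maxima independently", {
  tbl <- data.frame(patient_id = c("a", "a", "b", "b"),
                    f1 = c(2, 4, 10, 40), f2 = c(1, 0.5, 3, 1.5))
  out <- normalize_per_patient(tbl, cols = c("f1", "f2"))
  expect_equal(out$f1_norm, c(0.5, 1, 0.25, 1))
  expect_equal(out$f2_norm, c(1, 0.5, 1, 0.5))
  expect_true(all(out$f1_norm <= 1 & out$f1_norm >= 0))
  # rank order within patient preserved
  expect_equal(order(out$f1_norm[1:2]), order(tbl$f1[1:2]))
  # single row per patient: normalized value is 1
  one <- normalize_per_patient(data.frame(patient_id = "a", f1 = 3),
                               cols = "f1")
  expect_equal(one$f1_norm, 1)
  # zero maximum: defined as 0 with a warning
  expect_warning(
    z <- normalize_per_patient(data.frame(patient_id = "a", f1 = c(0, 0)),
                               cols = "f1"),
    "non-positive")
  expect_equal(z$f1_norm, c(0, 0))
})
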