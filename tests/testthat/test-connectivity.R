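# Hilbert phases and phase-locking values.

test_that("analytic phase behaves like the textbook analytic signal", {
  fs <- 500
  t <- seq_len(fs * 10) / fs
  rec <- make_recording(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)), fs)
  ph <- instantaneous_phase(rec, c(8, 12))
  core <- 500:3500
  # phase advances at 2*pi*f per second: unwrapped increment = 2*pi*10/fs
  d <- diff(ph[1, core])
  d[d < -pi] <- d[d < -pi] + 2 * pi
  expect_equal(median(d), 2 * pi * 10 / fs, tolerance = 1e-3)
  # cos leads sin by pi/2 throughout
  dd <- ph[1, core] - ph[2, core]
  dd[dd < 0] <- dd[dd < 0] + 2 * pi
  expect_equal(unname(quantile(dd, c(0.05, 0.95))), c(pi / 2, pi / 2),
               tolerance = 0.05)
  # constant channel: phase undefined, flagged NA
  rec2 <- make_recording(rbind(cos(2 * pi * 10 * t), rep(1, length(t))), fs)
  ph2 <- instantaneous_phase(rec2, c(8, 12))
  expect_true(all(is.na(ph2[2, ])))
})

test_that("plv is exact on locked signals and calibrated on null phases", {
  fs <- 500
  ph <- withr::with_seed(31, runif(5000, -pi, pi))
  expect_equal(plv(ph, ph), 1)
  expect_equal(plv(ph, ph + 1.2), 1)           # constant offset is ignored
  # independent uniform phases: mean PLV ~ sqrt(pi / (4N))
  n <- 2000
  null_plv <- withr::with_seed(32, vapply(1:300, function(i)
    plv(runif(n, -pi, pi), runif(n, -pi, pi)), numeric(1)))
  expect_equal(mean(null_plv), sqrt(pi / (4 * n)), tolerance = 0.1)
  expect_error(plv(ph, ph[-1]), "equal length")
  expect_error(plv(ph[1:50], ph[1:50]), "100")
})

test_that("plv matrices are symmetric, unit-diagonal and amplitude-invariant", {
  cfg <- small_cohort_config(seed = 77, per_group = 3, duration = 6)
  rec <- generate_recording(cfg)$recording
  pm <- plv_matrix(rec, c(8, 12))
  v <- pm$values
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(1, nrow(v)))
  expect_true(all(v >= 0 & v <= 1))
  # scaling any channel's amplitude leaves PLV unchanged
  rec2 <- rec
  rec2$samples[3, ] <- 10 * rec2$samples[3, ]
  pm2 <- plv_matrix(rec2, c(8, 12))
  expect_equal(pm2$values, v, tolerance = 1e-8)
})

test_that("compartment summary finds coupling where the generator put it", {
  prof <- default_profiles()
  prof <- lapply(prof, function(p) {
    p$coupling_strength <- if (p$label == "tumoral") 1 else 0
    p
  })
  cfg <- synth_config(sampling_rate = 500, duration = 8,
                      channels_per_compartment = c(
                        tumoral = 4, close_peritumoral = 4,
                        far_peritumoral = 4, healthy = 4),
                      n_patients = 1, profiles = prof, seed = 55)
  rec <- generate_recording(cfg)$recording
  for (bn in c("delta", "beta", "high_gamma")) {
    pm <- plv_matrix(rec, plv_bands()[[bn]], band_name = bn)
    sm <- compartment_plv_summary(pm, rec$channel_meta$label)
    tum <- sm$means["tumoral", "tumoral"]
    others <- sm$means[row(sm$means) != 1 | col(sm$means) != 1]
    expect_true(all(tum > others),
                info = sprintf("band %s: intratumoral PLV must dominate", bn))
  }
  # shape contract on a 2-label toy
  fs <- 500
  t <- seq_len(fs * 5) / fs
  x <- sin(2 * pi * 10 * t)
  rec2 <- make_recording(rbind(x, x, x, x), fs,
                         labels = c("tumoral", "tumoral", "healthy", "healthy"))
  sm2 <- compartment_plv_summary(plv_matrix(rec2, c(8, 12)),
                                 rec2$channel_meta$label)
  expect_equal(dim(sm2$means), c(2, 2))
  expect_equal(unname(sm2$means), matrix(1, 2, 2))  # identical channels
})
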