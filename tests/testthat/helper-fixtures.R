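# Shared fixtures and independent oracles for the test suite.

# Tiny recording wrapper around a sample matrix.
make_recording <- function(samples, fs, labels = NULL, patients = "P01") {
  n_ch <- nrow(samples)
  meta <- data.frame(
    channel_id = sprintf("ch%02d", seq_len(n_ch)),
    patient_id = rep_len(patients, n_ch),
    label = if (is.null(labels)) rep("healthy", n_ch) else labels,
    stringsAsFactors = FALSE
  )
  ecog_recording(samples, fs, meta)
}

# One-channel recording from a vector.
vec_recording <- function(x, fs, ...) make_recording(matrix(x, nrow = 1), fs, ...)

# Independent slope oracle: ordinary least squares of log10(psd) on
# log10(f) over a frequency range, optionally excluding a window (used to
# dodge an injected peak). Deliberately independent of fit_spectral_model.
loglog_ols <- function(freqs, psd, range, exclude = NULL) {
  sel <- freqs >= range[1] & freqs <= range[2] & psd > 0
  if (!is.null(exclude))
    sel <- sel & !(freqs >= exclude[1] & freqs <= exclude[2])
  fit <- lm(log10(psd[sel]) ~ log10(freqs[sel]))
  c(offset = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# Welch spectrum of a single vector (convenience).
psd_of <- function(x, fs, ...) welch_psd(vec_recording(x, fs), ...)

# A small synthetic cohort configuration used by several tests.
small_cohort_config <- function(seed = 42, per_group = 6, duration = 10,
                                fs = 500) {
  synth_config(sampling_rate = fs, duration = duration,
               channels_per_compartment = c(
                 tumoral = per_group, close_peritumoral = per_group,
                 far_peritumoral = per_group, healthy = per_group),
               n_patients = 2, seed = seed)
}

# Feature table with separable classes for classifier tests: 4 Gaussian
# blobs with large between-class margins in a handful of dimensions,
# replicated across the 38 canonical columns.
separable_features <- function(n_per_class = 30, seed = 1, gap = 6) {
  withr::with_seed(seed, {
    lev <- c("tumoral", "close_peritumoral", "far_peritumoral", "healthy")
    cols <- feature_columns()
    rows <- lapply(seq_along(lev), function(k) {
      base <- matrix(rnorm(n_per_class * length(cols), mean = k * gap),
                     nrow = n_per_class)
      df <- as.data.frame(base)
      names(df) <- cols
      df$label <- lev[k]
      df
    })
    tbl <- do.call(rbind, rows)
    tbl$channel_id <- sprintf("ch%03d", seq_len(nrow(tbl)))
    tbl$patient_id <- "P01"
    tbl$complete <- TRUE
    tbl
  })
}
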