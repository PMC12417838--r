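# Welch power spectra, line-noise bin exclusion, band powers and
# per-patient normalization.

#' Welch power spectral density per channel
#'
#' Averaged periodogram with a Hann window of `window_seconds * sampling_rate`
#' samples (default 2 s, i.e. n = 2 x rate) and 50% overlap. One-sided density
#' scaling: `sum(psd) * delta_f` approximates the signal variance (Parseval).
#' When a [reject_artifacts()] mask is supplied, windows are taken only
#' inside retained intervals; a channel with no interval long enough for a
#' single window gets an all-`NA` spectrum and is flagged.
#'
#' @param rec An [ecog_recording()].
#' @param mask Optional `segment_mask`; defaults to the full recording.
#' @param window_seconds Window length in seconds.
#' @param overlap_fraction Fractional overlap of consecutive windows.
#' @return An object of class `ecog_psd`: `freqs` (Hz), `psd`
#'   (channels x freqs, signal^2/Hz), `retained_bin_mask`, `channel_meta`,
#'   and `missing` flags.
#' @export
welch_psd <- function(rec, mask = NULL, window_seconds = 2,
                      overlap_fraction = 0.5) {
  stopifnot(inherits(rec, "ecog_recording"))
  stopifnot_scalar_pos(window_seconds, "window_seconds")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  if (is.null(mask)) mask <- full_mask(rec)
  fs <- rec$sampling_rate
  nw <- round(window_seconds * fs)
  hop <- max(1L, round(nw * (1 - overlap_fraction)))
  win <- signal::hanning(nw)
  u <- sum(win^2)
  nf <- nw %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nw

  n_ch <- nrow(rec$samples)
  psd <- matrix(NA_real_, n_ch, nf)
  missing <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    if (mask$removed[ch]) { missing[ch] <- TRUE; next }
    acc <- numeric(nf); n_seg <- 0L
    iv <- mask$intervals[[ch]]
    for (r in seq_len(nrow(iv))) {
      len <- iv[r, 2] - iv[r, 1]
      if (len < nw) next
      starts <- seq(iv[r, 1], iv[r, 2] - nw, by = hop)
      for (s in starts) {
        X <- fft(rec$samples[ch, s:(s + nw - 1)] * win)
        acc <- acc + Mod(X[seq_len(nf)])^2
        n_seg <- n_seg + 1L
      }
    }
    if (n_seg == 0L) { missing[ch] <- TRUE; next }
    p <- 2 * acc / (n_seg * fs * u)
    p[1] <- p[1] / 2
    if (nw %% 2 == 0) p[nf] <- p[nf] / 2
    psd[ch, ] <- p
  }
  structure(
    list(freqs = freqs, psd = psd,
         retained_bin_mask = rep(TRUE, nf),
         channel_meta = rec$channel_meta, missing = missing,
         sampling_rate = fs,
         params = list(window_seconds = window_seconds,
                       overlap_fraction = overlap_fraction)),
    class = "ecog_psd"
  )
}

#' @export
print.ecog_psd <- function(x, ...) {
  cat(sprintf("<ecog_psd> %d channels, %d bins (%.2g-%.6g Hz, df=%.3g), %d bins line-masked\n",
              nrow(x$psd), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], sum(!x$retained_bin_mask)))
  invisible(x)
}

#' Mask power-line frequency bins out of a spectrum
#'
#' Marks bins within `half_width_hz` of the mains frequency and every
#' harmonic as excluded; all downstream totals and band powers sum retained
#' bins only. The density values themselves are left untouched.
#'
#' @param spectrum An `ecog_psd`.
#' @param mains_hz Mains frequency (50 Hz here; use 60 where applicable).
#' @param half_width_hz Half-width of the notch around each harmonic.
#' @return The `ecog_psd` with an updated `retained_bin_mask`.
#' @export
remove_line_noise <- function(spectrum, mains_hz = 50, half_width_hz = 1) {
  stopifnot(inherits(spectrum, "ecog_psd"))
  stopifnot_scalar_pos(mains_hz, "mains_hz")
  if (mains_hz >= max(spectrum$freqs))
    stop("mains frequency above the spectral range", call. = FALSE)
  harmonics <- seq(mains_hz, max(spectrum$freqs), by = mains_hz)
  near <- Reduce(`|`, lapply(harmonics, function(h)
    abs(spectrum$freqs - h) <= half_width_hz))
  spectrum$retained_bin_mask <- spectrum$retained_bin_mask & !near
  spectrum
}

#' Absolute and relative band powers
#'
#' Absolute power of a band is the sum of retained PSD bins in
#' `[low, high)` times the bin width; relative power divides by the total
#' over all retained bins from `min_freq` (default 0.5 Hz) to the Nyquist of
#' the analysis rate. A band left empty after line-noise masking yields `NA`.
#'
#' @param spectrum An `ecog_psd`, usually after [remove_line_noise()].
#' @param bands Named list of `c(low, high)` intervals; see [default_bands()].
#' @param min_freq Lower edge of the total-power denominator, Hz.
#' @return Data frame: `channel_id`, `total_power`, then `abs_<band>` and
#'   `rel_<band>` columns.
#' @export
band_powers <- function(spectrum, bands = default_bands(), min_freq = 0.5) {
  stopifnot(inherits(spectrum, "ecog_psd"))
  f <- spectrum$freqs
  df <- f[2] - f[1]
  keep <- spectrum$retained_bin_mask
  total_sel <- keep & f >= min_freq
  out <- data.frame(channel_id = spectrum$channel_meta$channel_id,
                    stringsAsFactors = FALSE)
  total <- rowSums(spectrum$psd[, total_sel, drop = FALSE]) * df
  out$total_power <- total
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- bands[[b]][2]
    sel <- keep & f >= lo & f < hi
    if (!any(sel)) {
      out[[paste0("abs_", b)]] <- NA_real_
      out[[paste0("rel_", b)]] <- NA_real_
      next
    }
    absb <- rowSums(spectrum$psd[, sel, drop = FALSE]) * df
    out[[paste0("abs_", b)]] <- absb
    out[[paste0("rel_", b)]] <- ifelse(total > 0, absb / total, NA_real_)
  }
  out
}

#' Normalize feature columns per patient
#'
#' Divides each feature column, within each patient, by that patient's
#' maximum of the column, so every patient's maximum of every normalized
#' feature is 1 (this makes amplitude-scale differences between patients and
#' amplifiers commensurable). A patient whose maximum is zero or negative
#' gets zeros with a warning. `mode = "global"` instead divides all of a
#' patient's features by the single largest value across the selected
#' columns. Columns containing negative values (log-scale features such as
#' the aperiodic offset) cannot meaningfully be divided by a maximum; the
#' caller should map them to a positive scale first (see
#' [assemble_features()], which normalizes the offset on the power scale).
#'
#' @param features Data frame with a `patient_id` column.
#' @param cols Character vector of columns to normalize; default all numeric
#'   columns except identifiers.
#' @param mode `"per_feature"` (default) or `"global"`.
#' @param suffix Appended to normalized column names; `""` replaces in place.
#' @return The data frame with normalized columns added (or replaced).
#' @export
normalize_per_patient <- function(features, cols = NULL,
                                  mode = c("per_feature", "global"),
                                  suffix = "_norm") {
  mode <- match.arg(mode)
  if (is.null(features$patient_id))
    stop("features must carry a patient_id column", call. = FALSE)
  if (is.null(cols)) {
    num <- vapply(features, is.numeric, logical(1))
    cols <- setdiff(names(features)[num],
                    c("channel_id", "patient_id", "distance_mm", "total_power"))
  }
  for (cl in cols) {
    newcol <- paste0(cl, suffix)
    features[[newcol]] <- features[[cl]]
    for (p in unique(features$patient_id)) {
      i <- features$patient_id == p
      m <- if (mode == "per_feature") {
        suppressWarnings(max(features[[cl]][i], na.rm = TRUE))
      } else {
        suppressWarnings(max(as.matrix(features[i, cols, drop = FALSE]),
                             na.rm = TRUE))
      }
      if (!is.finite(m) || m <= 0) {
        if (is.finite(m) && m <= 0)
          warning(sprintf("patient %s has non-positive maximum for %s; normalized to 0",
                          p, cl))
        features[[newcol]][i] <- 0
      } else {
        features[[newcol]][i] <- features[[cl]][i] / m
      }
    }
  }
  features
}
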