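# Aperiodic (1/f) parameterization of power spectra: a knee-free line in
# log-log space plus Gaussian oscillatory peaks, in the spirit of spectral
# parameterization ("periodic + aperiodic") models.

gaussian_lf <- function(f, center, height, sd) {
  height * exp(-0.5 * ((f - center) / sd)^2)
}

# Robust line fit of y on x: ordinary least squares, then refit excluding
# the largest positive residuals (oscillatory peaks push the line up, so
# only the upper tail is trimmed).
robust_logline <- function(x, y, trim = 0.025) {
  fit <- lm(y ~ x)
  r <- resid(fit)
  keep <- r <= quantile(r, 1 - trim)
  if (sum(keep) >= 3) fit <- lm(y[keep] ~ x[keep])
  unname(coef(fit))
}

#' Parameterize one power spectrum into aperiodic + peak components
#'
#' Fits `log10(psd) = offset - exponent * log10(f)` over `fit_range`,
#' iteratively removing Gaussian peaks: (1) robust line fit; (2) while the
#' largest positive residual exceeds `min_peak_height` (and fewer than
#' `max_peaks` were taken), fit a Gaussian (in linear frequency, log power)
#' to the residual and subtract it; (3) refit the line on the peak-subtracted
#' spectrum. The exponent is reported as a positive magnitude for a
#' decreasing spectrum. Exact (to numerical precision) on a noiseless pure
#' power law.
#'
#' @param freqs Frequency grid, Hz.
#' @param psd Power spectral density values for one channel.
#' @param fit_range `c(low, high)` Hz.
#' @param max_peaks Maximum number of Gaussian peaks to remove.
#' @param min_peak_height Minimum peak height (log10-power units).
#' @param peak_sd_limits Gaussian SD bounds in Hz.
#' @param retained_mask Optional logical mask of usable bins (line-noise
#'   exclusion); defaults to all.
#' @return List with `aperiodic` (fit_range, offset, exponent, r_squared,
#'   n_peaks_removed) and `peaks` (data frame center_hz, height,
#'   bandwidth_hz). `NA` fit when fewer than 8 usable bins remain.
#' @export
fit_spectral_model <- function(freqs, psd, fit_range = c(1, 200),
                               max_peaks = 6, min_peak_height = 0.1,
                               peak_sd_limits = c(0.5, 12),
                               retained_mask = NULL) {
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, length(freqs))
  sel <- retained_mask & freqs >= fit_range[1] & freqs <= fit_range[2] &
    is.finite(psd)
  if (any(psd[sel] <= 0)) {
    warning("non-positive PSD bins excluded from aperiodic fit")
    sel <- sel & psd > 0
  }
  empty <- list(
    aperiodic = list(fit_range = fit_range, offset = NA_real_,
                     exponent = NA_real_, r_squared = NA_real_,
                     n_peaks_removed = NA_integer_),
    peaks = data.frame(center_hz = numeric(0), height = numeric(0),
                       bandwidth_hz = numeric(0)))
  if (sum(sel) < 8) return(empty)

  f <- freqs[sel]
  lf <- log10(f)
  lp <- log10(psd[sel])

  ab <- robust_logline(lf, lp)
  d <- lp - (ab[1] + ab[2] * lf)
  peaks <- list()
  peak_sum <- numeric(length(f))
  while (length(peaks) < max_peaks) {
    i <- which.max(d)
    h0 <- d[i]
    if (h0 < min_peak_height) break
    par0 <- c(center = f[i], height = h0, sd = min(max(2, peak_sd_limits[1]),
                                                   peak_sd_limits[2]))
    obj <- function(p) sum((d - gaussian_lf(f, p[1], p[2], p[3]))^2)
    opt <- optim(par0, obj, method = "L-BFGS-B",
                 lower = c(fit_range[1], min_peak_height / 2,
                           peak_sd_limits[1]),
                 upper = c(fit_range[2], 2 * h0, peak_sd_limits[2]))
    g <- gaussian_lf(f, opt$par[1], opt$par[2], opt$par[3])
    d <- d - g
    peak_sum <- peak_sum + g
    peaks[[length(peaks) + 1]] <- opt$par
  }

  final <- lm((lp - peak_sum) ~ lf)
  offset <- unname(coef(final)[1])
  slope <- unname(coef(final)[2])
  pred <- offset + slope * lf + peak_sum
  ss_res <- sum((lp - pred)^2)
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1

  peak_df <- if (length(peaks)) {
    m <- do.call(rbind, peaks)
    data.frame(center_hz = m[, 1], height = m[, 2],
               bandwidth_hz = 2 * sqrt(2 * log(2)) * m[, 3])
  } else empty$peaks
  list(
    aperiodic = list(fit_range = fit_range, offset = offset,
                     exponent = -slope, r_squared = r2,
                     n_peaks_removed = length(peaks)),
    peaks = peak_df
  )
}

#' Aperiodic feature block: one offset plus six range-restricted exponents
#'
#' Runs [fit_spectral_model()] per channel over each of the configured
#' frequency ranges and assembles the 7 aperiodic feature columns: the
#' offset from the widest (1--200 Hz) fit and the exponent ("slope") from
#' every range. Missing fits propagate as `NA`.
#'
#' @param spectrum An `ecog_psd` (after [remove_line_noise()] so that mains
#'   bins do not bias the fits).
#' @param ranges Named list of fit ranges; see [default_fit_ranges()]. The
#'   first range supplies the offset.
#' @param ... Passed to [fit_spectral_model()].
#' @return Data frame: `channel_id`, `offset`, then `slope_<range>` columns.
#' @export
aperiodic_feature_block <- function(spectrum, ranges = default_fit_ranges(),
                                    ...) {
  stopifnot(inherits(spectrum, "ecog_psd"))
  n_ch <- nrow(spectrum$psd)
  out <- data.frame(channel_id = spectrum$channel_meta$channel_id,
                    stringsAsFactors = FALSE)
  slope_cols <- paste0("slope_", sub("^r", "", names(ranges)))
  out$offset <- NA_real_
  for (cl in slope_cols) out[[cl]] <- NA_real_
  for (ch in seq_len(n_ch)) {
    if (isTRUE(spectrum$missing[ch])) next
    for (k in seq_along(ranges)) {
      fit <- fit_spectral_model(spectrum$freqs, spectrum$psd[ch, ],
                                fit_range = ranges[[k]],
                                retained_mask = spectrum$retained_bin_mask,
                                ...)
      out[[slope_cols[k]]][ch] <- fit$aperiodic$exponent
      if (k == 1L) out$offset[ch] <- fit$aperiodic$offset
    }
  }
  out
}
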