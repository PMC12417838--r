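# Zero-phase filtering, resampling and artifact exclusion.

# Design a Chebyshev type II filter cascade for a (low, high) band. Using a
# separate high-pass and low-pass section, each of the given order, is far
# better conditioned than a single bandpass design when the lower edge sits
# near DC (0.1 Hz at a 2000 Hz rate).
#
# cheby2's cutoff is the STOPBAND edge, not the passband edge; stop edges
# are therefore placed one octave outside the band (low/2 and 2*high),
# which for order 4 / 40 dB puts the -3 dB points right at the band edges.
# When 2*high exceeds Nyquist the transition is compressed and the order
# raised to keep the -3 dB point at the band edge. Returns a list of
# filters to apply in sequence; an unstable design is an error rather than
# a silent artifact.
design_cheby2_band <- function(low_hz, high_hz, sampling_rate,
                               order = 4, stopband_atten_db = 40) {
  nyq <- sampling_rate / 2
  if (!is.null(low_hz) && !is.null(high_hz) && low_hz >= high_hz)
    stop("band low edge must be below high edge", call. = FALSE)
  eps <- sqrt(10^(stopband_atten_db / 10) - 1)
  filters <- list()
  if (!is.null(low_hz) && low_hz > 0) {
    if (low_hz >= nyq) stop("low edge at or above Nyquist", call. = FALSE)
    filters$hp <- signal::cheby2(order, stopband_atten_db,
                                 (low_hz / 2) / nyq, type = "high")
  }
  if (!is.null(high_hz) && high_hz < nyq) {
    stop_hi <- min(2 * high_hz, 0.98 * nyq)
    n_lp <- order
    if (stop_hi < 2 * high_hz) {
      # compressed transition: raise the order so the -3 dB point stays at
      # the band edge (cosh(acosh(eps)/n) = stop/edge)
      n_lp <- min(12L, max(order,
                           ceiling(acosh(eps) / acosh(stop_hi / high_hz))))
    }
    filters$lp <- signal::cheby2(n_lp, stopband_atten_db, stop_hi / nyq,
                                 type = "low")
  }
  for (f in filters) {
    if (!all(abs(polyroot(rev(f$a))) < 1))
      stop("unstable Chebyshev II design at order ", order,
           "; lower the order or widen the band", call. = FALSE)
  }
  filters
}

filter_vector_zero_phase <- function(x, filters) {
  for (f in filters) x <- signal::filtfilt(f, x)
  x
}

#' Zero-phase Chebyshev II bandpass filtering
#'
#' Applies a forward-backward (zero net phase shift) Chebyshev type II
#' filter cascade -- a high-pass at `low_hz` and a low-pass at `high_hz`,
#' each of the given order -- to every channel.
#'
#' @param rec An [ecog_recording()].
#' @param low_hz,high_hz Passband edges in Hz. The default passband is
#'   0.1--250 Hz, wide enough to retain every analyzed range (high-gamma
#'   power to 100 Hz, aperiodic fits to 200 Hz); pass `high_hz = 50` to
#'   reproduce a narrow 0.1--50 Hz preset.
#' @param order Filter order per band edge.
#' @param stopband_atten_db Stopband attenuation of each section, in dB.
#' @return The filtered [ecog_recording()].
#' @export
bandpass_zero_phase <- function(rec, low_hz = 0.1, high_hz = 250,
                                order = 4, stopband_atten_db = 40) {
  stopifnot(inherits(rec, "ecog_recording"))
  filters <- design_cheby2_band(low_hz, high_hz, rec$sampling_rate,
                                order, stopband_atten_db)
  if (length(filters))
    rec$samples <- t(apply(rec$samples, 1, filter_vector_zero_phase, filters))
  rec
}

#' Resample a recording to the analysis rate
#'
#' Fourier-domain resampling: the spectrum is truncated at the target
#' Nyquist frequency and inverse-transformed at the new length. This is an
#' ideal (brick-wall) anti-aliasing decimator with exactly flat passband
#' gain, handles any rational rate ratio, and is never naive sample
#' dropping. Identity when the target equals the source rate.
#'
#' @param rec An [ecog_recording()].
#' @param target_hz Target rate in Hz (default 2000, the analysis rate).
#' @return The resampled [ecog_recording()].
#' @export
resample_recording <- function(rec, target_hz = 2000) {
  stopifnot(inherits(rec, "ecog_recording"))
  stopifnot_scalar_pos(target_hz, "target_hz")
  if (target_hz > rec$sampling_rate)
    stop("target rate above the source rate; upsampling is not supported",
         call. = FALSE)
  if (target_hz == rec$sampling_rate) return(rec)
  n <- ncol(rec$samples)
  m <- round(n * target_hz / rec$sampling_rate)
  out <- t(apply(rec$samples, 1, fft_resample, m = m))
  rec$samples <- out
  rec$sampling_rate <- target_hz
  rec
}

# Truncate the DFT to m bins (keeping the low-frequency half-spectrum,
# conjugate-symmetric) and invert; the real part of the output Nyquist bin
# keeps the result real-valued.
fft_resample <- function(x, m) {
  n <- length(x)
  X <- fft(x)
  Y <- complex(length.out = m)
  if (m %% 2 == 1) {
    h <- (m - 1) / 2
    Y[1] <- X[1]
    Y[2:(h + 1)] <- X[2:(h + 1)]
    Y[(h + 2):m] <- X[(n - h + 1):n]
  } else {
    h <- m / 2 - 1
    Y[1] <- X[1]
    Y[2:(h + 1)] <- X[2:(h + 1)]
    Y[h + 2] <- complex(real = Re(X[h + 2]), imaginary = 0)
    Y[(h + 3):m] <- X[(n - h + 1):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Detect and exclude artifactual signal segments
#'
#' Scans each channel in non-overlapping 1-second windows and excludes
#' windows whose peak amplitude is an outlier (robust z-score of the window
#' peak, against the channel's own median/MAD across windows, above
#' `amplitude_z_threshold`) or whose variance falls below `flatline_epsilon`.
#' Channels retaining less than `min_retained_seconds` are flagged noisy and
#' removed from analysis.
#'
#' @param rec An [ecog_recording()].
#' @param amplitude_z_threshold Robust z-score cutoff for window peaks.
#' @param flatline_epsilon Variance below which a window counts as flat.
#' @param min_retained_seconds Minimum retained duration per channel.
#' @return An object of class `segment_mask`: per-channel retained intervals
#'   `[start, end)` in samples, retained seconds, and removed-channel flags.
#' @export
reject_artifacts <- function(rec, amplitude_z_threshold = 8,
                             flatline_epsilon = 1e-12,
                             min_retained_seconds = 10) {
  stopifnot(inherits(rec, "ecog_recording"))
  stopifnot_scalar_pos(amplitude_z_threshold, "amplitude_z_threshold")
  stopifnot_scalar_pos(flatline_epsilon, "flatline_epsilon")
  fs <- rec$sampling_rate
  n_win <- floor(ncol(rec$samples) / fs)
  out <- lapply(seq_len(nrow(rec$samples)), function(ch) {
    x <- rec$samples[ch, ]
    keep <- rep(TRUE, n_win)
    peaks <- numeric(n_win); vars <- numeric(n_win)
    for (w in seq_len(n_win)) {
      seg <- x[((w - 1) * fs + 1):(w * fs)]
      peaks[w] <- max(abs(seg)); vars[w] <- var(seg)
    }
    scale_ <- max(mad(peaks), 1e-12)
    z <- (peaks - median(peaks)) / scale_
    # 1/f-weighted signals have heavy-tailed window peaks, so the robust z
    # alone over-flags; a window must also exceed 5x the median peak (a
    # genuine artifact scale) before it is excluded
    keep <- !(z > amplitude_z_threshold & peaks > 5 * median(peaks)) &
      vars >= flatline_epsilon
    intervals_from_keep(keep, fs)
  })
  retained <- vapply(out, function(iv)
    sum(iv[, 2] - iv[, 1]) / fs, numeric(1))
  # a recording shorter than the minimum cannot condemn its channels:
  # the requirement is capped at the scannable duration
  removed <- retained < min(min_retained_seconds, n_win)
  structure(
    list(intervals = out, retained_seconds = retained, removed = removed,
         channel_id = rec$channel_meta$channel_id,
         params = list(amplitude_z_threshold = amplitude_z_threshold,
                       flatline_epsilon = flatline_epsilon,
                       min_retained_seconds = min_retained_seconds)),
    class = "segment_mask"
  )
}

# Run-length encode a keep vector of 1-s windows into half-open sample
# intervals [start, end), 1-based starts.
intervals_from_keep <- function(keep, fs) {
  if (!any(keep)) return(matrix(numeric(0), ncol = 2))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  kept <- which(r$values)
  cbind(start = (starts[kept] - 1) * fs + 1, end = ends[kept] * fs + 1)
}

#' A segment mask retaining every full second of every channel
#'
#' @param rec An [ecog_recording()].
#' @return A `segment_mask` retaining everything.
#' @export
full_mask <- function(rec) {
  fs <- rec$sampling_rate
  n <- ncol(rec$samples)
  iv <- matrix(c(1, n + 1), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  structure(
    list(intervals = rep(list(iv), nrow(rec$samples)),
         retained_seconds = rep(n / fs, nrow(rec$samples)),
         removed = rep(FALSE, nrow(rec$samples)),
         channel_id = rec$channel_meta$channel_id,
         params = list()),
    class = "segment_mask"
  )
}

#' @export
print.segment_mask <- function(x, ...) {
  cat(sprintf("<segment_mask> %d channels, %d removed; retained %.1f-%.1f s\n",
              length(x$intervals), sum(x$removed),
              min(x$retained_seconds), max(x$retained_seconds)))
  invisible(x)
}
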