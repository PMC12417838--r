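# Phase-locking-value connectivity between simultaneously recorded channels.

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel in a frequency band
#'
#' Channels are forward-backward filtered into the band with a Chebyshev II
#' cascade (see [bandpass_zero_phase()]), the analytic signal is taken with
#' the Hilbert transform, and one second is trimmed from each end to drop
#' filter transients. Constant (zero-variance) channels have no defined
#' phase and come back as `NA` rows.
#'
#' @param rec An [ecog_recording()].
#' @param band `c(low, high)` Hz.
#' @param trim_seconds Seconds discarded at each end after filtering.
#' @param order,stopband_atten_db Filter design, as in [bandpass_zero_phase()].
#' @return Matrix channels x time of phases in (-pi, pi].
#' @export
instantaneous_phase <- function(rec, band, trim_seconds = 1,
                                order = 4, stopband_atten_db = 40) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$sampling_rate
  filters <- design_cheby2_band(band[1], band[2], fs, order,
                                stopband_atten_db)
  n <- ncol(rec$samples)
  trim <- round(trim_seconds * fs)
  if (n - 2 * trim < 2)
    stop("recording too short after transient trimming", call. = FALSE)
  keep <- (trim + 1):(n - trim)
  out <- matrix(NA_real_, nrow(rec$samples), length(keep))
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    if (sd(x) < .Machine$double.eps^0.5) next  # constant: phase undefined
    xf <- filter_vector_zero_phase(x, filters)
    out[ch, ] <- Arg(analytic_signal(xf))[keep]
  }
  out
}

#' Phase-locking value between two phase time series
#'
#' The modulus of the time-averaged unit phasor of the phase difference:
#' `|mean(exp(i * (phi_i - phi_j)))|`. 1 for perfectly locked signals (any
#' fixed lag), near `sqrt(pi/(4N))` for independent phases.
#'
#' @param phase_i,phase_j Equal-length numeric phase vectors (radians),
#'   length at least 100.
#' @return PLV in `[0, 1]`.
#' @export
plv <- function(phase_i, phase_j) {
  if (length(phase_i) != length(phase_j))
    stop("phase vectors must have equal length", call. = FALSE)
  if (length(phase_i) < 100)
    stop("need at least 100 samples for a stable PLV", call. = FALSE)
  Mod(mean(exp(1i * (phase_i - phase_j))))
}

#' Per-band PLV matrix over all simultaneous channel pairs
#'
#' Computes the full symmetric channel x channel PLV matrix for one band.
#' When the channel metadata carries an acquisition `block` column (strips
#' placed sequentially during surgery), only pairs recorded simultaneously
#' -- i.e. sharing a block -- are computed; cross-block entries are `NA`.
#'
#' @param rec An [ecog_recording()].
#' @param band `c(low, high)` Hz; see [plv_bands()].
#' @param band_name Optional label stored on the result.
#' @param ... Passed to [instantaneous_phase()].
#' @return Object of class `plv_matrix`: `values` (channels x channels,
#'   unit diagonal), `band`, `channel_id`, `n_samples_used`.
#' @export
plv_matrix <- function(rec, band, band_name = NULL, ...) {
  ph <- instantaneous_phase(rec, band, ...)
  z <- exp(1i * ph)
  n <- ncol(ph)
  bad <- !stats::complete.cases(ph)
  z[bad, ] <- 0
  m <- Mod(z %*% Conj(t(z))) / n
  m[bad, ] <- NA_real_; m[, bad] <- NA_real_
  diag(m) <- ifelse(bad, NA_real_, 1)
  blocks <- rec$channel_meta$block
  if (!is.null(blocks)) {
    same <- outer(blocks, blocks, `==`)
    m[!same] <- NA_real_
  }
  structure(
    list(values = m, band = if (is.null(band_name)) paste(band, collapse = "-")
         else band_name,
         channel_id = rec$channel_meta$channel_id, n_samples_used = n),
    class = "plv_matrix"
  )
}

#' @export
print.plv_matrix <- function(x, ...) {
  cat(sprintf("<plv_matrix> band %s, %d channels, N=%d\n",
              x$band, nrow(x$values), x$n_samples_used))
  invisible(x)
}

#' Mean PLV within and between cortical compartments
#'
#' Averages the PLV matrix over distinct unordered channel pairs for every
#' pair of compartment labels; diagonal blocks use within-group pairs only
#' (never the unit self-PLV). A group with fewer than two channels has an
#' undefined within-group mean, reported `NA`.
#'
#' @param plv_mat A `plv_matrix`.
#' @param labels Compartment label per channel (character or factor).
#' @return Object of class `compartment_plv`: `band` and a symmetric
#'   `means` matrix over the label levels.
#' @export
compartment_plv_summary <- function(plv_mat, labels) {
  stopifnot(inherits(plv_mat, "plv_matrix"))
  v <- plv_mat$values
  if (length(labels) != nrow(v))
    stop("one label per channel required", call. = FALSE)
  labels <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = intersect(compartment_levels(), unique(labels)))
  lev <- levels(labels)
  k <- length(lev)
  m <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(labels == lev[a]); ib <- which(labels == lev[b])
      if (a == b) {
        if (length(ia) < 2) next
        block <- v[ia, ia, drop = FALSE]
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(v[ia, ib, drop = FALSE])
      }
      m[a, b] <- m[b, a] <- mean(vals, na.rm = TRUE)
    }
  }
  structure(list(band = plv_mat$band, means = m), class = "compartment_plv")
}

#' @export
print.compartment_plv <- function(x, ...) {
  cat(sprintf("<compartment_plv> band %s\n", x$band))
  print(round(x$means, 3))
  invisible(x)
}
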