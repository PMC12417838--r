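# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}

# The four cortical compartments, in fixed order (used as factor levels
# throughout so that group summaries and confusion matrices are aligned).
compartment_levels <- function() {
  c("tumoral", "close_peritumoral", "far_peritumoral", "healthy")
}

as_compartment <- function(x) {
  factor(as.character(x), levels = compartment_levels())
}

#' Canonical EEG frequency bands used for band-power features
#'
#' Delta 0.5--4, theta 4--8, alpha 8--12, beta 12--29, low gamma 30--45 and
#' high gamma 55--100 Hz. Intervals are half-open `[low, high)` so adjacent
#' bands never double-count a frequency bin.
#'
#' @return Named list of `c(low, high)` vectors in Hz.
#' @export
default_bands <- function() {
  list(
    delta      = c(0.5, 4),
    theta      = c(4, 8),
    alpha      = c(8, 12),
    beta       = c(12, 29),
    low_gamma  = c(30, 45),
    high_gamma = c(55, 100)
  )
}

#' Frequency bands used for phase-locking-value connectivity
#'
#' Same canonical bands as [default_bands()] except beta, which spans
#' 12--30 Hz for connectivity (the band tables differ between the power and
#' connectivity stages and are kept verbatim per stage).
#'
#' @return Named list of `c(low, high)` vectors in Hz.
#' @export
plv_bands <- function() {
  list(
    delta      = c(0.5, 4),
    theta      = c(4, 8),
    alpha      = c(8, 12),
    beta       = c(12, 30),
    low_gamma  = c(30, 45),
    high_gamma = c(55, 100)
  )
}

#' Frequency ranges over which the aperiodic component is fitted
#'
#' One wide range (1--200 Hz, which also supplies the offset feature) and five
#' narrow ranges targeting the beta/gamma region.
#'
#' @return Named list of `c(low, high)` vectors in Hz.
#' @export
default_fit_ranges <- function() {
  list(
    r1_200   = c(1, 200),
    r20_30   = c(20, 30),
    r20_40   = c(20, 40),
    r30_45   = c(30, 45),
    r40_60   = c(40, 60),
    r60_120  = c(60, 120)
  )
}
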