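# Recording container and on-disk formats (plain matrix + metadata, EDF).

#' Construct a multi-channel ECoG recording
#'
#' @param samples Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_meta Data frame with one row per channel. Must contain
#'   `channel_id`; typically also `patient_id`, `label` (compartment),
#'   `distance_mm` (distance from the FLAIR tumor border) and `on_tumor`.
#' @return An object of class `ecog_recording`.
#' @export
ecog_recording <- function(samples, sampling_rate, channel_meta) {
  samples <- as.matrix(samples)
  stopifnot_scalar_pos(sampling_rate, "sampling_rate")
  channel_meta <- as.data.frame(channel_meta)
  if (is.null(channel_meta$channel_id))
    stop("channel_meta must contain a `channel_id` column", call. = FALSE)
  if (nrow(channel_meta) != nrow(samples))
    stop(sprintf("channel_meta has %d rows but samples has %d channels",
                 nrow(channel_meta), nrow(samples)), call. = FALSE)
  if (anyDuplicated(channel_meta$channel_id))
    stop("duplicated channel_id in channel_meta", call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_meta = channel_meta),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  if (!is.null(x$channel_meta$label))
    print(table(x$channel_meta$label, useNA = "ifany"))
  invisible(x)
}

#' @export
dim.ecog_recording <- function(x) dim(x$samples)

#' Write a recording as a plain delimited matrix plus metadata table
#'
#' `basename.samples.tsv` holds the channels x samples matrix (no header);
#' `basename.channels.tsv` holds the channel metadata with a header row and a
#' `sampling_rate` column so the pair is self-describing.
#'
#' @param rec An [ecog_recording()].
#' @param basename Path prefix for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_recording_plain <- function(rec, basename) {
  stopifnot(inherits(rec, "ecog_recording"))
  sample_path <- paste0(basename, ".samples.tsv")
  meta_path <- paste0(basename, ".channels.tsv")
  # %.17g round-trips IEEE doubles exactly (write.table would truncate to
  # 15 significant digits)
  writeLines(apply(rec$samples, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), sample_path)
  meta <- rec$channel_meta
  meta$sampling_rate <- rec$sampling_rate
  write.table(meta, meta_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(samples = sample_path, channels = meta_path))
}

#' Read a recording written by [write_recording_plain()]
#'
#' @param basename Path prefix used when writing.
#' @return An [ecog_recording()].
#' @export
read_recording_plain <- function(basename) {
  sample_path <- paste0(basename, ".samples.tsv")
  meta_path <- paste0(basename, ".channels.tsv")
  if (!file.exists(sample_path) || !file.exists(meta_path))
    stop("missing .samples.tsv / .channels.tsv pair at ", basename, call. = FALSE)
  meta <- read.table(meta_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  samples <- as.matrix(read.table(sample_path, sep = "\t", header = FALSE))
  dimnames(samples) <- NULL
  fs <- unique(meta$sampling_rate)
  if (length(fs) != 1L)
    stop("inconsistent sampling_rate in metadata", call. = FALSE)
  meta$sampling_rate <- NULL
  ecog_recording(samples, fs, meta)
}

#' Read a recording from EDF or from the plain two-file format
#'
#' Dispatches on the file name: a path ending in `.edf` is parsed as EDF,
#' anything else is treated as a plain-format basename. When `metadata_path`
#' is given, the channel metadata table (TSV with `channel_id` and typically
#' `patient_id`, `distance_mm`, `on_tumor`) is matched to the recording's
#' channels; any recorded channel missing from the table is an error.
#'
#' @param path EDF file or plain-format basename.
#' @param metadata_path Optional TSV of per-channel metadata.
#' @return An [ecog_recording()].
#' @export
read_recording <- function(path, metadata_path = NULL) {
  rec <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_edf(path)
  } else {
    read_recording_plain(path)
  }
  if (!is.null(metadata_path)) {
    meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
    missing <- setdiff(rec$channel_meta$channel_id, meta$channel_id)
    if (length(missing))
      stop("metadata is missing channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    idx <- match(rec$channel_meta$channel_id, meta$channel_id)
    rec$channel_meta <- meta[idx, , drop = FALSE]
    rownames(rec$channel_meta) <- NULL
  }
  rec
}

# --- minimal EDF support -----------------------------------------------------
# EDF stores 16-bit integers with a per-signal physical/digital calibration,
# in 1-second data records; amplitudes therefore round-trip only to 16-bit
# quantization, while the plain format above round-trips exactly.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

# Format a numeric so its decimal representation fits an 8-byte EDF field;
# returns the string actually written, which the writer reparses so that the
# calibration used for encoding matches the header byte-for-byte.
edf_num8 <- function(v) {
  vapply(v, function(x) {
    for (d in 7:1) {
      s <- sprintf("%.*g", d, x)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent ", x, " in an 8-byte EDF field", call. = FALSE)
  }, character(1))
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records, so the sampling rate must be a positive
#' integer; a trailing partial second is truncated with a warning.
#'
#' @param rec An [ecog_recording()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ecog_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate", call. = FALSE)
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  if (n_rec * fs < ncol(rec$samples))
    warning("EDF export truncates a trailing partial second")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  pmin_s <- edf_num8(pmin_); pmax_s <- edf_num8(pmax_)
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4),
    paste(edf_pad(rec$channel_meta$channel_id, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(edf_pad(pmin_s, 8), collapse = ""),
    paste(edf_pad(pmax_s, 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = "")
  ), con, eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, cols] - pmin_[ch]) * gain[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the plain EDF layout written by [write_edf()]: equal sampling
#' rate across signals and 1-second (or equal-duration) data records.
#'
#' @param path EDF file.
#' @return An [ecog_recording()] with `channel_id` taken from signal labels.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256)
    stop("malformed EDF header (file too short)", call. = FALSE)
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  n_rec <- num(substr(hdr, 237, 244))
  rec_dur <- num(substr(hdr, 245, 252))
  ns <- num(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1)
    stop("malformed EDF header (signal/record counts)", call. = FALSE)
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      substr(sig_hdr, offset + (i - 1) * width + 1, offset + i * width),
      character(1))
  }
  labels <- trimws(fld(0, 16))
  pmin_ <- as.numeric(trimws(fld(ns * (16 + 80 + 8), 8)))
  pmax_ <- as.numeric(trimws(fld(ns * (16 + 80 + 8 + 8), 8)))
  dmin <- as.numeric(trimws(fld(ns * (16 + 80 + 8 + 8 + 8), 8)))
  dmax <- as.numeric(trimws(fld(ns * (16 + 80 + 8 + 8 + 8 + 8), 8)))
  spr <- as.numeric(trimws(fld(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8)))
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported", call. = FALSE)
  fs <- spr[1] / rec_dur
  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      cols <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      x[ch, cols] <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax[ch] - dmin[ch]) + pmin_[ch]
    }
  }
  ecog_recording(x, fs, data.frame(channel_id = labels,
                                   stringsAsFactors = FALSE))
}

#' Assign cortical compartment labels from electrode metadata
#'
#' An electrode is `tumoral` when flagged as lying on the MRI-positive /
#' macroscopically suspicious area; otherwise the distance from the FLAIR
#' tumor border decides: `close_peritumoral` for (0, 15] mm,
#' `far_peritumoral` for (15, 30] mm and `healthy` beyond 30 mm. The
#' intervals are half-open and gap-free so every nonnegative distance maps to
#' exactly one compartment. Electrodes with neither flag nor distance are
#' labeled `NA` (excluded from group statistics).
#'
#' @param meta Data frame with `on_tumor` (logical) and/or `distance_mm`
#'   columns, or a numeric vector of distances.
#' @param on_tumor Optional logical vector when `meta` is numeric.
#' @return Factor with levels [compartment_levels()].
#' @export
label_compartment <- function(meta, on_tumor = NULL) {
  if (is.data.frame(meta)) {
    distance <- meta$distance_mm
    on_tumor <- if (!is.null(meta$on_tumor)) meta$on_tumor else FALSE
  } else {
    distance <- meta
    if (is.null(on_tumor)) on_tumor <- FALSE
  }
  n <- max(length(distance), length(on_tumor))
  distance <- rep_len(if (is.null(distance)) NA_real_ else distance, n)
  on_tumor <- rep_len(ifelse(is.na(on_tumor), FALSE, on_tumor), n)
  if (any(distance < 0, na.rm = TRUE))
    stop("distance_mm must be >= 0", call. = FALSE)
  lab <- ifelse(on_tumor, "tumoral",
         ifelse(is.na(distance), NA_character_,
         ifelse(distance <= 15, "close_peritumoral",
         ifelse(distance <= 30, "far_peritumoral", "healthy"))))
  as_compartment(lab)
}
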