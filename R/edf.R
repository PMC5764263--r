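## Minimal European Data Format (EDF) I/O with base-R binary streams: the
## pre-installed stack has no EDF reader, and the format is fixed-layout
## (ASCII header blocks + 16-bit little-endian samples), so a compact
## implementation here keeps the artifact self-contained. Only continuous
## uniform-rate signals are supported.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width)
  edf_pad(formatC(x, format = "fg", digits = 6, width = 1), width)

#' Write a recording to an EDF file
#'
#' 16-bit EDF with physical units in microvolts, one-second data records,
#' per-channel symmetric physical ranges. The signal is zero-padded to a
#' whole number of records.
#'
#' @param recording An `"eeg_recording"` (requires integer `fs`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  D <- recording$data
  fs <- recording$fs
  if (fs != round(fs)) stop_config("EDF writer requires an integer fs")
  nch <- nrow(D)
  n <- ncol(D)
  ns <- as.integer(fs)
  n_rec <- ceiling(n / ns)
  if (n_rec * ns > n) D <- cbind(D, matrix(0, nch, n_rec * ns - n))
  # Round the physical range to what the 8-char header field can carry,
  # and scale with that same rounded value so writer and reader agree.
  phys_max <- signif(pmax(apply(abs(D), 1, max), 1e-6) * (1 + 1e-5), 6)
  dig <- pmin(pmax(round(sweep(D, 1, phys_max, "/") * 32767), -32767), 32767)
  header <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2000 X X X", 80),
    "01.01.00", "00.00.00",
    edf_pad(256 * (1 + nch), 8), edf_pad("", 44),
    edf_num(n_rec, 8), edf_num(1, 8), edf_num(nch, 4),
    paste(vapply(recording$channel_labels, edf_pad, "", width = 16),
          collapse = ""),
    paste(rep(edf_pad("AgAgCl electrode", 80), nch), collapse = ""),
    paste(rep(edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(-phys_max, function(p) edf_num(p, 8), ""), collapse = ""),
    paste(vapply(phys_max, function(p) edf_num(p, 8), ""), collapse = ""),
    paste(rep(edf_num(-32767, 8), nch), collapse = ""),
    paste(rep(edf_num(32767, 8), nch), collapse = ""),
    paste(rep(edf_pad("BP 0.0-inf Hz", 80), nch), collapse = ""),
    paste(rep(edf_num(ns, 8), nch), collapse = ""),
    paste(rep(edf_pad("", 32), nch), collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  arr <- array(dig, dim = c(nch, ns, n_rec)) # ch x sample x record
  v <- as.integer(aperm(arr, c(2, 1, 3)))    # sample fastest, then channel
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any continuous EDF)
#'
#' @param path EDF file.
#' @return An `"eeg_recording"` (length a whole number of records; any
#'   write-side zero padding is retained).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  num <- function(w) as.numeric(trimws(rd(w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  num(8) # header bytes
  rd(44)
  n_rec <- num(8)
  rec_dur <- num(8)
  nch <- as.integer(num(4))
  fields <- function(w) vapply(seq_len(nch), function(i) trimws(rd(w)), "")
  labels <- fields(16)
  fields(80); fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  ns <- as.integer(fields(8))
  fields(32)
  if (length(unique(ns)) != 1L)
    stop_input("mixed per-signal rates are not supported")
  ns <- ns[1]
  total <- n_rec * nch * ns
  v <- readBin(con, "integer", total, size = 2L, endian = "little",
               signed = TRUE)
  arr <- array(v, dim = c(ns, nch, n_rec))
  D <- matrix(aperm(arr, c(2, 1, 3)), nrow = nch)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  D <- sweep(sweep(D, 1, dig_min), 1, scale, "*")
  D <- sweep(D, 1, phys_min, "+")
  rownames(D) <- labels
  structure(list(data = D, fs = ns / rec_dur, channel_labels = labels,
                 events = NULL, artifact_log = NULL),
            class = "eeg_recording")
}

#' Write a BIDS-style events table
#'
#' Tab-separated, columns `onset`, `duration`, `trial_type`,
#' `block_index`, `trial_index`, and `response` when present.
#'
#' @param events Events data frame.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' Read a BIDS-style events table written by [write_events_tsv()]
#' @param path `.tsv` path.
#' @return Events data frame.
#' @export
read_events_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
             stringsAsFactors = FALSE)
}
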