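#' Preprocessing configuration
#'
#' Defaults follow the published pipeline: 0.1-50 Hz band-pass, 512 Hz
#' target rate, -1000..4000 ms block epochs, +/-100 uV rejection bound
#' (inclusive), deterministic blink-template regression, and a 0.2 uV
#' peak-to-peak flat-channel detector feeding bad-channel interpolation.
#'
#' @param band Passband `(low, high)`, Hz.
#' @param fs_target Target sampling rate after downsampling, Hz.
#' @param epoch_window `(tmin, tmax)` seconds around each block's first dot.
#' @param reject_uv Absolute amplitude rejection bound, uV.
#' @param blink_removal `"template_regression"` or `"none"`.
#' @param flat_uv Peak-to-peak threshold marking a channel flat/bad, uV.
#' @param filter_order Butterworth section order.
#' @return Validated list of class `"preproc_config"`.
#' @export
preproc_config <- function(band = c(0.1, 50), fs_target = 512,
                           epoch_window = c(-1.0, 4.0), reject_uv = 100,
                           blink_removal = c("template_regression", "none"),
                           flat_uv = 0.2, filter_order = 4) {
  blink_removal <- match.arg(blink_removal)
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= fs_target / 2)
    stop_config("band must satisfy 0 < low < high < fs_target/2")
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop_config("epoch_window must straddle 0 (tmin < 0 < tmax)")
  if (reject_uv <= 0) stop_config("reject_uv must be positive")
  structure(list(band = band, fs_target = fs_target,
                 epoch_window = epoch_window, reject_uv = reject_uv,
                 blink_removal = blink_removal, flat_uv = flat_uv,
                 filter_order = filter_order), class = "preproc_config")
}

#' Cut block-locked epochs from a continuous recording
#'
#' One epoch per block, time-locked to the block's first dot onset, using a
#' half-open sample window `[tmin, tmax)`: each epoch holds exactly
#' `round((tmax - tmin) * fs)` samples.
#'
#' @param recording An `"eeg_recording"`.
#' @param events Events data frame with `onset` (s), `trial_type`,
#'   `block_index`, `trial_index`; defaults to `recording$events`.
#' @param window `(tmin, tmax)` in seconds.
#' @return Object of class `"eeg_epochs"`: `data` (n_epochs x n_channels x
#'   n_samples array), `fs`, `tmin`, `channel_labels`, `info` (one row per
#'   epoch: `block_index`), `rejection_log`.
#' @export
epoch_recording <- function(recording, events = recording$events,
                            window = c(-1.0, 4.0)) {
  if (is.null(events)) stop_input("no events available for epoching")
  fs <- recording$fs
  dots <- events[events$trial_type == "dot", , drop = FALSE]
  if (nrow(dots) == 0L) stop_input("events contain no dot stimuli")
  first <- do.call(rbind, lapply(split(dots, dots$block_index), function(d)
    d[which.min(d$onset), c("onset", "block_index")]))
  first <- first[order(first$block_index), , drop = FALSE]
  n_samp <- round(diff(window) * fs)
  n_total <- ncol(recording$data)
  dat <- array(NA_real_,
               dim = c(nrow(first), nrow(recording$data), n_samp),
               dimnames = list(NULL, recording$channel_labels, NULL))
  for (i in seq_len(nrow(first))) {
    i0 <- round(first$onset[i] * fs) + 1L + round(window[1] * fs)
    if (i0 < 1L || i0 + n_samp - 1L > n_total)
      stop_input(sprintf(
        "epoch for block %d (dot onset %.3f s) exceeds recording bounds",
        first$block_index[i], first$onset[i]))
    dat[i, , ] <- recording$data[, i0:(i0 + n_samp - 1L)]
  }
  structure(list(data = dat, fs = fs, tmin = window[1],
                 channel_labels = recording$channel_labels,
                 info = data.frame(block_index = first$block_index),
                 rejection_log = data.frame(epoch = integer(),
                                            block_index = integer(),
                                            channel = character(),
                                            reason = character())),
            class = "eeg_epochs")
}

#' Epoch time axis, seconds relative to the first dot onset
#' @param epochs An `"eeg_epochs"` object.
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$fs
}

#' Block-level amplitude artifact rejection
#'
#' Drops a whole epoch (block) when any channel sample exceeds the bound in
#' absolute value; the bound itself is retained (inclusive). No epoch is
#' ever partially rejected. Idempotent.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param reject_uv Rejection bound, uV.
#' @return Epochs with offending blocks removed and `rejection_log` grown.
#' @export
reject_artifacts <- function(epochs, reject_uv = 100) {
  if (reject_uv <= 0) stop_config("reject_uv must be positive")
  n_ep <- dim(epochs$data)[1]
  if (n_ep == 0L) return(epochs)
  bad <- logical(n_ep)
  log_add <- list()
  for (i in seq_len(n_ep)) {
    mx <- apply(abs(epochs$data[i, , , drop = FALSE]), 2, max)
    over <- which(mx > reject_uv)
    if (length(over)) {
      bad[i] <- TRUE
      log_add[[length(log_add) + 1L]] <- data.frame(
        epoch = i, block_index = epochs$info$block_index[i],
        channel = epochs$channel_labels[over[1]],
        reason = sprintf("max |amplitude| %.1f uV > %.1f uV",
                         max(mx), reject_uv))
    }
  }
  if (any(bad)) {
    epochs$data <- epochs$data[!bad, , , drop = FALSE]
    epochs$info <- epochs$info[!bad, , drop = FALSE]
    epochs$rejection_log <- rbind(epochs$rejection_log,
                                  do.call(rbind, log_add))
  }
  epochs
}

#' Remove eye blinks by time-locked template regression
#'
#' Detects blink instants by matched filtering a frontal detection channel
#' with the stereotyped blink waveform, then removes each detected blink by
#' per-channel least-squares regression of the template at that lag. With a
#' noiseless injected blink of matching shape the cancellation is exact.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param template Blink waveform, shorter than the epoch; default
#'   [blink_template()] at the epoch rate.
#' @param min_amplitude_uv Smallest fitted frontal amplitude accepted as a
#'   blink, uV.
#' @param detect_channels Channels averaged into the detection trace.
#' @param max_per_epoch Safety cap on blinks removed per epoch.
#' @return Epochs with blink contributions regressed out; attribute
#'   `blinks_removed` counts detections.
#' @export
remove_blinks <- function(epochs, template = blink_template(epochs$fs),
                          min_amplitude_uv = 25,
                          detect_channels = c("Fp1", "Fp2"),
                          max_per_epoch = 12L) {
  nt <- length(template)
  n_samp <- dim(epochs$data)[3]
  if (nt >= n_samp) stop_config("template must be shorter than the epoch")
  det_idx <- match(detect_channels, epochs$channel_labels)
  det_idx <- det_idx[!is.na(det_idx)]
  if (length(det_idx) == 0L) det_idx <- 1L
  ss <- sum(template^2)
  n_removed <- 0L
  for (i in seq_len(dim(epochs$data)[1])) {
    for (rep in seq_len(max_per_epoch)) {
      seg_det <- matrix(epochs$data[i, det_idx, , drop = FALSE],
                        nrow = length(det_idx))
      d <- colMeans(seg_det)
      # LS template amplitude at every lag (valid part of the correlation)
      amp <- convolve(d, template, type = "filter") / ss
      k <- which.max(abs(amp))
      if (abs(amp[k]) < min_amplitude_uv) break
      idx <- k:(k + nt - 1L)
      seg <- epochs$data[i, , idx, drop = FALSE][1, , , drop = TRUE]
      beta <- as.numeric(seg %*% template) / ss
      epochs$data[i, , idx] <- seg - outer(beta, template)
      n_removed <- n_removed + 1L
    }
  }
  attr(epochs, "blinks_removed") <- n_removed
  epochs
}

#' Flag flat channels
#'
#' A channel is marked bad when its peak-to-peak amplitude within any epoch
#' falls below `flat_uv` (default 0.2 uV), the configured reading of the
#' "lowest amplitude threshold" rule.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param flat_uv Peak-to-peak threshold, uV.
#' @return Character vector of bad channel labels (possibly empty).
#' @export
detect_flat_channels <- function(epochs, flat_uv = 0.2) {
  if (dim(epochs$data)[1] == 0L) return(character())
  p2p <- apply(epochs$data, c(1, 2), function(x) diff(range(x)))
  bad <- apply(p2p < flat_uv, 2, any)
  epochs$channel_labels[bad]
}

#' Interpolate bad channels from montage neighbors
#'
#' Each bad channel is replaced by the inverse-distance weighted mean of
#' its `k` nearest good channels on the montage sphere.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param bad_labels Labels of channels to rebuild.
#' @param montage Montage supplying 3-D positions.
#' @param k Number of neighbors (default 4).
#' @return Epochs with bad channels replaced.
#' @export
interpolate_bad_channels <- function(epochs, bad_labels,
                                     montage = montage_1020_32(), k = 4L) {
  if (length(bad_labels) == 0L) return(epochs)
  bad_labels <- unique(bad_labels)
  if (!all(bad_labels %in% epochs$channel_labels))
    stop_input("unknown channel label(s): ",
               paste(setdiff(bad_labels, epochs$channel_labels), collapse = ", "))
  good <- setdiff(epochs$channel_labels, bad_labels)
  if (length(good) == 0L)
    stop_input("all channels marked bad; interpolation impossible")
  pos <- montage$positions
  for (lab in bad_labels) {
    d <- sqrt(rowSums(sweep(pos[good, , drop = FALSE], 2, pos[lab, ])^2))
    nb <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / d[order(d)][seq_len(length(nb))]
    w <- w / sum(w)
    bi <- match(lab, epochs$channel_labels)
    ni <- match(nb, epochs$channel_labels)
    for (i in seq_len(dim(epochs$data)[1])) {
      neigh <- epochs$data[i, ni, , drop = FALSE][1, , , drop = TRUE]
      epochs$data[i, bi, ] <- as.numeric(w %*% matrix(neigh, nrow = length(ni)))
    }
  }
  epochs
}

#' Full preprocessing chain
#'
#' Fixed stage order: band-pass filter, downsample, epoch, blink removal,
#' block-level rejection, flat-channel interpolation.
#'
#' @param recording An `"eeg_recording"`.
#' @param events Events data frame (default `recording$events`).
#' @param config A [preproc_config()].
#' @param montage Montage for interpolation.
#' @return Cleaned `"eeg_epochs"`.
#' @export
preprocess_recording <- function(recording, events = recording$events,
                                 config = preproc_config(),
                                 montage = montage_1020_32()) {
  stopifnot(inherits(config, "preproc_config"))
  rec <- recording
  rec$data <- bandpass_filter(rec$data, rec$fs, config$band,
                              config$filter_order)
  if (config$fs_target < rec$fs) {
    rec$data <- resample_signal(rec$data, rec$fs, config$fs_target)
    rec$fs <- config$fs_target
  }
  ep <- epoch_recording(rec, events, config$epoch_window)
  if (config$blink_removal == "template_regression")
    ep <- remove_blinks(ep)
  ep <- reject_artifacts(ep, config$reject_uv)
  bad <- detect_flat_channels(ep, config$flat_uv)
  if (length(bad) > 0L && length(bad) < length(ep$channel_labels))
    ep <- interpolate_bad_channels(ep, bad, montage)
  ep
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (tmin %.2f s), %d rejected\n",
              d[1], d[2], d[3], x$fs, x$tmin, nrow(x$rejection_log)))
  invisible(x)
}
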