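#' Canonical frequency bands
#'
#' Mu 8-12 Hz and beta 13-20 Hz, the two non-overlapping sensorimotor bands
#' used throughout the analysis.
#' @return Named list of `(low, high)` pairs in Hz.
#' @export
band_definitions <- function() list(mu = c(8, 12), beta = c(13, 20))

#' Default trial windows within an epoch
#'
#' First three dot trials relative to the first dot onset: 0.0-0.8,
#' 1.3-2.1 and 2.6-3.4 s.
#' @return List of `(start, end)` pairs in seconds.
#' @export
trial_windows <- function() list(c(0.0, 0.8), c(1.3, 2.1), c(2.6, 3.4))

## Complex Morlet wavelet at frequency f (Hz), n_cycles cycles, truncated
## at +/-3.5 temporal SDs.
morlet_wavelet <- function(f, fs, n_cycles = 7) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-3.5 * sigma_t, 3.5 * sigma_t, by = 1 / fs)
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2)) # unit energy; absolute scale cancels in ERSP
}

#' Event-related spectral perturbation
#'
#' Time-frequency power by Morlet wavelet convolution (7 cycles), averaged
#' over epochs, expressed per channel and frequency as
#' `10 * log10(power / mean baseline power)` (divisive pre-stimulus
#' baseline). By construction the map is invariant to any global amplitude
#' scaling of the data.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param freqs Analysis frequencies, Hz (default 4-30 Hz in 1 Hz steps).
#' @param baseline_window `(start, end)` seconds, must lie within
#'   `[tmin, 0]`.
#' @param n_cycles Wavelet cycles.
#' @param channels Optional subset of channel labels to analyze.
#' @return Object of class `"ersp_map"`: `values` (n_channels x n_freqs x
#'   n_times, dB), `freqs`, `times`, `baseline_window`, `channel_labels`.
#' @export
compute_ersp <- function(epochs, freqs = 4:30,
                         baseline_window = c(epochs$tmin, 0), n_cycles = 7,
                         channels = NULL) {
  times <- epoch_times(epochs)
  if (baseline_window[1] < epochs$tmin - 1e-9 || baseline_window[2] > 1e-9 ||
      baseline_window[1] >= baseline_window[2])
    stop_config("baseline_window must be a nonempty interval inside [tmin, 0]")
  labels <- channels %||% epochs$channel_labels
  ch_idx <- match(labels, epochs$channel_labels)
  if (anyNA(ch_idx)) stop_input("unknown channel(s): ",
                                paste(labels[is.na(ch_idx)], collapse = ", "))
  n_ep <- dim(epochs$data)[1]
  n_samp <- dim(epochs$data)[3]
  vals <- array(NA_real_, dim = c(length(ch_idx), length(freqs), n_samp),
                dimnames = list(labels, NULL, NULL))
  bl_all <- which(times >= baseline_window[1] & times < baseline_window[2])
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], epochs$fs, n_cycles)
    nt <- length(w)
    nfft <- 2^ceiling(log2(n_samp + nt - 1L))
    W <- fft(c(w, complex(length.out = nfft - nt)))
    off <- (nt - 1L) %/% 2L # center alignment of the convolution
    # The baseline mean skips samples within half the wavelet support of
    # the epoch start, where the implicit zero padding attenuates power
    # (otherwise low frequencies acquire a map-wide bias). If the guard
    # would consume the whole window, the later half is used instead.
    guard <- times[1] + (nt %/% 2L) / epochs$fs
    bl_idx <- bl_all[times[bl_all] >= guard]
    if (length(bl_idx) < max(2L, length(bl_all) %/% 4L))
      bl_idx <- bl_all[times[bl_all] >= mean(range(times[bl_all]))]
    for (ci in seq_along(ch_idx)) {
      sig <- matrix(epochs$data[, ch_idx[ci], ], nrow = n_ep)
      X <- matrix(0, nfft, n_ep)
      X[seq_len(n_samp), ] <- t(sig)
      conv <- mvfft(mvfft(X) * W, inverse = TRUE) / nfft
      pow <- rowMeans(Mod(conv[(off + 1L):(off + n_samp), , drop = FALSE])^2)
      vals[ci, fi, ] <- 10 * log10(pow / mean(pow[bl_idx]))
    }
  }
  structure(list(values = vals, freqs = freqs, times = times,
                 baseline_window = baseline_window, channel_labels = labels),
            class = "ersp_map")
}

#' Band- and window-averaged ERSP
#'
#' Arithmetic mean of the dB map over a frequency band x time window
#' rectangle, per channel.
#'
#' @param ersp An `"ersp_map"`.
#' @param band `(low, high)` Hz, or a name from [band_definitions()].
#' @param window `(start, end)` seconds.
#' @return Named numeric vector, one dB value per channel.
#' @export
band_average <- function(ersp, band = "mu", window = c(0, 0.8)) {
  if (is.character(band)) band <- band_definitions()[[match.arg(
    band, names(band_definitions()))]]
  fi <- which(ersp$freqs >= band[1] & ersp$freqs <= band[2])
  ti <- which(ersp$times >= window[1] & ersp$times < window[2])
  if (length(fi) == 0L || length(ti) == 0L)
    stop_config("empty band/window selection")
  out <- apply(ersp$values[, fi, ti, drop = FALSE], 1, mean)
  names(out) <- ersp$channel_labels
  out
}

#' Event-related desynchronization index at one channel
#'
#' Band/window-averaged ERSP restricted to a named channel (typically C3
#' or C4); negative values indicate desynchronization.
#'
#' @inheritParams band_average
#' @param channel Channel label.
#' @return Scalar dB value.
#' @export
erd_index <- function(ersp, channel = "C3", band = "mu", window = c(0, 0.8)) {
  if (!channel %in% ersp$channel_labels)
    stop_input("channel '", channel, "' not in the ERSP map")
  band_average(ersp, band, window)[[channel]]
}

#' Per-channel band/window table
#'
#' Band averages for every combination of [band_definitions()] and
#' [trial_windows()], one row per channel x band x window (topography
#' table).
#'
#' @param ersp An `"ersp_map"`.
#' @return Data frame with `channel`, `band`, `window_start`, `window_end`,
#'   `ersp_db`.
#' @export
ersp_band_table <- function(ersp) {
  rows <- list()
  for (bn in names(band_definitions())) {
    for (w in trial_windows()) {
      v <- band_average(ersp, bn, w)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = names(v), band = bn, window_start = w[1],
        window_end = w[2], ersp_db = as.numeric(v))
    }
  }
  do.call(rbind, rows)
}
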