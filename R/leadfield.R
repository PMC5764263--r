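#' Synthetic Gaussian-spread lead field
#'
#' Gain from each source to each electrode falls off as a Gaussian of the
#' 3-D distance between the source and the electrode position. This stands
#' in for a boundary-element forward model: it preserves the two properties
#' downstream analyses rely on (spatial smearing and contralateral
#' weighting, e.g. left M1 projecting most strongly to C3) while remaining
#' fully self-contained.
#'
#' @param montage An [montage_1020_32()] montage.
#' @param roiset A [default_roiset()]; its four centers are the first four
#'   source columns, in node order.
#' @param n_distractors Number of additional background sources scattered
#'   on a shell below the electrode sphere (default 20).
#' @param sigma_mm Gaussian spatial-spread scale, mm.
#' @param gain_scale Peak gain, microvolts per source unit.
#' @param seed Integer seed controlling distractor placement.
#' @return Object of class `"lead_field"`: `gain` (n_channels x n_sources,
#'   uV per source unit), `channel_labels`, `source_positions`,
#'   `source_labels` (ROI names then `distractor_i`).
#' @export
simulate_leadfield <- function(montage = montage_1020_32(),
                               roiset = default_roiset(),
                               n_distractors = 20, sigma_mm = 25,
                               gain_scale = 50, seed = 1L) {
  if (!is_count(n_distractors)) stop_config("n_distractors must be >= 0")
  src <- roiset$centers
  if (n_distractors > 0) {
    dpos <- with_seed(seed, {
      u <- matrix(rnorm(3 * n_distractors), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- runif(n_distractors, 0.55, 0.8) * montage$radius_mm
      u * r
    })
    rownames(dpos) <- paste0("distractor_", seq_len(n_distractors))
    colnames(dpos) <- c("x", "y", "z")
    src <- rbind(src, dpos)
  }
  d2 <- outer(seq_len(nrow(montage$positions)), seq_len(nrow(src)),
              Vectorize(function(i, j) sum((montage$positions[i, ] - src[j, ])^2)))
  gain <- gain_scale * exp(-d2 / (2 * sigma_mm^2))
  dimnames(gain) <- list(montage$labels, rownames(src))
  if (any(!is.finite(gain)) || any(rowSums(abs(gain)) == 0))
    stop_config("invalid lead field: non-finite entries or all-zero channel row")
  structure(list(gain = gain, channel_labels = montage$labels,
                 source_positions = src, source_labels = rownames(src),
                 montage = montage),
            class = "lead_field")
}

## 1/f ("pink") noise via spectral shaping; unit variance, then scaled.
pink_noise <- function(n, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  sd * x / sd(x)
}

#' Project source activity to the scalp
#'
#' `data = gain %*% sources` plus independent pink (1/f) and white sensor
#' noise per channel.
#'
#' @param sources n_sources x n_samples matrix (source units).
#' @param leadfield A [simulate_leadfield()] object, or any list with a
#'   `gain` matrix whose column count equals `nrow(sources)`.
#' @param fs Sampling rate, Hz.
#' @param noise List with `pink_sd` and `sensor_sd` (uV).
#' @param events Optional events data frame (carried through).
#' @param seed Integer seed.
#' @return Object of class `"eeg_recording"`: `data` (n_channels x
#'   n_samples, uV), `fs`, `channel_labels`, `events`, `artifact_log`.
#' @export
project_to_scalp <- function(sources, leadfield, fs,
                             noise = list(pink_sd = 4, sensor_sd = 2),
                             events = NULL, seed = 1L) {
  sources <- as.matrix(sources)
  gain <- leadfield$gain
  if (ncol(gain) != nrow(sources))
    stop_input("lead field has ", ncol(gain), " sources but sources has ",
               nrow(sources), " rows")
  data <- gain %*% sources
  n <- ncol(data)
  pink_sd <- noise$pink_sd %||% 0
  sensor_sd <- noise$sensor_sd %||% 0
  if (pink_sd > 0 || sensor_sd > 0) {
    data <- data + with_seed(seed, {
      nz <- matrix(0, nrow(data), n)
      for (ch in seq_len(nrow(data))) {
        if (pink_sd > 0) nz[ch, ] <- pink_noise(n, pink_sd)
        if (sensor_sd > 0) nz[ch, ] <- nz[ch, ] + rnorm(n, sd = sensor_sd)
      }
      nz
    })
  }
  labels <- leadfield$channel_labels %||% rownames(gain) %||%
    paste0("ch", seq_len(nrow(gain)))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, channel_labels = labels,
                 events = events, artifact_log = NULL),
            class = "eeg_recording")
}

#' Stereotyped eye-blink waveform
#'
#' Fixed biphasic 400 ms template (large positive lobe, small negative
#' rebound), unit peak amplitude.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Template length, seconds.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
blink_template <- function(fs, duration_s = 0.4) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  w <- sin(pi * t / duration_s)^2 * (1.25 * exp(-((t - 0.12)^2) / (2 * 0.05^2)) -
                                     0.35 * exp(-((t - 0.27)^2) / (2 * 0.07^2)))
  w / max(abs(w))
}

## Frontal-proximity channel weights for the blink topography: Gaussian in
## distance from a point above the nasion (between the eyes).
blink_weights <- function(montage, sigma_mm = 55) {
  eye <- c(0, montage$radius_mm, -0.25 * montage$radius_mm)
  d2 <- rowSums(sweep(montage$positions, 2, eye)^2)
  w <- exp(-d2 / (2 * sigma_mm^2))
  w / max(w)
}

#' Inject eye blinks and amplitude artifacts
#'
#' Adds frontal-weighted biphasic blink transients at Poisson times and
#' optional large spikes at specified samples/channels. Injection times are
#' logged in `artifact_log` so removal and rejection can be tested against
#' ground truth.
#'
#' @param recording An `"eeg_recording"`.
#' @param blink_rate Blinks per second (Poisson rate, >= 0).
#' @param blink_amplitude_uv Peak blink amplitude at the most frontal
#'   channel, uV.
#' @param spikes Optional data frame with columns `sample`, `channel`
#'   (label or index), `amplitude_uv`: deterministic square spikes of
#'   50 ms.
#' @param montage Montage used for the frontal weighting (defaults to the
#'   standard 32-channel cap).
#' @param seed Integer seed (blink times only).
#' @return The recording with artifacts added and `artifact_log` set to a
#'   list with `blink_onsets` (samples) and `spikes`.
#' @export
inject_artifacts <- function(recording, blink_rate = 0.2,
                             blink_amplitude_uv = 90, spikes = NULL,
                             montage = montage_1020_32(), seed = 1L) {
  if (blink_rate < 0) stop_config("blink_rate must be >= 0")
  data <- recording$data
  n <- ncol(data)
  fs <- recording$fs
  tmpl <- blink_template(fs)
  wts <- blink_weights(montage)[recording$channel_labels]
  wts[is.na(wts)] <- 0
  blink_onsets <- integer(0)
  if (blink_rate > 0) {
    blink_onsets <- with_seed(seed, {
      # Poisson process: exponential gaps
      gaps <- rexp(ceiling(blink_rate * n / fs * 3) + 10, rate = blink_rate)
      on <- cumsum(gaps)
      round(on[on < (n - length(tmpl)) / fs] * fs) + 1L
    })
    for (on in blink_onsets) {
      idx <- on:(on + length(tmpl) - 1L)
      data[, idx] <- data[, idx] +
        blink_amplitude_uv * outer(wts, tmpl)
    }
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    for (i in seq_len(nrow(spikes))) {
      ch <- spikes$channel[i]
      if (is.character(ch)) ch <- match(ch, recording$channel_labels)
      idx <- spikes$sample[i]:min(n, spikes$sample[i] + round(0.05 * fs))
      data[ch, idx] <- data[ch, idx] + spikes$amplitude_uv[i]
    }
  }
  recording$data <- data
  recording$artifact_log <- list(blink_onsets = blink_onsets,
                                 blink_amplitude_uv = blink_amplitude_uv,
                                 spikes = spikes)
  recording
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}
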