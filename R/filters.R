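## IIR filter design and zero-phase filtering. The pre-installed stack has
## no DSP package, so Butterworth design (bilinear transform) and
## forward-backward filtering are implemented here and checked in the tests
## against the closed-form magnitude response.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

polyval_z <- function(p, z) {
  out <- 0 + 0i
  for (pi in p) out <- out * z + pi
  out
}

#' Digital Butterworth filter coefficients
#'
#' Bilinear-transform design of an order-`n` lowpass or highpass section.
#' A band-pass is applied as a highpass/lowpass cascade (see
#' [bandpass_filter()]).
#'
#' @param n Filter order (number of poles of this section).
#' @param wc_hz Cutoff frequency, Hz (-3 dB point).
#' @param fs Sampling rate, Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b`, denominator `a` (a\[1\] = 1), and
#'   `sos`, the equivalent cascade of second-order sections used for
#'   filtering (polynomial forms above order ~6 are numerically fragile
#'   for narrow highpass cutoffs; the cascade is not).
#' @export
butter_design <- function(n, wc_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (wc_hz <= 0 || wc_hz >= fs / 2)
    stop_config("cutoff must satisfy 0 < wc < fs/2 (Nyquist)")
  Wc <- 2 * fs * tan(pi * wc_hz / fs) # prewarped analog cutoff (rad/s)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n)) # unit LHP Butterworth poles
  p <- if (type == "low") Wc * proto else Wc / proto
  zp <- (2 * fs + p) / (2 * fs - p)               # bilinear poles
  z0 <- if (type == "low") -1 + 0i else 1 + 0i    # digital zeros
  zref <- if (type == "low") 1 + 0i else -1 + 0i  # unity at DC / Nyquist
  # second-order sections from conjugate pole pairs
  half <- n %/% 2
  sos <- vector("list", half + n %% 2)
  for (s in seq_len(half)) {
    pr <- c(p[s], Conj(p[s]))
    a_s <- Re(poly_from_roots((2 * fs + pr) / (2 * fs - pr)))
    b_s <- Re(poly_from_roots(c(z0, z0)))
    g_s <- Re(polyval_z(a_s, zref) / polyval_z(b_s, zref))
    sos[[s]] <- list(b = b_s * g_s, a = a_s)
  }
  if (n %% 2 == 1) { # middle real pole
    pr <- p[half + 1]
    a_s <- Re(poly_from_roots((2 * fs + pr) / (2 * fs - pr)))
    b_s <- Re(poly_from_roots(z0))
    g_s <- Re(polyval_z(a_s, zref) / polyval_z(b_s, zref))
    sos[[half + 1]] <- list(b = b_s * g_s, a = a_s)
  }
  b <- Re(poly_from_roots(rep(z0, n)))
  a <- Re(poly_from_roots(zp))
  g <- Re(polyval_z(a, zref) / polyval_z(b, zref))
  list(b = b * g, a = a, sos = sos)
}

#' Magnitude response of a digital filter
#' @param coef List with `b`, `a` from [butter_design()].
#' @param f Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @return `|H(f)|`, linear amplitude.
#' @export
filter_response <- function(coef, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  if (!is.null(coef$sos)) {
    out <- rep(1, length(z))
    for (s in coef$sos)
      out <- out * abs(polyval_z(s$b, z) / polyval_z(s$a, z))
    return(out)
  }
  abs(polyval_z(coef$b, z) / polyval_z(coef$a, z))
}

iir_one <- function(b, a, x) {
  n <- length(x)
  v <- if (length(b) == 1L) b * x
       else convolve(x, rev(b), type = "open")[seq_len(n)]
  if (length(a) == 1L) return(v / a)
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

iir_filter <- function(coef, x) {
  if (!is.null(coef$sos)) {
    for (s in coef$sos) x <- iir_one(s$b, s$a, x)
    return(x)
  }
  iir_one(coef$b, coef$a, x)
}

## Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_1 <- function(coef, x, padlen = NULL) {
  n <- length(x)
  padlen <- min(n - 1L, padlen %||% (3L * (length(coef$a) - 1L) * 25L))
  xf <- c(2 * x[1] - x[(padlen + 1L):2L], x,
          2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- iir_filter(coef, xf)
  y <- rev(iir_filter(coef, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-`order` highpass at `band[1]` cascaded with order-`order` lowpass
#' at `band[2]`, each applied forward and backward (zero phase, squared
#' magnitude response). Default band 0.1-50 Hz.
#'
#' @param data Numeric vector or channels-by-samples matrix (uV).
#' @param fs Sampling rate, Hz.
#' @param band Length-2 numeric `(low, high)`, Hz.
#' @param order Order of each section (default 4).
#' @return Filtered data, same shape.
#' @export
bandpass_filter <- function(data, fs, band = c(0.1, 50), order = 4) {
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2] ||
      band[2] >= fs / 2)
    stop_config("band must satisfy 0 < low < high < fs/2")
  hp <- butter_design(order, band[1], fs, "high")
  lp <- butter_design(order, band[2], fs, "low")
  apply_fn <- function(x) filtfilt_1(lp, filtfilt_1(hp, x, padlen = round(fs)),
                                     padlen = round(fs))
  if (is.matrix(data)) {
    out <- t(apply(data, 1L, apply_fn))
    dimnames(out) <- dimnames(data)
    out
  } else apply_fn(data)
}

#' Fourier-method resampling (downsampling)
#'
#' Band-limited sinc resampling by spectral truncation; output length is
#' `round(n * fs_out / fs_in)`.
#'
#' @param data Numeric vector or channels-by-samples matrix.
#' @param fs_in,fs_out Input/output sampling rates, Hz; `fs_out <= fs_in`.
#' @return Resampled data.
#' @export
resample_signal <- function(data, fs_in, fs_out) {
  if (fs_out > fs_in)
    stop_config("upsampling not supported (fs_out > fs_in)")
  if (fs_out == fs_in) return(data)
  one <- function(x) {
    n <- length(x)
    m <- round(n * fs_out / fs_in)
    X <- fft(x)
    Y <- complex(length.out = m)
    h <- m %/% 2
    if (m %% 2 == 1) {
      Y[1:(h + 1)] <- X[1:(h + 1)]
      if (h > 0) Y[(m - h + 1):m] <- X[(n - h + 1):n]
    } else {
      Y[1:h] <- X[1:h]
      Y[h + 1] <- Re(X[h + 1]) # fold the new Nyquist bin, keep output real
      if (h > 1) Y[(m - h + 2):m] <- X[(n - h + 2):n]
    }
    Re(fft(Y, inverse = TRUE)) / n
  }
  if (is.matrix(data)) {
    out <- t(apply(data, 1L, one))
    rownames(out) <- rownames(data)
    out
  } else one(data)
}
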