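#' Specify a bilinear dynamic causal model
#'
#' The neural model is the bilinear state-space
#' `dx/dt = (A + u_mod B) x + C u_drive` over the four ROIs, with a fixed
#' self-decay of -1/s on the diagonal of `A` and free parameters only
#' where the masks allow. Observation: each ROI state is read out through
#' a free per-ROI gain (prior N(1, 1/16)) plus Gaussian noise, absorbing
#' the arbitrary sign/scale of minimum-norm ROI series.
#'
#' Priors (shrinkage, standard for this model class): free A entries
#' N(0, 1/16), B entries N(0, 1/16), the single C entry N(0, 1), noise
#' precision Gamma(shape 2, rate 1).
#'
#' @param input_region `"PMC"` or `"SMA"` (fixes the one nonzero C entry).
#' @param structure Modulatory structure 1..8, see [b_mask_structure()].
#' @param a_mask,b_mask Optional explicit binary masks (row = target,
#'   col = source) overriding the defaults; DLPFC<->M1 must be zero.
#' @param self_decay Fixed diagonal of A, 1/s (strictly negative).
#' @param priors Optional list overriding `a_var`, `b_var`, `c_var`,
#'   `gain_mean`, `gain_var`.
#' @param noise_prior List with Gamma `shape` and `rate` for the
#'   observation noise precision.
#' @return Object of class `"dcm_spec"`.
#' @export
dcm_spec <- function(input_region = c("PMC", "SMA"), structure = 1,
                     a_mask = NULL, b_mask = NULL, self_decay = -1,
                     priors = list(), noise_prior = list(shape = 2, rate = 1)) {
  input_region <- match.arg(input_region)
  a_mask <- a_mask %||% a_mask_default()
  b_mask <- b_mask %||% b_mask_structure(structure, input_region)
  for (m in list(a_mask, b_mask)) {
    if (m["M1", "DLPFC"] != 0 || m["DLPFC", "M1"] != 0)
      stop_config("DLPFC<->M1 mask entries must be zero")
  }
  if (any(diag(b_mask) != 0))
    stop_config("diagonal self-modulation is not a free parameter")
  if (self_decay >= 0) stop_config("self_decay must be negative")
  pr <- modifyList(list(a_var = 1 / 16, b_var = 1 / 16, c_var = 1,
                        gain_mean = 1, gain_var = 1 / 16), priors)
  a_idx <- which(a_mask != 0 & row(a_mask) != col(a_mask))
  b_idx <- which(b_mask != 0)
  c_idx <- match(input_region, roi_nodes())
  nodes <- roi_nodes()
  nm <- function(idx, tag) sprintf("%s_%s<-%s", tag,
                                   nodes[(idx - 1) %% 4 + 1],
                                   nodes[(idx - 1) %/% 4 + 1])
  par_names <- c(nm(a_idx, "A"), nm(b_idx, "B"),
                 paste0("C_", input_region), paste0("gain_", nodes))
  prior_mean <- c(rep(0, length(a_idx)), rep(0, length(b_idx)), 0,
                  rep(pr$gain_mean, 4))
  prior_var <- c(rep(pr$a_var, length(a_idx)), rep(pr$b_var, length(b_idx)),
                 pr$c_var, rep(pr$gain_var, 4))
  names(prior_mean) <- names(prior_var) <- par_names
  structure(list(nodes = nodes, input_region = input_region,
                 structure = structure, a_mask = a_mask, b_mask = b_mask,
                 c_mask = c_mask_input(input_region),
                 self_decay = self_decay,
                 a_idx = a_idx, b_idx = b_idx, c_idx = c_idx,
                 n_a = length(a_idx), n_b = length(b_idx),
                 prior_mean = prior_mean, prior_var = prior_var,
                 noise_prior = noise_prior), class = "dcm_spec")
}

## theta layout: [A free | B free | C | gains(4)]
dcm_unpack <- function(spec, theta) {
  A <- matrix(0, 4, 4, dimnames = list(spec$nodes, spec$nodes))
  diag(A) <- spec$self_decay
  A[spec$a_idx] <- theta[seq_len(spec$n_a)]
  B <- matrix(0, 4, 4, dimnames = list(spec$nodes, spec$nodes))
  B[spec$b_idx] <- theta[spec$n_a + seq_len(spec$n_b)]
  Cv <- numeric(4)
  Cv[spec$c_idx] <- theta[spec$n_a + spec$n_b + 1L]
  gains <- theta[spec$n_a + spec$n_b + 1L + 1:4]
  list(A = A, B = B, C = Cv, gains = gains)
}

#' Predicted ROI series under a DCM parameter vector
#'
#' Deterministic integration of the bilinear system (shared compiled
#' integrator, RK4) followed by the per-ROI gain readout.
#'
#' @param spec A [dcm_spec()].
#' @param theta Parameter vector in spec order (`spec$prior_mean` names).
#' @param inputs List with `u_drive`, `u_mod`, `dt`.
#' @param method Integration method, `"rk4"` or `"euler"`.
#' @return 4 x n predicted ROI matrix.
#' @export
dcm_integrate <- function(spec, theta, inputs, method = c("rk4", "euler")) {
  method <- match.arg(method)
  p <- dcm_unpack(spec, theta)
  x <- .integrate_bilinear_c(p$A, p$B, p$C, as.numeric(inputs$u_drive),
                             as.numeric(inputs$u_mod), inputs$dt,
                             if (method == "euler") 0L else 1L)
  out <- p$gains * x
  rownames(out) <- spec$nodes
  out
}

#' Canonical DCM inputs for a three-trial block window
#'
#' Dot onsets at 0, 1.3 and 2.6 s on a `[0, duration)` grid at `fs` Hz:
#' driving boxcars of `drive_duration` seconds, modulatory boxcars of
#' `dot_duration` seconds, matching the generator's conventions.
#'
#' @param fs Model sampling rate, Hz (default 64).
#' @param duration Window length, seconds.
#' @param onsets Trial onsets, seconds.
#' @param drive_duration,dot_duration Boxcar lengths, seconds.
#' @return List with `u_drive`, `u_mod`, `dt`, `n`.
#' @export
dcm_inputs <- function(fs = 64, duration = 4, onsets = c(0, 1.3, 2.6),
                       drive_duration = 0.2, dot_duration = 0.8) {
  n <- round(duration * fs)
  u_drive <- numeric(n)
  u_mod <- numeric(n)
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    u_drive[i0:min(n, i0 + round(drive_duration * fs) - 1L)] <- 1
    u_mod[i0:min(n, i0 + round(dot_duration * fs) - 1L)] <- 1
  }
  list(u_drive = u_drive, u_mod = u_mod, dt = 1 / fs, n = n)
}

#' Invert a DCM on ROI data
#'
#' Variational-Laplace inversion (see [vl_invert()]) of the bilinear model
#' on a 4 x n ROI data matrix. Initialization is deterministic at the
#' prior mean; unstable parameter proposals produce clamped trajectories
#' with huge residuals and are rejected by the damped line search rather
#' than raising.
#'
#' @param spec A [dcm_spec()].
#' @param roi_data 4 x n matrix, rows in node order PMC, SMA, M1, DLPFC.
#' @param inputs List with `u_drive`, `u_mod`, `dt` (see [dcm_inputs()]).
#' @param max_iter,tol Convergence controls (defaults 64, 1e-2 nats).
#' @param noise Optional fixed-noise override
#'   `list(fixed = TRUE, precision = h)`.
#' @return Object of class `"dcm_fit"`: `posterior_mean`, `posterior_cov`,
#'   `free_energy`, `predicted` (4 x n), `B` (4 x 4 posterior-mean
#'   modulatory matrix), `iterations`, `converged`, `spec`.
#' @export
dcm_invert <- function(spec, roi_data, inputs, max_iter = 64L, tol = 1e-2,
                       noise = NULL) {
  roi_data <- as.matrix(roi_data)
  if (nrow(roi_data) != 4L || ncol(roi_data) != length(inputs$u_drive))
    stop_input("roi_data must be 4 x length(inputs$u_drive)")
  if (any(!is.finite(roi_data))) stop_input("roi_data must be finite")
  y <- as.numeric(roi_data)
  f <- function(theta) as.numeric(dcm_integrate(spec, theta, inputs))
  nz <- noise %||% list(shape = spec$noise_prior$shape,
                        rate = spec$noise_prior$rate)
  fit <- vl_invert(f, y, spec$prior_mean, diag(spec$prior_var),
                   noise = nz, max_iter = max_iter, tol = tol)
  p <- dcm_unpack(spec, fit$mean)
  structure(list(posterior_mean = setNames(fit$mean, names(spec$prior_mean)),
                 posterior_cov = fit$cov, free_energy = fit$free_energy,
                 precision = fit$precision,
                 predicted = matrix(fit$predicted, 4,
                                    dimnames = list(spec$nodes, NULL)),
                 B = p$B, A = p$A, C = p$C, gains = p$gains,
                 iterations = fit$iterations, converged = fit$converged,
                 spec = spec), class = "dcm_fit")
}

#' Simulate ROI data from a DCM at a given signal-to-noise ratio
#'
#' Generates the noiseless prediction at `theta` and adds white Gaussian
#' noise scaled to the requested SNR (signal power / noise power, dB)
#' computed over the nonzero part of the signal.
#'
#' @param spec A [dcm_spec()].
#' @param theta True parameter vector.
#' @param inputs DCM inputs.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` for noiseless.
#' @param seed Integer seed.
#' @return List with `roi_data` (4 x n), `clean`, `noise_sd`.
#' @export
dcm_simulate <- function(spec, theta, inputs, snr_db = 10, seed = 1L) {
  clean <- dcm_integrate(spec, theta, inputs)
  sig_pow <- mean(clean^2)
  noise_sd <- if (is.infinite(snr_db)) 0 else
    sqrt(sig_pow / 10^(snr_db / 10))
  noisy <- clean + with_seed(seed,
    matrix(rnorm(length(clean), sd = noise_sd), nrow(clean)))
  list(roi_data = noisy, clean = clean, noise_sd = noise_sd)
}

#' Free energy of a DCM posterior
#'
#' Evaluates the variational free energy of an arbitrary Gaussian
#' posterior over the spec's parameters given ROI data (see
#' [vl_free_energy()]).
#'
#' @param spec A [dcm_spec()].
#' @param posterior List with `mean`, `cov`.
#' @param roi_data 4 x n data matrix.
#' @param inputs DCM inputs.
#' @param noise Noise model passed through to [vl_free_energy()]; default
#'   the spec's Gamma prior.
#' @return Nats.
#' @export
dcm_free_energy <- function(spec, posterior, roi_data, inputs, noise = NULL) {
  f <- function(theta) as.numeric(dcm_integrate(spec, theta, inputs))
  vl_free_energy(f, as.numeric(as.matrix(roi_data)), posterior,
                 spec$prior_mean, diag(spec$prior_var),
                 noise %||% list(shape = spec$noise_prior$shape,
                                 rate = spec$noise_prior$rate))
}

#' Ground-truth parameter vector for a spec
#'
#' Packs a [motor_network()]'s A/B/C (plus unit gains) into the spec's
#' parameter order; network entries outside the spec's masks are dropped.
#'
#' @param spec A [dcm_spec()].
#' @param net A [motor_network()].
#' @return Named numeric vector aligned with `spec$prior_mean`.
#' @export
dcm_theta_from_network <- function(spec, net) {
  theta <- c(net$A[spec$a_idx], net$B[spec$b_idx], net$C[spec$c_idx],
             rep(1, 4))
  setNames(theta, names(spec$prior_mean))
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %s-input structure %d: F = %.2f nats, %d iter%s\n",
              x$spec$input_region, x$spec$structure, x$free_energy,
              x$iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}
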