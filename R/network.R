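#' Ground-truth bilinear network over {PMC, SMA, M1, DLPFC}
#'
#' Constructs the generative network used by the simulator: intrinsic
#' couplings `A` (1/s, fixed self-decay -1/s on the diagonal), task-related
#' modulatory gains `B` (unitless, active while a dot trial is performed),
#' and a driving-input gain vector `C` that is nonzero only at the input
#' region (PMC for execution-like, SMA for imagery-like input routing).
#' DLPFC<->M1 connections are structurally absent in `A` and `B`.
#'
#' @param input_region `"PMC"` or `"SMA"`.
#' @param structure Within-family modulatory structure 1..8 (see
#'   [b_mask_structure()]); default 2, the structure reported best-fitting.
#' @param A,B,C Optional explicit matrices/vector overriding the defaults;
#'   must respect the structural zeros.
#' @param a_offdiag Default magnitude of allowed intrinsic couplings.
#' @param b_forward,b_backward Default modulatory gains on forward
#'   (toward M1 / from DLPFC) and backward edges.
#' @param c_gain Driving-input gain at the input region.
#' @return Object of class `"motor_network"`.
#' @export
motor_network <- function(input_region = c("PMC", "SMA"), structure = 2,
                          A = NULL, B = NULL, C = NULL,
                          a_offdiag = 0.3, b_forward = 0.3,
                          b_backward = -0.2, c_gain = 1) {
  input_region <- match.arg(input_region)
  nodes <- roi_nodes()
  am <- a_mask_default()
  if (is.null(A)) {
    A <- am * a_offdiag
    diag(A) <- -1
  }
  if (is.null(B)) {
    bm <- b_mask_structure(structure, input_region)
    fwd <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
    fwd[rbind(c("SMA", "PMC"), c("M1", "PMC"), c("M1", "SMA"),
              c("PMC", "DLPFC"), c("SMA", "DLPFC"))] <- 1
    B <- bm * ifelse(fwd == 1, b_forward, b_backward)
  }
  if (is.null(C)) C <- c_mask_input(input_region) * c_gain
  A <- as.matrix(A); B <- as.matrix(B); C <- as.numeric(C)
  dimnames(A) <- dimnames(B) <- list(nodes, nodes)
  names(C) <- nodes
  validate_network(A, B, C, input_region)
  structure(list(nodes = nodes, A = A, B = B, C = C,
                 input_region = input_region, structure = structure),
            class = "motor_network")
}

validate_network <- function(A, B, C, input_region) {
  if (A["M1", "DLPFC"] != 0 || A["DLPFC", "M1"] != 0 ||
      B["M1", "DLPFC"] != 0 || B["DLPFC", "M1"] != 0)
    stop_config("DLPFC<->M1 entries of A and B must be exactly 0")
  if (any(diag(A) >= 0))
    stop_config("diagonal of A must be strictly negative")
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop_config("A must be stable (all eigenvalue real parts < 0)")
  nz <- which(C != 0)
  if (length(nz) != 1L || roi_nodes()[nz] != input_region)
    stop_config("C must be nonzero only at the input region")
  invisible(TRUE)
}

#' Integrate bilinear network dynamics
#'
#' Solves `dx/dt = (A + u_mod(t) B) x + C u_drive(t)` from `x(0) = 0` on a
#' uniform grid; inputs are held constant within each step. Column `k` of
#' the result is the state at time `k * dt`. The same compiled integrator
#' backs DCM model inversion, so generator and estimator agree bit-for-bit
#' on identical parameters.
#'
#' @param net A [motor_network()] (or any list with `A`, `B`, `C`).
#' @param u_drive Driving-input series.
#' @param u_mod Modulatory-input series, same length (recycled scalar 0/1
#'   allowed).
#' @param dt Step size in seconds.
#' @param method `"rk4"` (default; matches constant-input closed forms to
#'   ~1e-10) or `"euler"` (first order; kept for convergence diagnostics).
#' @return 4 x n matrix of source states, rows named by node.
#' @export
simulate_network_dynamics <- function(net, u_drive, u_mod = 0, dt,
                                      method = c("rk4", "euler")) {
  method <- match.arg(method)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop_config("dt must be a positive scalar")
  n <- length(u_drive)
  if (length(u_mod) == 1L) u_mod <- rep(u_mod, n)
  if (length(u_mod) != n)
    stop_input("u_drive and u_mod must be sampled on the same grid")
  ev <- eigen(net$A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop(errorCondition("unstable A: eigenvalue with non-negative real part",
                        class = c("eegdcm_stability_error", "error")))
  out <- .integrate_bilinear_c(net$A, net$B, net$C, as.numeric(u_drive),
                               as.numeric(u_mod), dt,
                               if (method == "euler") 0L else 1L)
  rownames(out) <- rownames(net$A)
  out
}

#' Build driving/modulatory input regressors from a paradigm
#'
#' The driving input is a brief boxcar (default 0.2 s) at every dot onset,
#' entering the network through `C`; the modulatory input is 1 while each
#' trial is performed (dot onset to onset + dot duration) and 0 elsewhere.
#'
#' @param paradigm A [simulate_paradigm()] object.
#' @param fs Sampling rate of the regressors, Hz.
#' @param duration Total duration, seconds; default [paradigm_duration()].
#' @param drive_duration Driving boxcar length, seconds.
#' @return List with `u_drive`, `u_mod` (length `round(duration * fs)`),
#'   `fs`, and `n`.
#' @export
paradigm_inputs <- function(paradigm, fs, duration = paradigm_duration(paradigm),
                            drive_duration = 0.2) {
  n <- round(duration * fs)
  u_drive <- numeric(n)
  u_mod <- numeric(n)
  ev <- paradigm_events(paradigm)
  dots <- ev[ev$trial_type == "dot", , drop = FALSE]
  dot_dur <- paradigm$timing$dot_duration
  for (i in seq_len(nrow(dots))) {
    on <- dots$onset[i]
    i0 <- floor(on * fs) + 1L
    u_drive[i0:min(n, i0 + round(drive_duration * fs) - 1L)] <- 1
    u_mod[i0:min(n, i0 + round(dot_dur * fs) - 1L)] <- 1
  }
  list(u_drive = u_drive, u_mod = u_mod, fs = fs, n = n)
}

#' @export
print.motor_network <- function(x, ...) {
  cat(sprintf("<motor_network> input: %s, structure %d, %d modulated edges\n",
              x$input_region, x$structure %||% NA, sum(x$B != 0)))
  invisible(x)
}
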