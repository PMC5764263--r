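#' Tikhonov minimum-norm inverse
#'
#' Regularized linear source estimate
#' `s_hat = G' (G G' + lambda I)^-1 y` applied column-wise to channel data.
#' This is the desk-scale stand-in for template-head-model source
#' inversion: the downstream connectivity analysis needs only ROI time
#' series, not anatomically precise maps.
#'
#' @param data n_channels x n_samples matrix (uV).
#' @param leadfield A [simulate_leadfield()] object (or list with `gain`).
#' @param lambda Regularization (>= 0). `"auto"` picks
#'   `0.01 * mean(diag(G G'))`, a discrepancy-principle-style default.
#' @return n_sources x n_samples matrix of source estimates.
#' @export
minimum_norm_inverse <- function(data, leadfield, lambda = "auto") {
  G <- leadfield$gain
  data <- as.matrix(data)
  if (nrow(data) != nrow(G))
    stop_input("data has ", nrow(data), " channels but lead field has ",
               nrow(G))
  GGt <- G %*% t(G)
  if (identical(lambda, "auto")) lambda <- 0.01 * mean(diag(GGt))
  if (!is.numeric(lambda) || lambda < 0) stop_config("lambda must be >= 0")
  M <- GGt + lambda * diag(nrow(G))
  ok <- tryCatch({ ch <- chol(M); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop(errorCondition(
      "G G' + lambda I is numerically singular (rank-deficient G at lambda = 0)",
      class = c("eegdcm_rank_error", "error")))
  out <- t(G) %*% chol2inv(ch) %*% data
  rownames(out) <- colnames(G)
  out
}

#' Extract ROI time series from source estimates
#'
#' For each ROI, takes the first principal component of all sources within
#' `radius_mm` of the ROI center, sign-aligned so its inner product with
#' the ROI-mean source series is positive (deterministic sign convention
#' resolving the PCA ambiguity).
#'
#' @param source_est n_sources x n_samples matrix from
#'   [minimum_norm_inverse()].
#' @param leadfield Lead field carrying `source_positions`.
#' @param roiset A [default_roiset()].
#' @return Object of class `"roi_timeseries"`: `data` (4 x n_samples,
#'   arbitrary source units, rows named PMC/SMA/M1/DLPFC) and `members`
#'   (source labels per ROI).
#' @export
extract_roi_timeseries <- function(source_est, leadfield, roiset) {
  pos <- leadfield$source_positions
  out <- matrix(NA_real_, 4, ncol(source_est),
                dimnames = list(roiset$labels, NULL))
  members <- list()
  for (r in roiset$labels) {
    d <- sqrt(rowSums(sweep(pos, 2, roiset$centers[r, ])^2))
    inside <- which(d <= roiset$radius_mm)
    if (length(inside) == 0L)
      stop(errorCondition(paste0("no sources within ", roiset$radius_mm,
                                 " mm of ROI ", r),
                          class = c("eegdcm_coverage_error", "error")))
    members[[r]] <- rownames(pos)[inside]
    seg <- source_est[inside, , drop = FALSE]
    if (length(inside) == 1L) {
      comp <- as.numeric(seg)
    } else {
      pc <- prcomp(t(seg), center = FALSE, scale. = FALSE)
      comp <- pc$x[, 1]
    }
    m <- colMeans(seg)
    if (sum(comp * m) < 0) comp <- -comp
    out[r, ] <- comp
  }
  structure(list(data = out, members = members), class = "roi_timeseries")
}

#' ROI series for every epoch
#'
#' Convenience wrapper: inverts each epoch and extracts ROI components,
#' returning an array aligned with the epochs object.
#'
#' @param epochs An `"eeg_epochs"` object.
#' @param leadfield,roiset As in [extract_roi_timeseries()].
#' @param lambda Passed to [minimum_norm_inverse()].
#' @return n_epochs x 4 x n_samples array (ROI order PMC, SMA, M1, DLPFC).
#' @export
epochs_to_roi <- function(epochs, leadfield, roiset = default_roiset(),
                          lambda = "auto") {
  n_ep <- dim(epochs$data)[1]
  n_samp <- dim(epochs$data)[3]
  out <- array(NA_real_, c(n_ep, 4, n_samp),
               dimnames = list(NULL, roiset$labels, NULL))
  for (i in seq_len(n_ep)) {
    y <- matrix(epochs$data[i, , ], nrow = dim(epochs$data)[2])
    s <- minimum_norm_inverse(y, leadfield, lambda)
    out[i, , ] <- extract_roi_timeseries(s, leadfield, roiset)$data
  }
  out
}
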