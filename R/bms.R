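#' Build the 16-model space
#'
#' Two input families (PMC, models 1-8; SMA, models 9-16) times eight
#' modulatory structures per family (see [b_mask_structure()]). All models
#' share the intrinsic mask; DLPFC<->M1 connections are absent everywhere.
#'
#' @param structures Optional list of 8 explicit binary B masks per family
#'   (`list(PMC = list(...), SMA = list(...))`) replacing the default
#'   toggle enumeration.
#' @return Object of class `"model_space"`: `models` (list of 16
#'   [dcm_spec()]), `family_of` (character vector `"PMC_input"` /
#'   `"SMA_input"`), `model_index` 1..16.
#' @export
build_model_space <- function(structures = NULL) {
  models <- list()
  family_of <- character(16)
  for (fam_i in 1:2) {
    region <- c("PMC", "SMA")[fam_i]
    for (s in 1:8) {
      idx <- (fam_i - 1L) * 8L + s
      bm <- if (!is.null(structures)) structures[[region]][[s]] else NULL
      models[[idx]] <- dcm_spec(input_region = region, structure = s,
                                b_mask = bm)
      family_of[idx] <- paste0(region, "_input")
    }
  }
  structure(list(models = models, family_of = family_of,
                 model_index = seq_len(16L)), class = "model_space")
}

#' Family partition with uniform family-level priors
#'
#' Families partition the space into K disjoint subsets of sizes `N_k`;
#' the family prior is uniform, `p(f_k) = 1/K`, and each member model gets
#' `p(m) = 1/(K N_k)`, so model priors sum to the family prior and to one
#' overall.
#'
#' @param space A [build_model_space()] space (or any object with a
#'   `family_of` character vector).
#' @return Object of class `"family_partition"`: `families` (named list of
#'   model indices), `K`, `N_k`, `family_prior`, `model_prior`.
#' @export
family_partition <- function(space) {
  fam <- space$family_of
  families <- split(seq_along(fam), fam)
  K <- length(families)
  N_k <- vapply(families, length, integer(1))
  model_prior <- numeric(length(fam))
  for (k in seq_len(K)) model_prior[families[[k]]] <- 1 / (K * N_k[k])
  structure(list(families = families, K = K, N_k = N_k,
                 family_prior = setNames(rep(1 / K, K), names(families)),
                 model_prior = model_prior), class = "family_partition")
}

#' Fixed-effects pooling of model evidence
#'
#' Column sums of the subjects-by-models free-energy table: under fixed
#' effects the group log evidence of a model is the sum of its per-subject
#' log evidences.
#'
#' @param evidence n_subjects x n_models numeric matrix (nats).
#' @return Numeric vector of summed log evidences, one per model.
#' @export
ffx_pool <- function(evidence) {
  evidence <- as.matrix(evidence)
  if (nrow(evidence) < 1L) stop_input("evidence table has no subjects")
  if (any(!is.finite(evidence))) stop_input("evidence table must be finite")
  colSums(evidence)
}

#' Posterior model probabilities from summed log evidence
#'
#' `p(m | Y) ∝ exp(F_m) p(m)`, normalized with log-sum-exp
#' stabilization (summed evidences over a cohort overflow naive
#' exponentiation).
#'
#' @param summed_F Vector of summed log evidences.
#' @param partition A [family_partition()] (supplies the model priors);
#'   `NULL` for a uniform prior.
#' @return Probability vector summing to 1.
#' @export
model_posteriors <- function(summed_F, partition = NULL) {
  prior <- if (is.null(partition)) rep(1 / length(summed_F), length(summed_F))
           else partition$model_prior
  if (length(prior) != length(summed_F))
    stop_input("prior/evidence length mismatch")
  lp <- summed_F + log(prior)
  if (all(!is.finite(lp))) stop_input("degenerate evidence: all -Inf")
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}

#' Family posteriors by subset summation
#'
#' `p(f_k | Y) = sum of p(m | Y) over members of f_k`; the dominant family
#' is the argmax.
#'
#' @param p_m Normalized model posterior vector.
#' @param partition A [family_partition()].
#' @return List with `family_posterior` (named), `dominant`.
#' @export
family_posteriors <- function(p_m, partition) {
  if (abs(sum(p_m) - 1) > 1e-8)
    stop_input("model posteriors must be normalized (sum to 1)")
  fp <- vapply(partition$families, function(ix) sum(p_m[ix]), numeric(1))
  list(family_posterior = fp, dominant = names(fp)[which.max(fp)])
}

#' Select the best model within the dominant family
#'
#' Recomputes fixed-effects posteriors over the dominant family's models
#' only (uniform 1/N_k prior within the family) and returns the argmax,
#' ties broken deterministically toward the lowest model index.
#'
#' @param space A [build_model_space()] space.
#' @param summed_F Summed log evidences over all models.
#' @param dominant_family Family name (e.g. `"SMA_input"`).
#' @return List with `best_model` (index into the full space),
#'   `within_posterior` (named by model index).
#' @export
restrict_and_select <- function(space, summed_F, dominant_family) {
  part <- family_partition(space)
  ix <- part$families[[dominant_family]]
  if (is.null(ix)) stop_input("unknown family: ", dominant_family)
  lp <- summed_F[ix] - logsumexp(summed_F[ix])
  p <- exp(lp)
  p <- p / sum(p)
  best <- ix[which.max(p)] # which.max takes the first maximum: lowest index
  list(best_model = best, within_posterior = setNames(p, ix))
}

#' Bayesian model averaging of modulatory couplings
#'
#' Entry-wise posterior-probability-weighted mean of posterior-mean B
#' matrices across the models of one family; edges absent from a model
#' contribute zero.
#'
#' @param b_list List of 4 x 4 posterior-mean B matrices (one per model).
#' @param weights Posterior probabilities, same length, summing to 1.
#' @return 4 x 4 averaged B matrix (row = target, column = source).
#' @export
bma_couplings <- function(b_list, weights) {
  if (length(b_list) != length(weights))
    stop_input("one weight per model required")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_input("weights must sum to 1")
  out <- matrix(0, 4, 4, dimnames = dimnames(b_list[[1]]))
  for (i in seq_along(b_list)) out <- out + weights[i] * b_list[[i]]
  out
}

#' Full fixed-effects family-level BMS
#'
#' Pools evidence, forms model and family posteriors under the uniform
#' family prior, selects the best model within the dominant family, and
#' (when per-model fits are supplied) Bayes-model-averages the modulatory
#' couplings within that family.
#'
#' @param space A [build_model_space()] space.
#' @param evidence n_subjects x 16 free-energy matrix.
#' @param b_by_model Optional list of 16 posterior-mean B matrices (cohort
#'   level) for the BMA step.
#' @return Object of class `"bms_result"`: `summed_F`, `p_model`,
#'   `p_family`, `dominant_family`, `best_model`, `within_posterior`,
#'   `bma_B` (or NULL).
#' @export
run_bms <- function(space, evidence, b_by_model = NULL) {
  part <- family_partition(space)
  sF <- ffx_pool(evidence)
  p_m <- model_posteriors(sF, part)
  fam <- family_posteriors(p_m, part)
  sel <- restrict_and_select(space, sF, fam$dominant)
  bma <- NULL
  if (!is.null(b_by_model)) {
    ix <- part$families[[fam$dominant]]
    bma <- bma_couplings(b_by_model[ix], as.numeric(sel$within_posterior))
  }
  structure(list(summed_F = sF, p_model = p_m,
                 p_family = fam$family_posterior,
                 dominant_family = fam$dominant,
                 best_model = sel$best_model,
                 within_posterior = sel$within_posterior, bma_B = bma),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> dominant family %s (p = %.3f), best model %d\n",
              x$dominant_family, max(x$p_family), x$best_model))
  invisible(x)
}
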