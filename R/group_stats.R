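#' One-way ANOVA over coupling edges
#'
#' Groups are the directed edges of the selected model, observations the
#' per-subject coupling values. Degenerate convention: when both between-
#' and within-group variability are zero the test is uninformative and
#' `p = 1` is returned (documented, not an error); a zero within-group
#' variance with nonzero separation yields `p = 0`.
#'
#' @param coupling_table n_subjects x n_edges numeric matrix (columns
#'   named by edge).
#' @return List with `F_statistic`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(coupling_table) {
  X <- as.matrix(coupling_table)
  if (ncol(X) < 2L)
    stop(errorCondition("ANOVA needs at least two edge groups",
                        class = c("eegdcm_design_error", "error")))
  if (nrow(X) < 2L)
    stop(errorCondition("ANOVA needs at least two subjects",
                        class = c("eegdcm_design_error", "error")))
  n <- nrow(X); k <- ncol(X)
  grand <- mean(X)
  ss_between <- n * sum((colMeans(X) - grand)^2)
  ss_within <- sum(sweep(X, 2, colMeans(X))^2)
  df_b <- k - 1L
  df_w <- k * (n - 1L)
  if (ss_within == 0 && ss_between == 0)
    return(list(F_statistic = 0, df_between = df_b, df_within = df_w, p = 1))
  if (ss_within == 0)
    return(list(F_statistic = Inf, df_between = df_b, df_within = df_w,
                p = 0))
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  list(F_statistic = Fstat, df_between = df_b, df_within = df_w,
       p = pf(Fstat, df_b, df_w, lower.tail = FALSE))
}

#' Paired two-sided t-test on one coupling edge
#'
#' Per-subject differences between two condition/response streams; both
#' streams must contain the edge (models selected in different streams can
#' have different parameter sets, in which case non-shared edges are
#' excluded from comparison).
#'
#' @param stream_a,stream_b n_subjects x n_edges matrices with identical
#'   subject order.
#' @param edge Column name to test.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(stream_a, stream_b, edge) {
  missing_in <- c(if (!edge %in% colnames(stream_a)) "first",
                  if (!edge %in% colnames(stream_b)) "second")
  if (length(missing_in))
    stop(errorCondition(
      paste0("edge '", edge, "' missing from the ", paste(missing_in,
             collapse = " and "), " stream; excluded from comparison"),
      class = c("eegdcm_excluded_edge_error", "error")))
  if (nrow(stream_a) != nrow(stream_b))
    stop_input("streams must cover the same subjects")
  d <- stream_a[, edge] - stream_b[, edge]
  n <- length(d)
  df <- n - 1L
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = df, p = .Machine$double.xmin))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Rejects all hypotheses with sorted p-value rank `i <= max{i : p(i) <=
#' i q / m}`; the rejected set is always a prefix of the sorted p-values.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param q Target false discovery rate in (0, 1).
#' @return Logical vector of rejection flags in the input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (m == 0L) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = FALSE) || anyNA(p_values))
    stop_input("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop_config("q must be in (0, 1)")
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ok)) reject[ord[seq_len(max(ok))]] <- TRUE
  reject
}

#' Edge-wise group comparison of two coupling tables
#'
#' Paired t-tests on every edge shared by both streams, BH-corrected at
#' level `q`; a Table-2-style report (mean, SD per stream, t, raw p,
#' significance flag).
#'
#' @param stream_a,stream_b n_subjects x n_edges matrices.
#' @param q FDR level.
#' @return Data frame with one row per shared edge.
#' @export
compare_streams <- function(stream_a, stream_b, q = 0.05) {
  shared <- intersect(colnames(stream_a), colnames(stream_b))
  if (length(shared) == 0L) stop_input("streams share no edges")
  rows <- lapply(shared, function(e) {
    tt <- paired_ttest(stream_a, stream_b, e)
    data.frame(edge = e,
               mean_a = mean(stream_a[, e]), sd_a = sd(stream_a[, e]),
               mean_b = mean(stream_b[, e]), sd_b = sd(stream_b[, e]),
               t = tt$t, df = tt$df, p_raw = tt$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p_raw, q)
  out
}

#' Per-subject coupling table from DCM fits
#'
#' Stacks the posterior-mean B entries of one model's fits into a
#' subjects x edges matrix, columns named `target<-source` over the
#' model's modulated edges.
#'
#' @param fits List of `"dcm_fit"` objects (one per subject, same spec).
#' @return n_subjects x n_edges matrix.
#' @export
coupling_table <- function(fits) {
  spec <- fits[[1]]$spec
  edges <- names(spec$prior_mean)[spec$n_a + seq_len(spec$n_b)]
  edges <- sub("^B_", "", edges)
  tab <- t(vapply(fits, function(f) f$B[f$spec$b_idx],
                  numeric(spec$n_b)))
  colnames(tab) <- edges
  tab
}
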