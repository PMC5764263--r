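test_that("one-way ANOVA matches the sum-of-squares decomposition", {
  set.seed(121)
  X <- matrix(rnorm(20 * 5, mean = rep(c(0, 0.2, 0, -0.1, 0.3), each = 20)),
              20)
  colnames(X) <- paste0("e", 1:5)
  res <- one_way_anova(X)
  # independent oracle: stats::lm / anova
  df <- data.frame(y = as.numeric(X),
                   g = factor(rep(colnames(X), each = nrow(X))))
  or <- anova(lm(y ~ g, df))
  expect_equal(res$F_statistic, or$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, or$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(res$df_between, or$Df[1])
  expect_equal(res$df_within, or$Df[2])
})

test_that("ANOVA degenerate conventions are honored", {
  const <- matrix(2, 6, 3)
  expect_equal(one_way_anova(const)$p, 1)
  sep <- cbind(rep(0, 3), rep(1, 3)) + rnorm(6, sd = 1e-6)
  expect_lt(one_way_anova(sep)$p, 1e-6)
  expect_error(one_way_anova(matrix(1, 5, 1)), class = "eegdcm_design_error")
})

test_that("paired t-test matches stats::t.test and handles edge cases", {
  set.seed(122)
  a <- matrix(rnorm(15 * 2), 15, dimnames = list(NULL, c("x", "y")))
  b <- matrix(rnorm(15 * 2), 15, dimnames = list(NULL, c("x", "y")))
  res <- paired_ttest(a, b, "x")
  or <- t.test(a[, "x"], b[, "x"], paired = TRUE)
  expect_equal(res$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(res$p, or$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(or$parameter))
  same <- paired_ttest(a, a, "x")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # dyadic values so the +1 shift is exact and the difference sd is 0
  a[, "x"] <- round(a[, "x"] * 8) / 8
  shifted <- a
  shifted[, "x"] <- a[, "x"] + 1
  res_inf <- paired_ttest(shifted, a, "x")
  expect_equal(res_inf$t, Inf)
  expect_lte(res_inf$p, .Machine$double.xmin)
  colnames(b) <- c("x", "z")
  expect_error(paired_ttest(a, b, "y"),
               class = "eegdcm_excluded_edge_error", regexp = "'y'")
})

test_that("paired t-test holds its nominal type-I error", {
  set.seed(123)
  rej <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    d <- rnorm(20)
    t <- mean(d) / (sd(d) / sqrt(20))
    rej <- rej + (2 * pt(-abs(t), 19) < 0.05)
  }
  # same computation through the package API on a subsample (cheap check
  # that the implementation is the formula used above)
  a <- matrix(rnorm(20), 20, dimnames = list(NULL, "e"))
  b <- matrix(rnorm(20), 20, dimnames = list(NULL, "e"))
  expect_equal(paired_ttest(a, b, "e")$t,
               mean(a - b) / (sd(a - b) / sqrt(20)), tolerance = 1e-12)
  expect_gte(rej / n_rep, 0.035)
  expect_lte(rej / n_rep, 0.065)
})

test_that("BH follows the step-up rule and equals p.adjust", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04, 0.5), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_equal(fdr_bh(rep(0, 6), 0.05), rep(TRUE, 6))
  expect_equal(fdr_bh(numeric(0), 0.05), logical(0))
  set.seed(124)
  for (r in 1:50) {
    p <- runif(12)^2
    expect_equal(fdr_bh(p, 0.05), p.adjust(p, "BH") <= 0.05)
  }
  expect_error(fdr_bh(c(0.5, 1.2), 0.05), class = "eegdcm_input_error")
})

test_that("BH rejections grow monotonically as p-values shrink", {
  set.seed(125)
  for (r in 1:25) {
    p <- runif(10)
    base <- fdr_bh(p, 0.05)
    p2 <- p
    i <- sample(10, 1)
    p2[i] <- p2[i] * runif(1)
    expect_true(all(which(base) %in% which(fdr_bh(p2, 0.05))))
  }
})

test_that("compare_streams reports shared edges with FDR flags", {
  set.seed(126)
  a <- matrix(rnorm(20 * 3), 20,
              dimnames = list(NULL, c("e1", "e2", "e3")))
  b <- matrix(rnorm(20 * 3), 20,
              dimnames = list(NULL, c("e2", "e3", "e4")))
  b[, "e2"] <- b[, "e2"] + 2
  out <- compare_streams(a, b, q = 0.05)
  expect_setequal(out$edge, c("e2", "e3"))
  expect_true(out$significant[out$edge == "e2"])
  expect_false(out$significant[out$edge == "e3"])
})
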