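test_that("the model space has 16 models, 8 per family, structurally valid", {
  space <- build_model_space()
  expect_length(space$models, 16)
  expect_equal(space$family_of[1:8], rep("PMC_input", 8))
  expect_equal(space$family_of[9:16], rep("SMA_input", 8))
  for (m in space$models) {
    expect_equal(m$b_mask["M1", "DLPFC"], 0L)
    expect_equal(m$b_mask["DLPFC", "M1"], 0L)
    expect_equal(m$a_mask, a_mask_default())
  }
  # model 10 is "model 2 with the SMA input"
  expect_equal(space$models[[10]]$structure, 2)
  expect_equal(space$models[[10]]$input_region, "SMA")
  expect_equal(space$models[[2]]$b_mask, b_mask_structure(2, "PMC"))
  # all 8 structures distinct within a family
  masks <- lapply(space$models[1:8], `[[`, "b_mask")
  expect_equal(length(unique(lapply(masks, paste, collapse = ""))), 8L)
})

test_that("family partition carries the uniform priors exactly", {
  space <- build_model_space()
  part <- family_partition(space)
  expect_equal(part$K, 2L)
  expect_equal(unname(part$N_k), c(8L, 8L))
  expect_equal(unname(part$family_prior), c(0.5, 0.5))
  expect_equal(part$model_prior, rep(1 / 16, 16))
  # family prior equals the sum of member model priors, for any partition
  for (k in seq_len(part$K))
    expect_equal(sum(part$model_prior[part$families[[k]]]),
                 unname(part$family_prior[k]), tolerance = 1e-15)
})

test_that("FFX pooling is exact column summation", {
  expect_equal(ffx_pool(rbind(1, 2)), 3)
  one <- matrix(rnorm(16), 1)
  expect_equal(ffx_pool(one), as.numeric(one))
  set.seed(111)
  E <- matrix(rnorm(20 * 16, mean = -500, sd = 30), 20)
  brute <- vapply(seq_len(16), function(j) sum(E[, j]), numeric(1))
  expect_equal(ffx_pool(E), brute, tolerance = 1e-12)
  expect_error(ffx_pool(E[0, , drop = FALSE]), class = "eegdcm_input_error")
})

test_that("model posteriors follow the stabilized softmax", {
  space <- build_model_space()
  part <- family_partition(space)
  # equal evidence -> uniform 1/16
  expect_equal(model_posteriors(rep(-1000, 16), part), rep(0.0625, 16))
  # two models, evidence gap ln 3, equal priors -> 0.75 / 0.25
  p2 <- model_posteriors(c(log(3), 0), NULL)
  expect_equal(p2, c(0.75, 0.25), tolerance = 1e-12)
  # huge summed evidences do not overflow
  set.seed(112)
  sF <- rnorm(16, mean = -20000, sd = 10)
  p <- model_posteriors(sF, part)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # brute force via pairwise ratios (independent of log-sum-exp)
  brute <- 1 / vapply(seq_len(16),
                      function(i) sum(exp(sF - sF[i])), numeric(1))
  expect_equal(p, brute / sum(brute), tolerance = 1e-12)
})

test_that("family posteriors are subset sums with a dominant family", {
  space <- build_model_space()
  part <- family_partition(space)
  u <- rep(1 / 16, 16)
  fp <- family_posteriors(u, part)
  expect_equal(unname(fp$family_posterior), c(0.5, 0.5))
  all10 <- replace(rep(0, 16), 10, 1)
  fp10 <- family_posteriors(all10, part)
  expect_equal(unname(fp10$family_posterior["SMA_input"]), 1)
  expect_equal(fp10$dominant, "SMA_input")
  set.seed(113)
  p <- runif(16); p <- p / sum(p)
  fpr <- family_posteriors(p, part)
  expect_equal(unname(fpr$family_posterior["PMC_input"]), sum(p[1:8]),
               tolerance = 1e-12)
  expect_error(family_posteriors(p * 2, part), class = "eegdcm_input_error")
})

test_that("within-family selection is an argmax with lowest-index ties", {
  space <- build_model_space()
  sF <- rep(-100, 16)
  sF[2] <- -50
  expect_equal(restrict_and_select(space, sF, "PMC_input")$best_model, 2L)
  expect_equal(restrict_and_select(space, rep(-100, 16),
                                   "SMA_input")$best_model, 9L) # tie-break
  set.seed(114)
  sFr <- rnorm(16, -300, 5)
  sel <- restrict_and_select(space, sFr, "SMA_input")
  expect_equal(sel$best_model, (9:16)[which.max(sFr[9:16])])
  expect_equal(sum(sel$within_posterior), 1, tolerance = 1e-12)
})

test_that("BMA averages couplings with posterior weights", {
  b1 <- matrix(0.2, 4, 4, dimnames = list(roi_nodes(), roi_nodes()))
  b2 <- matrix(0.4, 4, 4, dimnames = list(roi_nodes(), roi_nodes()))
  expect_equal(bma_couplings(list(b1, b2), c(1, 0)), b1)
  expect_equal(bma_couplings(list(b1, b2), c(0.5, 0.5))[1, 2], 0.3)
  set.seed(115)
  bl <- replicate(8, matrix(rnorm(16), 4,
                            dimnames = list(roi_nodes(), roi_nodes())),
                  simplify = FALSE)
  w <- runif(8); w <- w / sum(w)
  brute <- Reduce(`+`, Map(function(b, wi) b * wi, bl, w))
  expect_equal(bma_couplings(bl, w), brute, tolerance = 1e-12)
  expect_error(bma_couplings(bl, w[1:3]), class = "eegdcm_input_error")
})
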