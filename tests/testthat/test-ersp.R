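# Helper: epochs with a given per-channel signal generator.
ersp_epochs <- function(n_ep, n, fs, gen, labels = c("C3", "C4")) {
  arr <- array(0, c(n_ep, length(labels), n))
  for (e in seq_len(n_ep)) for (ch in seq_along(labels))
    arr[e, ch, ] <- gen(e, ch)
  make_epochs(arr, fs, tmin = -1, labels = labels)
}

test_that("stationary noise gives a flat 0 dB map on average", {
  fs <- 256
  n <- 5 * fs
  set.seed(71)
  ep <- ersp_epochs(200, n, fs, function(e, ch) rnorm(n))
  em <- compute_ersp(ep, freqs = 4:30)
  interior <- em$times > -0.5 & em$times < 3.5
  # per channel x frequency time-average over the analysis bands,
  # excluding wavelet edge effects (see vignette for the Monte-Carlo
  # floor of pointwise values)
  inband <- em$freqs >= 8 & em$freqs <= 20
  cf_means <- apply(em$values[, inband, interior], c(1, 2), mean)
  expect_lt(max(abs(cf_means)), 0.5)
  for (b in c("mu", "beta")) for (w in trial_windows())
    expect_lt(max(abs(band_average(em, b, w))), 0.5)
})

test_that("amplitude halving at onset gives the closed-form -6.02 dB", {
  fs <- 256
  n <- 5 * fs
  tt <- seq(-1, 4 - 1 / fs, by = 1 / fs)
  set.seed(72)
  ep <- ersp_epochs(40, n, fs, function(e, ch) {
    ifelse(tt < 0, 1, 0.5) * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi))
  }, labels = c("C3", "C4"))
  em <- compute_ersp(ep)
  v <- band_average(em, "mu", c(0.5, 3.5))
  expect_equal(unname(v["C3"]), 10 * log10(0.25), tolerance = 0.3 / 6.02)
  # power identically equal to baseline -> 0 dB (no amplitude change)
  ep0 <- ersp_epochs(5, n, fs, function(e, ch) sin(2 * pi * 10 * tt))
  em0 <- compute_ersp(ep0)
  expect_lt(abs(band_average(em0, "mu", c(0.5, 3.5))[["C3"]]), 0.05)
})

test_that("ERSP is invariant to global amplitude scaling", {
  fs <- 128
  n <- 5 * fs
  set.seed(73)
  ep <- ersp_epochs(10, n, fs, function(e, ch) rnorm(n))
  ep_scaled <- ep
  ep_scaled$data <- ep$data * 3.7
  e1 <- compute_ersp(ep, freqs = c(10, 20))
  e2 <- compute_ersp(ep_scaled, freqs = c(10, 20))
  expect_equal(e1$values, e2$values, tolerance = 1e-9)
})

test_that("band averages match a brute-force mean and validate selections", {
  fs <- 128
  n <- 5 * fs
  set.seed(74)
  ep <- ersp_epochs(4, n, fs, function(e, ch) rnorm(n))
  em <- compute_ersp(ep, freqs = 4:30)
  fi <- which(em$freqs >= 8 & em$freqs <= 12)
  ti <- which(em$times >= 0 & em$times < 0.8)
  manual <- mean(em$values[1, fi, ti])
  expect_equal(band_average(em, "mu", c(0, 0.8))[["C3"]], manual,
               tolerance = 1e-12)
  # constant map returns the constant; disjoint bands stay disjoint
  em2 <- em
  em2$values[] <- 0
  em2$values[, em2$freqs >= 8 & em2$freqs <= 12, ] <- 1
  em2$values[, em2$freqs >= 13 & em2$freqs <= 20, ] <- -1
  expect_equal(unname(band_average(em2, "mu", c(0, 1))), c(1, 1))
  expect_equal(unname(band_average(em2, "beta", c(0, 1))), c(-1, -1))
  expect_error(band_average(em, c(8, 12), c(90, 91)),
               class = "eegdcm_config_error")
  expect_error(erd_index(em, "XX"), class = "eegdcm_input_error")
})

test_that("mu suppression at M1 produces contralateral ERD at C3", {
  sim <- simulate_session("ME", n_blocks = 12, fs = 512, seed = 75,
                          osc_components = list(list(
                            roi = "M1", freq = 10, bandwidth = 4,
                            amplitude = 0.4, suppression = 0.4)),
                          blink_rate = 0)
  ep <- preprocess_recording(sim$recording,
                             config = preproc_config(fs_target = 256))
  em <- compute_ersp(ep, channels = c("C3", "C4"))
  c3 <- erd_index(em, "C3", "mu", c(0, 3.4))
  c4 <- erd_index(em, "C4", "mu", c(0, 3.4))
  expect_lt(c3, 0)       # desynchronization present
  expect_lt(c3, c4)      # more negative contralaterally
})

test_that("graded per-trial suppression deepens beta ERD across trials", {
  sim <- simulate_session("ME", n_blocks = 12, fs = 512, seed = 76,
                          osc_components = list(list(
                            roi = "M1", freq = 16, bandwidth = 4,
                            amplitude = 0.5,
                            suppression = c(0.9, 0.6, 0.3))),
                          blink_rate = 0)
  ep <- preprocess_recording(sim$recording,
                             config = preproc_config(fs_target = 256))
  em <- compute_ersp(ep, channels = "C3")
  w <- trial_windows()
  first <- erd_index(em, "C3", "beta", w[[1]])
  third <- erd_index(em, "C3", "beta", w[[3]])
  expect_lt(third, first) # 3rd-trial ERD more distinct than 1st
})
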