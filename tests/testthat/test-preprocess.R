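test_that("epoching obeys the half-open window convention", {
  fs <- 512
  n <- 30 * fs
  rec <- make_recording(matrix(rnorm(2 * n), 2), fs)
  ev <- data.frame(onset = c(5, 15), duration = 0.8, trial_type = "dot",
                   block_index = 1:2, trial_index = 1L)
  ep <- epoch_recording(rec, ev, c(-1, 4))
  expect_equal(dim(ep$data), c(2L, 2L, 2560L)) # 5.0 s x 512 Hz
  expect_equal(epoch_times(ep)[1], -1)
  expect_lt(max(epoch_times(ep)), 4) # half open: last sample < tmax
  # locked to the block's FIRST dot
  ev2 <- rbind(ev, data.frame(onset = c(6.3, 16.3), duration = 0.8,
                              trial_type = "dot", block_index = 1:2,
                              trial_index = 2L))
  ep2 <- epoch_recording(rec, ev2, c(-1, 4))
  expect_equal(ep2$data, ep$data)
  # event at sample 0 with tmin -1 exceeds bounds
  ev_bad <- data.frame(onset = 0, duration = 0.8, trial_type = "dot",
                       block_index = 1L, trial_index = 1L)
  expect_error(epoch_recording(rec, ev_bad, c(-1, 4)),
               class = "eegdcm_input_error", regexp = "block 1")
})

test_that("a 20-block paradigm yields 20 epochs end-to-end", {
  sim <- simulate_session("ME", n_blocks = 20, fs = 256, seed = 31,
                          osc_components = NULL, blink_rate = 0,
                          noise = list(pink_sd = 1, sensor_sd = 1))
  ep <- epoch_recording(sim$recording, window = c(-1, 4))
  expect_equal(dim(ep$data)[1], 20L)
})

test_that("amplitude rejection drops whole blocks, inclusively bounded, idempotent", {
  arr <- array(rnorm(4 * 3 * 100, sd = 5), c(4, 3, 100))
  ep <- make_epochs(arr, fs = 100)
  expect_equal(dim(reject_artifacts(ep, 100)$data)[1], 4L) # clean: none dropped
  arr2 <- arr
  arr2[2, 1, 50] <- 150 # one supra-threshold sample
  ep2 <- make_epochs(arr2, fs = 100)
  r2 <- reject_artifacts(ep2, 100)
  expect_equal(dim(r2$data)[1], 3L)
  expect_equal(r2$info$block_index, c(1L, 3L, 4L))
  expect_equal(r2$rejection_log$epoch, 2L)
  # boundary: exactly 100 uV is retained
  arr3 <- arr
  arr3[1, 1, 1] <- 100
  expect_equal(dim(reject_artifacts(make_epochs(arr3, 100), 100)$data)[1], 4L)
  # idempotence
  expect_equal(reject_artifacts(r2, 100)$data, r2$data)
})

test_that("blink template regression cancels injected blinks", {
  fs <- 256
  n <- 1280
  tmpl <- blink_template(fs)
  arr <- array(0, c(2, 4, n))
  wts <- c(1, 0.8, 0.3, 0) # last channel orthogonal to the blink
  at <- 301
  for (ch in 1:4) arr[1, ch, at:(at + length(tmpl) - 1)] <-
    80 * wts[ch] * tmpl
  ep <- make_epochs(arr, fs, labels = c("Fp1", "Fp2", "Cz", "Oz"))
  out <- remove_blinks(ep)
  expect_lt(max(abs(out$data[1, 1:3, ])), 0.8) # < 1 % of 80 uV
  expect_equal(out$data[1, 4, ], arr[1, 4, ], tolerance = 1e-9)
  expect_equal(out$data[2, , ], arr[2, , ], tolerance = 1e-9,
               ignore_attr = TRUE) # untouched epoch
  # nothing to regress: identity
  ep0 <- make_epochs(array(rnorm(2 * 4 * n, sd = 1), c(2, 4, n)), fs,
                     labels = c("Fp1", "Fp2", "Cz", "Oz"))
  expect_equal(remove_blinks(ep0)$data, ep0$data, tolerance = 1e-9)
})

test_that("bad-channel interpolation equals the inverse-distance weighted mean", {
  mon <- montage_1020_32()
  n <- 50
  arr <- array(rnorm(2 * 32 * n), c(2, 32, n))
  ep <- make_epochs(arr, 100, labels = mon$labels)
  expect_equal(interpolate_bad_channels(ep, character(), mon)$data, ep$data)
  # constant neighbors reproduce the constant
  arr_c <- array(7, c(1, 32, n))
  ep_c <- make_epochs(arr_c, 100, labels = mon$labels)
  out_c <- interpolate_bad_channels(ep_c, "C3", mon)
  expect_equal(unname(out_c$data[1, match("C3", mon$labels), ]), rep(7, n))
  # hand-computed weighted mean oracle
  out <- interpolate_bad_channels(ep, "Cz", mon, k = 4)
  good <- setdiff(mon$labels, "Cz")
  d <- sqrt(rowSums(sweep(mon$positions[good, ], 2, mon$positions["Cz", ])^2))
  nb <- good[order(d)][1:4]
  w <- (1 / sort(d)[1:4]); w <- w / sum(w)
  manual <- w %*% matrix(arr[1, match(nb, mon$labels), ], nrow = 4)
  expect_equal(unname(out$data[1, match("Cz", mon$labels), ]),
               as.numeric(manual), tolerance = 1e-9)
  expect_error(interpolate_bad_channels(ep, mon$labels, mon),
               class = "eegdcm_input_error")
})

test_that("flat channels are detected at the 0.2 uV peak-to-peak bound", {
  arr <- array(rnorm(2 * 3 * 100), c(2, 3, 100))
  arr[1, 2, ] <- 0.01 * sin(seq_len(100)) # p2p ~0.02 uV
  ep <- make_epochs(arr, 100)
  expect_equal(detect_flat_channels(ep, 0.2), "ch2")
})

test_that("the full preprocessing chain runs in the documented order", {
  sim <- simulate_session("MI", n_blocks = 6, fs = 512, seed = 33,
                          blink_rate = 0.15)
  ep <- preprocess_recording(sim$recording,
                             config = preproc_config(fs_target = 256))
  expect_equal(ep$fs, 256)
  expect_equal(dim(ep$data)[3], 1280L)
  expect_lte(dim(ep$data)[1], 6L)
  expect_true(all(abs(ep$data) <= 100))
})
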