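test_that("montage and lead field have the advertised geometry", {
  mon <- montage_1020_32()
  expect_length(mon$labels, 32)
  expect_true(all(c("C3", "C4", "Fp1", "Cz") %in% mon$labels))
  expect_equal(dim(mon$positions), c(32L, 3L))
  # C3 left (negative x), C4 right, symmetric
  expect_lt(mon$positions["C3", "x"], 0)
  expect_equal(mon$positions["C3", "x"], -mon$positions["C4", "x"])

  lf <- simulate_leadfield(seed = 1)
  expect_equal(dim(lf$gain), c(32L, 24L))
  expect_true(all(is.finite(lf$gain)))
  expect_true(all(rowSums(abs(lf$gain)) > 0))
  # left-hemisphere M1 source projects more strongly to C3 than C4
  expect_gt(lf$gain["C3", "M1"], lf$gain["C4", "M1"])
  expect_identical(lf$gain, simulate_leadfield(seed = 1)$gain)
})

test_that("scalp projection is exact under identity gain and zero noise", {
  src <- matrix(rnorm(5 * 200), 5)
  rec <- project_to_scalp(src, identity_leadfield(5), fs = 100,
                          noise = list(pink_sd = 0, sensor_sd = 0))
  expect_equal(unname(rec$data), src)
  expect_error(project_to_scalp(matrix(0, 3, 10), identity_leadfield(5), 100),
               class = "eegdcm_input_error")
  # default montage recording has 32 channels
  lf <- simulate_leadfield(seed = 2)
  rec32 <- project_to_scalp(matrix(0, 24, 50), lf, fs = 100)
  expect_equal(nrow(rec32$data), 32L)
})

test_that("white sensor noise variance scales as sd squared", {
  n <- 1.2e5
  lf <- identity_leadfield(1)
  v <- vapply(c(1, 2), function(s) {
    rec <- project_to_scalp(matrix(0, 1, n), lf, fs = 1000,
                            noise = list(pink_sd = 0, sensor_sd = s),
                            seed = 11)
    var(rec$data[1, ])
  }, numeric(1))
  expect_lt(abs(v[2] / v[1] - 4), 0.4) # 4x within 10 %
})

test_that("artifact injection is logged, reproducible and optional", {
  lf <- simulate_leadfield(seed = 3)
  rec <- project_to_scalp(matrix(0, 24, 4000), lf, fs = 200,
                          noise = list(pink_sd = 1, sensor_sd = 1), seed = 4)
  clean <- inject_artifacts(rec, blink_rate = 0, spikes = NULL)
  expect_identical(clean$data, rec$data) # bit-exact no-op
  art <- inject_artifacts(rec, blink_rate = 0.3, blink_amplitude_uv = 80,
                          seed = 5)
  expect_gt(length(art$artifact_log$blink_onsets), 0)
  expect_identical(art$data,
                   inject_artifacts(rec, blink_rate = 0.3,
                                    blink_amplitude_uv = 80, seed = 5)$data)
  # blinks are frontal-weighted: Fp1 perturbed more than Oz
  dif <- abs(art$data - rec$data)
  expect_gt(max(dif["Fp1", ]), max(dif["Oz", ]))
})

test_that("blink counts follow the Poisson rate", {
  lf <- identity_leadfield(1)
  lf$channel_labels <- "Fp1"
  rec <- project_to_scalp(matrix(0, 1, 400 * 100), lf, fs = 100,
                          noise = list(pink_sd = 0, sensor_sd = 0))
  art <- inject_artifacts(rec, blink_rate = 0.25, blink_amplitude_uv = 50,
                          seed = 21)
  n_blinks <- length(art$artifact_log$blink_onsets)
  expect_lt(abs(n_blinks - 100), 3 * sqrt(100))
})

test_that("EDF round trip preserves data to quantization accuracy", {
  set.seed(8)
  data <- matrix(rnorm(4 * 300, sd = 20), 4)
  rec <- make_recording(data, fs = 100, labels = c("C3", "C4", "Fp1", "Oz"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, 100)
  expect_equal(back$channel_labels, rec$channel_labels)
  tol <- max(abs(data)) / 32767 * 1.01
  expect_lt(max(abs(back$data[, seq_len(ncol(data))] - data)), tol)
})

test_that("events TSV round trip is faithful", {
  p <- simulate_paradigm("MI", n_blocks = 3, seed = 2)
  ev <- paradigm_events(p)
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path)
  expect_equal(back$onset, ev$onset, tolerance = 1e-9)
  expect_equal(back$trial_type, ev$trial_type)
  expect_equal(back$block_index, ev$block_index)
})
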