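test_that("subject sampling is seeded and spreads as specified", {
  gt <- ground_truth("C", subject_sd = 0.2)

  s1 <- sample_subject(gt, seed = 5)
  s2 <- sample_subject(gt, seed = 5)
  expect_identical(s1$model, s2$model)

  gt0 <- ground_truth("C", subject_sd = 0)
  s0 <- sample_subject(gt0, seed = 7)
  expect_identical(s0$model$forward, gt0$model$forward)
  expect_identical(s0$model$inputs$phasic$gains, gt0$model$inputs$phasic$gains)

  draws <- vapply(1:1000, function(i)
    log(sample_subject(gt, seed = i)$model$inputs$phasic$gains[["SIc"]]),
    numeric(1))
  expect_equal(sd(draws), 0.2, tolerance = 0.1)
  expect_equal(mean(draws), 0, tolerance = 0.05)   # centred on the group mean
})

test_that("continuous recordings have the stated timing structure", {
  gt <- ground_truth("C", n_channels = 8)
  gain <- test_gain(8)
  sp <- sample_subject(gt, seed = 3, n_trials = 154)
  rec <- synthesize_recording(sp, gain)
  expect_equal(length(rec$event_times), 154)
  isi <- diff(rec$event_times)
  expect_true(all(isi >= 2 & isi <= 3.8))
  dur <- ncol(rec$data) / rec$sample_rate
  expect_gt(dur, 154 * 2 - 2)                 # ~308 s lower bound
  expect_lt(dur, 154 * 3.8 + 3)               # ~586 s upper bound
  expect_equal(rec$sample_rate, 2000)
})

test_that("the noiseless limit reproduces the projected simulation", {
  gt <- ground_truth("C", snr = 1e7, n_channels = 8)
  gain <- test_gain(8)
  sp <- sample_subject(gt, seed = 9, n_trials = 5)
  rec <- synthesize_recording(sp, gain)
  ep <- downsample_epoch_baseline(rec)
  erf <- average_erf(ep)
  src <- simulate_sources(sp$model, erf$times)
  ref <- project_to_sensors(src, gain)
  ref <- ref - rowMeans(ref[, erf$times < 0])
  rel <- sqrt(mean((erf$data - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(rel, 0.02)   # anti-alias filtering leaves ~1% in-band ripple
})

test_that("the requested SNR is realized within 10%", {
  gt <- ground_truth("C", snr = 5)
  gain <- test_gain()
  sp <- sample_subject(gt, seed = 17)
  ep <- synthesize_epochs(sp, gain)
  erf <- average_erf(ep)
  measured <- sqrt(mean(erf$data[, erf$times >= 0]^2)) / attr(ep, "noise_sd")
  expect_equal(measured, 5, tolerance = 0.1)
})

test_that("epoch and recording paths agree on the evoked signal", {
  gt <- ground_truth("C", snr = 50, n_channels = 8)
  gain <- test_gain(8)
  sp <- sample_subject(gt, seed = 23, n_trials = 40)
  erf_fast <- average_erf(synthesize_epochs(sp, gain))
  erf_cont <- average_erf(downsample_epoch_baseline(
    synthesize_recording(sp, gain)))
  rel <- sqrt(mean((erf_fast$data - erf_cont$data)^2)) /
    sqrt(mean(erf_cont$data^2))
  expect_lt(rel, 0.1)                          # differ only in noise draws
})

test_that("group synthesis is reproducible and properly randomized", {
  gt <- ground_truth("C", n_channels = 12)
  g1 <- synthesize_group(gt, n_subjects = 3, seed = 8, n_trials = 10)
  g2 <- synthesize_group(gt, n_subjects = 3, seed = 8, n_trials = 10)
  g3 <- synthesize_group(gt, n_subjects = 3, seed = 9, n_trials = 10)
  expect_length(g1$data, 3)
  expect_identical(g1$data[[2]]$data, g2$data[[2]]$data)
  expect_false(identical(g1$data[[1]]$data, g3$data[[1]]$data))
  # same group-mean structure regardless of master seed
  expect_identical(g1$gt$model$forward, g3$gt$model$forward)
  # subjects differ from each other
  expect_false(identical(g1$subjects[[1]]$model$inputs$phasic$gains,
                         g1$subjects[[2]]$model$inputs$phasic$gains))
})

test_that("asymmetric input gains shape the group-mean model", {
  gt <- ground_truth("D", input_gains = c(SIc = 2, SIIc = 1))
  expect_equal(gt$model$inputs$phasic$gains[["SIc"]], 2)
  expect_equal(gt$model$inputs$phasic$gains[["SIIc"]], 1)
  expect_equal(gt$model$inputs$sustained$gains[["SIc"]], 2)
})
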