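test_that("band-pass preserves the passband and removes DC and HF", {
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  mid <- seq(2 * fs, 8 * fs)                   # avoid filter edge transients

  s10 <- sin(2 * pi * 10 * t)
  rec <- recording(rbind(s10, s10 + 5), fs)    # second channel carries DC 5
  out <- bandpass(rec)
  amp <- max(out$data[1, mid])
  expect_equal(amp, 1, tolerance = 0.01)
  expect_lt(abs(mean(out$data[2, mid])), 0.01) # DC gone

  s200 <- sin(2 * pi * 200 * t)
  out2 <- bandpass(recording(rbind(s200), fs))
  atten_db <- 20 * log10(max(out2$data[1, mid]))
  expect_lt(atten_db, -20)

  expect_error(bandpass(recording(rbind(s10), fs), lp = 1200), "Nyquist")
})

test_that("epoching yields 176 samples at 500 Hz over [-50, 300] ms", {
  fs <- 2000
  n_ev <- 20
  ev <- seq(1, by = 2.5, length.out = n_ev)
  dur <- ev[n_ev] + 1
  dat <- matrix(rnorm(2 * dur * fs), 2)
  rec <- recording(dat, fs, event_times = ev)
  ep <- downsample_epoch_baseline(rec)
  expect_equal(dim(ep$data), c(2, 176, n_ev))
  expect_equal(length(ep$times), 176)
  expect_equal(range(ep$times), c(-50, 300))
  expect_equal(ep$sample_rate, 500)
  # baseline mean is zero per channel and trial
  bl <- ep$times < 0
  expect_lt(max(abs(apply(ep$data[, bl, , drop = FALSE], c(1, 3), mean))),
            1e-10)
})

test_that("constant channels are nulled by baseline correction", {
  fs <- 2000
  rec <- recording(matrix(7, 1, 10 * fs), fs, event_times = c(2, 5))
  ep <- downsample_epoch_baseline(rec)
  expect_lt(max(abs(ep$data)), 1e-10)
})

test_that("edge events are dropped with a warning", {
  fs <- 2000
  rec <- recording(matrix(rnorm(fs * 6), 1), fs,
                   event_times = c(0.02, 3, 5.9))
  expect_warning(ep <- downsample_epoch_baseline(rec), "dropped")
  expect_equal(dim(ep$data)[3], 1)
})

test_that("the artifact projector removes exactly the artifact subspace", {
  set.seed(8)
  n_ch <- 24
  u <- rnorm(n_ch); u <- u / sqrt(sum(u^2))
  w <- sin(seq(0, 6 * pi, length.out = 176)) * 50
  tt <- epoch_times()

  # pure artifact data is annihilated
  art <- array(rep(outer(u, w), 3), c(n_ch, 176, 3))
  proj <- artifact_project(epoch_set(art, tt), list(cardiac = outer(u, w)))
  expect_lt(sum(proj$data^2) / sum(art^2), 1e-20)

  # data orthogonal to the topography passes unchanged
  v <- rnorm(n_ch); v <- v - sum(v * u) * u
  ortho <- array(rep(outer(v, w), 3), c(n_ch, 176, 3))
  proj2 <- artifact_project(epoch_set(ortho, tt), list(cardiac = outer(u, w)))
  expect_equal(proj2$data, ortho, tolerance = 1e-12)

  expect_error(
    artifact_project(epoch_set(ortho, tt), list(bad = matrix(0, n_ch, 10))),
    "degenerate")
})

test_that("a planted topography at SNR 1 is suppressed below 5% residual power", {
  set.seed(11)
  gain <- test_gain()
  erf_clean <- make_erf("C", seed = 31, gain = gain)
  n_ch <- nrow(erf_clean$data)
  u <- rnorm(n_ch); u <- u / sqrt(sum(u^2))
  w <- sin(2 * pi * epoch_times() / 90)
  w <- w * sqrt(mean(erf_clean$data^2)) / sqrt(mean((u %*% t(w))^2))  # SNR 1
  art <- outer(u, w)
  mixed <- epoch_set(array(erf_clean$data + art, c(n_ch, 176, 1)),
                     epoch_times())
  # topography estimated from artifact-dominated but contaminated segments
  seg <- 5 * art + matrix(rnorm(n_ch * 176, 0, sqrt(mean(art^2))), n_ch)
  cleaned <- artifact_project(mixed, list(planted = seg))
  u_hat <- attr(cleaned, "projectors")[, 1]
  resid <- cleaned$data[, , 1] -
    (erf_clean$data - tcrossprod(u_hat) %*% erf_clean$data)
  expect_lt(sum(resid^2) / sum(art^2), 0.05)
})

test_that("trial averaging reduces noise as 1/n", {
  set.seed(13)
  n_tr <- 154
  sig <- sin(2 * pi * epoch_times() / 80)
  dat <- array(rnorm(4 * 176 * n_tr), c(4, 176, n_tr)) +
    rep(rbind(sig, sig, sig, sig), n_tr)
  ep <- epoch_set(dat, epoch_times())
  erf <- average_erf(ep)
  expect_equal(erf$n_trials_averaged, n_tr)
  noise_tr <- mean((dat[, , 1] - rbind(sig, sig, sig, sig))^2)
  noise_av <- mean((erf$data - rbind(sig, sig, sig, sig))^2)
  expect_equal(noise_tr / noise_av, n_tr, tolerance = 0.2)

  # identical trials average to any single trial
  same <- array(rep(dat[, , 1], 3), c(4, 176, 3))
  expect_equal(average_erf(epoch_set(same, epoch_times()))$data, dat[, , 1])
})
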