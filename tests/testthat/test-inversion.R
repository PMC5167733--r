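test_that("variational Laplace matches the conjugate solution on a linear model", {
  toy <- conjugate_toy()
  res <- variational_laplace(toy$y, toy$f, toy$prior,
                             settings = list(update_noise = FALSE,
                                             tol = 1e-12, maxit = 300))
  expect_lt(abs(res$posterior$mean - toy$post_mean), 1e-6)
  expect_lt(abs(res$posterior$cov - toy$post_var), 1e-6)
  expect_lt(abs(res$evidence$free_energy - toy$logZ), 1e-3)
  expect_equal(res$evidence$free_energy,
               res$evidence$accuracy - res$evidence$complexity,
               tolerance = 1e-6)
  expect_true(all(diff(res$F_trace) >= -1e-9))
})

test_that("the noise-precision update recovers the generating noise level", {
  toy <- conjugate_toy(seed = 7)
  prior <- toy$prior
  prior$noise_hyperprior <- c(0, 16)
  res <- variational_laplace(toy$y, toy$f, prior)
  expect_equal(exp(-res$posterior$noise$log_precision), toy$sig2,
               tolerance = 0.35)
  expect_true(all(diff(res$F_trace) >= -1e-9))
})

test_that("a pinned irrelevant parameter leaves the evidence unchanged", {
  toy <- conjugate_toy()
  res <- variational_laplace(toy$y, toy$f, toy$prior,
                             settings = list(update_noise = FALSE,
                                             tol = 1e-12, maxit = 300))
  prior2 <- structure(
    list(mean = c(theta = 0, dummy = 0),
         cov = diag(c(toy$prior$cov[1, 1], 1e-10)),
         noise_hyperprior = toy$prior$noise_hyperprior),
    class = "prior_density")
  f2 <- function(th) matrix(th[1] * toy$g + th[2] * seq_along(toy$g), 1)
  res2 <- variational_laplace(toy$y, f2, prior2,
                              settings = list(update_noise = FALSE,
                                              tol = 1e-12, maxit = 300))
  expect_lt(abs(res2$evidence$free_energy - res$evidence$free_energy), 1e-3)
})

test_that("windowing follows the closed-interval sample convention", {
  erf <- make_erf("A", seed = 41)
  rd <- window_data(erf, window_spec(1, 40))
  expect_equal(ncol(rd$Y), 20)                  # samples in [1, 41] on 2 ms grid
  expect_equal(rd$times[1], 2)
  expect_equal(rd$times[length(rd$times)], 40)

  full <- window_data(erf, window_spec(0, 300))
  expect_equal(ncol(full$Y), sum(erf$times >= 0))

  # nesting: shorter windows are a prefix of longer ones before reduction
  sel <- function(w) erf$data[, erf$times >= w$start - 1e-9 &
                                erf$times <= w$start + w$length + 1e-9]
  a <- sel(window_spec(1, 100)); b <- sel(window_spec(1, 200))
  expect_identical(a, b[, seq_len(ncol(a))])

  expect_error(window_data(erf, window_spec(200, 60), n_modes = 7), NA)
  w_bad <- window_spec(0, 300); w_bad$start <- -80
  expect_error(window_data(erf, w_bad), "outside")

  # orthonormal reduction basis
  expect_lt(max(abs(crossprod(rd$basis) - diag(ncol(rd$basis)))), 1e-10)
})

test_that("noiseless data at the prior mean is recovered at the prior mean", {
  gain <- test_gain()
  model <- build_model("C")
  src <- simulate_sources(model, epoch_times())
  erf <- structure(list(times = epoch_times(),
                        data = project_to_sensors(src, gain),
                        n_trials_averaged = 1), class = "erf")
  rd <- window_data(erf, window_spec(1, 260))
  fit <- invert(model, rd, gain)
  sds <- sqrt(diag(default_priors(model)$cov))
  expect_true(all(abs(fit$posterior$mean) < 0.1 * sds))
  expect_true(all(diff(fit$F_trace) >= -1e-9))
})

test_that("the generating architecture has higher evidence than its rival", {
  gain <- synthetic_gain(sensor_layout(102), seed = 1)
  gt <- ground_truth("C", snr = 5)
  wins <- 0L
  for (r in 1:10) {
    sp <- sample_subject(gt, seed = 2000 + r)
    erf <- average_erf(synthesize_epochs(sp, gain))
    rd <- window_data(erf, window_spec(1, 260))
    fC <- invert(build_model("C"), rd, gain)$evidence$free_energy
    fA <- invert(build_model("A"), rd, gain)$evidence$free_energy
    wins <- wins + (fC > fA)
  }
  expect_gte(wins, 9)
})

test_that("posterior input strengths track the per-subject ground truth", {
  gt <- ground_truth("D", snr = 5)
  gain <- synthetic_gain(sensor_layout(102), seed = gt$gain_seed)
  truth <- fitted <- numeric(20)
  for (i in 1:20) {
    sp <- sample_subject(gt, seed = 1000 + i)
    erf <- average_erf(synthesize_epochs(sp, gain))
    rd <- window_data(erf, window_spec(1, 260))
    fit <- invert(build_model("D"), rd, gain)
    truth[i] <- log(sp$model$inputs$phasic$gains[["SIc"]])
    fitted[i] <- fit$posterior$mean[["amp_phasic_SIc"]]
  }
  expect_gt(cor(truth, fitted), 0.8)
})

test_that("parameter maps rebuild the model consistently", {
  m <- build_model("D")
  tab <- model_parameters(m)
  expect_setequal(
    tab$name,
    c("for_SIIc_SIc", "for_SIIi_SIIc", "bac_SIc_SIIc", "bac_SIIc_SIIi",
      "self_SIc", "self_SIIc", "self_SIIi",
      "amp_phasic_SIc", "amp_phasic_SIIc",
      "amp_sustained_SIc", "amp_sustained_SIIc",
      "mu_phasic", "sigma_phasic", "mu_sustained", "sigma_sustained"))
  th <- stats::setNames(rep(0.1, nrow(tab)), tab$name)
  m2 <- apply_parameters(m, th)
  expect_equal(m2$forward["SIIc", "SIc"], m$forward["SIIc", "SIc"] * exp(0.1))
  expect_equal(m2$self, m$self + 0.1)
  expect_equal(m2$inputs$phasic$component$onset_mean, 30.1)
  expect_equal(m2$inputs$sustained$component$onset_sd, 70 * exp(0.1))
  # zero vector is the identity
  th0 <- stats::setNames(rep(0, nrow(tab)), tab$name)
  expect_equal(apply_parameters(m, th0)$forward, m$forward)
})
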