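# shared fixtures: everything is generated in code, sized for fast tests

# default epoch grid (500 Hz, closed [-50, 300] ms)
epoch_times <- function() seq(-50, 300, by = 2)

# small sensor array + gain reused across tests
test_gain <- function(n_channels = 24, seed = 3) {
  synthetic_gain(sensor_layout(n_channels), seed = seed)
}

# one subject's trial-averaged ERF from a given architecture
make_erf <- function(architecture = "C", seed = 1, snr = 5, n_trials = 154,
                     gain = test_gain(), gt = NULL) {
  if (is.null(gt)) gt <- ground_truth(architecture, snr = snr)
  sp <- sample_subject(gt, seed = seed, n_trials = n_trials)
  average_erf(synthesize_epochs(sp, gain))
}

# linear-Gaussian toy problem with its exact conjugate solution
conjugate_toy <- function(seed = 42, Tn = 60, sig2 = 0.5, s0 = 2,
                          theta_true = 1.3) {
  set.seed(seed)
  g <- sin(seq(0, 3 * pi, length.out = Tn))
  y <- matrix(theta_true * g + rnorm(Tn, 0, sqrt(sig2)), 1)
  P <- 1 / s0^2 + sum(g^2) / sig2
  S <- sig2 * diag(Tn) + s0^2 * tcrossprod(g)
  logZ <- -Tn / 2 * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * drop(y %*% solve(S, t(y)))
  list(y = y, g = g, sig2 = sig2,
       f = function(th) matrix(th[1] * g, 1),
       prior = structure(list(mean = c(theta = 0), cov = matrix(s0^2),
                              noise_hyperprior = c(log(1 / sig2), 1e8)),
                         class = "prior_density"),
       post_mean = (sum(g * y) / sig2) / P, post_var = 1 / P, logZ = logZ)
}
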