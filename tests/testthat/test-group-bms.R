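test_that("equal evidences give a symmetric Dirichlet posterior", {
  for (M in c(2, 4)) {
    Fm <- matrix(5, 10, M)
    bms <- rfx_bms(evidence_table(Fm))
    expect_equal(unname(bms$alpha), rep(bms$alpha[[1]], M))
    expect_equal(unname(bms$exceedance), rep(1 / M, M), tolerance = 0.02)
    expect_equal(sum(bms$exceedance), 1)
    expect_equal(sum(bms$expected_freq), 1, tolerance = 1e-9)
  }
})

test_that("decisive evidence drives the exceedance probability to its limit", {
  # one decisive subject: alpha = (1, 2) under the uniform prior, so the
  # exceedance is exactly 1 - BetaCDF(1/2; 2, 1) = 3/4 -- the random-effects
  # ceiling for n = 1
  Fm <- matrix(c(0, 20), 1, 2)
  bms <- rfx_bms(evidence_table(Fm))
  expect_equal(unname(bms$alpha), c(1, 2), tolerance = 1e-6)
  expect_equal(bms$exceedance[[2]], 1 - pbeta(0.5, 2, 1), tolerance = 1e-6)
  # a decisive group saturates it
  bms10 <- rfx_bms(evidence_table(matrix(rep(c(0, 20), each = 10), 10, 2)))
  expect_gt(bms10$exceedance[[2]], 0.99)
})

test_that("the Dirichlet update is invariant to per-subject evidence shifts", {
  set.seed(5)
  Fm <- matrix(rnorm(30, sd = 3), 10, 3)
  b1 <- rfx_bms(evidence_table(Fm))
  b2 <- rfx_bms(evidence_table(Fm + rnorm(10) %o% rep(1, 3) * 50))
  expect_equal(b1$alpha, b2$alpha, tolerance = 1e-6)
})

test_that("two-model exceedance agrees with the Beta closed form", {
  # consistent group favoring model 2 by 3 nats
  Fm <- matrix(rep(c(0, 3), each = 10), 10, 2)
  bms <- rfx_bms(evidence_table(Fm))
  a <- unname(bms$alpha)
  expect_equal(bms$exceedance[[2]], 1 - pbeta(0.5, a[2], a[1]),
               tolerance = 0.005)
  # Monte-Carlo route matches the closed form too
  mc <- exceedance_prob(a, n_samples = 1e6, seed = 2, method = "mc")
  expect_equal(mc[2], 1 - pbeta(0.5, a[2], a[1]), tolerance = 0.005)
})

test_that("exceedance probabilities behave across methods and shapes", {
  expect_equal(exceedance_prob(c(1, 1)), c(0.5, 0.5), tolerance = 0.002)
  mc <- exceedance_prob(c(8, 2), n_samples = 1e6, seed = 3, method = "mc")
  expect_equal(mc[1], 1 - pbeta(0.5, 8, 2), tolerance = 0.003)
  ep4 <- exceedance_prob(c(1, 1, 1, 1), n_samples = 1e6, seed = 4)
  expect_equal(ep4, rep(0.25, 4), tolerance = 0.005)
  expect_equal(sum(ep4), 1)                    # argmax partition: exact
  expect_error(exceedance_prob(c(1, -1)), "alpha")
  expect_error(exceedance_prob(c(1, 1, 1), method = "beta"), "2 models")
})

test_that("the paired t-test matches the textbook computation", {
  # printed toy table: 5 paired measurements
  x <- c(4.1, 5.0, 6.2, 4.8, 5.5)
  y <- c(3.6, 4.8, 5.1, 4.9, 4.7)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  res <- paired_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("BMA weights and strengths follow the evidence table", {
  Fm <- matrix(c(1, 2, 5, 9, 2, 1), 3, 2,
               dimnames = list(NULL, c("A", "D")))
  ev <- evidence_table(Fm)
  mk <- function(si, sii) list(input_strengths = c(SIc = si, SIIc = sii))
  posts <- list(list(A = mk(1, 1), D = mk(2.0, 1.0)),
                list(A = mk(1, 1), D = mk(2.2, 1.1)),
                list(A = mk(1, 1), D = mk(1.8, 0.9)))
  gr <- bma_inputs(ev, posts, mode = "winner")
  expect_equal(gr$winning_model, "D")
  expect_true(all(rowSums(gr$weights == 1) == 1))   # one-hot rows
  expect_equal(unname(gr$strengths[, "SIc"]), c(2.0, 2.2, 1.8))
  expect_gt(gr$contrast$t, 0)
  expect_equal(gr$contrast$df, 2)

  grs <- bma_inputs(ev, posts, mode = "softmax")
  expect_equal(unname(rowSums(grs$weights)), rep(1, 3), tolerance = 1e-12)
  expect_error(evidence_table(matrix(1, 3, 1)), "2 models")
})

test_that("identical strengths give a null contrast", {
  Fm <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("A", "D")))
  mk <- function() list(input_strengths = c(SIc = 1.5, SIIc = 1.5))
  posts <- replicate(3, list(A = mk(), D = mk()), simplify = FALSE)
  gr <- bma_inputs(evidence_table(Fm), posts)
  expect_equal(gr$contrast$t, 0)
  expect_equal(gr$contrast$p, 1)
})

test_that("identical subjects and identical models give EP = 1/M", {
  gain <- test_gain()
  erf <- make_erf("C", seed = 61, gain = gain)
  plan <- build_plan("initiation", windows = list(window_spec(1, 60)))
  plan$models <- c("serial", "serial")         # same model under two labels
  sw <- bms_sweep(plan, list(erf, erf), gain)
  ex <- sw$results[[1]]$bms$exceedance
  expect_equal(unname(ex), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(sum(ex), 1, tolerance = 1e-9)
  ev <- sw$results[[1]]$evidence$values
  expect_identical(ev[1, ], ev[2, ])           # identical subjects
  expect_identical(unname(ev[, 1]), unname(ev[, 2]))  # identical models
})
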