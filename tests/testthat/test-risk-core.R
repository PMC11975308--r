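test_that("sigmoid matches direct evaluation and stays stable at extremes", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sigmoid(-2), 1 / (1 + exp(2)), tolerance = 1e-12)
  # no overflow/underflow to 0 or 1 at |score| = 500
  p <- sigmoid(c(-500, 500))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(is.finite(p)))
  expect_error(sigmoid(NaN), "finite")
  expect_error(sigmoid(Inf), "finite")
})

test_that("compose_risks reproduces the closed forms of each formulation", {
  r <- compose_risks(0, 0, "riskform1")
  expect_equal(r$y_hat_1, 0.5)
  expect_equal(r$y_hat_2, 0.75)

  # risk2 exceeds risk1 even when the second score is lower
  r <- compose_risks(1.0, -2.0, "riskform1")
  expect_equal(r$y_hat_1, 1 / (1 + exp(-1)), tolerance = 1e-6)
  expect_equal(r$y_hat_2,
               1 - (1 - 1 / (1 + exp(-1))) * (1 - 1 / (1 + exp(2))),
               tolerance = 1e-6)
  expect_gt(r$y_hat_2, r$y_hat_1)

  r <- compose_risks(0, 2.0, "riskform2")
  expect_equal(r$y_hat_2, 1 - 0.5 * (1 / (1 + exp(-2))), tolerance = 1e-6)

  r <- compose_risks(0, 5.0, "baseline")
  expect_equal(r$y_hat_1, 0.5)
  expect_equal(r$y_hat_2, 1 / (1 + exp(-5)), tolerance = 1e-6)

  expect_error(compose_risks(0, 0, "riskform3"), "formulation")
  expect_error(compose_risks(c(0, 1), 0, "baseline"), "equal length")
})

test_that("progressive formulations never decrease risk over scans", {
  set.seed(91)
  n <- 20000
  s1 <- runif(n, -20, 20)
  s2 <- runif(n, -20, 20)
  for (fm in c("riskform1", "riskform2")) {
    r <- compose_risks(s1, s2, fm)
    expect_equal(sum(r$y_hat_2 < r$y_hat_1), 0)
    expect_true(all(r$y_hat_1 > 0 & r$y_hat_1 < 1))
    expect_true(all(r$y_hat_2 > 0 & r$y_hat_2 < 1))
  }
  # the unconstrained baseline does violate the ordering for some pairs
  rb <- compose_risks(s1, s2, "baseline")
  expect_gt(sum(rb$y_hat_2 < rb$y_hat_1), 0)
})

test_that("riskform1 risk2 is symmetric in the two scores", {
  set.seed(92)
  s1 <- runif(200, -10, 10)
  s2 <- runif(200, -10, 10)
  expect_equal(compose_risks(s1, s2, "riskform1")$y_hat_2,
               compose_risks(s2, s1, "riskform1")$y_hat_2, tolerance = 1e-12)
})

test_that("limit behaviour of the compositions", {
  s2 <- seq(-5, 5, by = 0.5)
  # first scan carries no risk: riskform1 collapses to sigmoid(s2)
  r <- compose_risks(rep(-30, length(s2)), s2, "riskform1")
  expect_equal(r$y_hat_2, sigmoid(s2), tolerance = 1e-6)
  # riskform2: a large second score attains the equality boundary ...
  s1 <- seq(-5, 5, by = 0.5)
  r <- compose_risks(s1, rep(30, length(s1)), "riskform2")
  expect_equal(r$y_hat_2, r$y_hat_1, tolerance = 1e-6)
  # ... and a very low one drives the risk to 1
  r <- compose_risks(s1, rep(-30, length(s1)), "riskform2")
  expect_equal(r$y_hat_2, rep(1, length(s1)), tolerance = 1e-6)
})

test_that("risk2 is increasing in s2 under riskform1, decreasing under riskform2", {
  s2 <- seq(-10, 10, by = 0.1)
  for (s1 in c(-3, 0, 2)) {
    y1 <- compose_risks(rep(s1, length(s2)), s2, "riskform1")$y_hat_2
    expect_true(all(diff(y1) > 0))
    y2 <- compose_risks(rep(s1, length(s2)), s2, "riskform2")$y_hat_2
    expect_true(all(diff(y2) < 0))
  }
})

test_that("pair_loss is the summed natural-log cross-entropy", {
  expect_equal(pair_loss(0.5, 0.75, y1 = 0, y2 = 1),
               -log(0.5) - log(0.75), tolerance = 1e-6)
  expect_equal(pair_loss(0.5, NULL, y1 = 1), -log(0.5), tolerance = 1e-6)
  # single-scan form via NA second entries
  expect_equal(pair_loss(c(0.5, 0.5), c(0.75, NA), y1 = c(0, 1),
                         y2 = c(1, NA)),
               c(-log(0.5) - log(0.75), -log(0.5)), tolerance = 1e-6)
  # perfect prediction drives the loss to (clamped) zero
  expect_lt(pair_loss(1 - 1e-9, 1 - 1e-9, y1 = 1, y2 = 1), 1e-5)
  # non-negative on random valid inputs
  set.seed(5)
  p <- runif(100); q <- runif(100)
  y1 <- rbinom(100, 1, 0.5); y2 <- rbinom(100, 1, 0.5)
  expect_true(all(pair_loss(p, q, y1, y2) >= 0))
})

test_that("riskreg penalty is a margin loss on raw scores", {
  cfg <- regularizer_config(margin = 2, gamma = 1, mode = "riskreg")
  expect_equal(riskreg_penalty(0, 3, cfg), 0)
  expect_equal(riskreg_penalty(0, 0, cfg), 2)
  cfg2 <- regularizer_config(margin = 2, gamma = 0.5, mode = "riskreg")
  expect_equal(riskreg_penalty(1, 2, cfg2), 0.5)
  # zero on, and only on, s2 - s1 >= margin
  set.seed(6)
  s1 <- runif(500, -5, 5); s2 <- runif(500, -5, 5)
  pen <- riskreg_penalty(s1, s2, cfg)
  expect_equal(pen == 0, s2 - s1 >= 2)
  expect_true(all(pen >= 0))
  expect_error(riskreg_penalty(0, 0, regularizer_config(mode = "none")),
               "margin-loss")
})

test_that("conreg penalty is the contrastive loss on embeddings", {
  cfg <- regularizer_config(margin = 2, gamma = 1, mode = "conreg")
  h <- c(0.3, -0.2, 0.5)
  expect_equal(conreg_penalty(h, h, 1, 1, cfg), 0)
  expect_equal(conreg_penalty(h, h, 0, 1, cfg), 4)   # max(0, 2 - 0)^2
  # unit distance, differing labels: (2 - 1)^2
  expect_equal(conreg_penalty(c(0, 0), c(1, 0), 0, 1, cfg), 1)
  # same labels at unit distance: d^2
  expect_equal(conreg_penalty(c(0, 0), c(1, 0), 1, 1, cfg), 1)
  expect_error(conreg_penalty(c(1, 2), c(1, 2, 3), 0, 1, cfg), "dimension")
})
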