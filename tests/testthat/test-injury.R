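test_that("injury probability is the analytic strength-exceedance average", {
  # deterministic compression 3315.2 N against strength N(5448, 2366):
  # standard normal CDF at (3315.2 - 5448)/2366 = -0.9015 -> 0.1836
  s <- compression_samples(rep(3315.2, 10))
  expect_equal(injury_probability(s, strength_model(5448, 2366)), 0.1836,
               tolerance = 1e-3)
  # unbreakable disc
  expect_lt(injury_probability(s, strength_model(1e9, 2366)), 1e-12)
  # compression exactly at the strength mean with a nearly rigid strength
  expect_equal(injury_probability(compression_samples(rep(5448, 5)),
                                  strength_model(5448, 1e-6)), 0.5)
})

test_that("conditioning reweights but never touches the draws", {
  sc <- fixture_scenario(n = 5000, seed = 2)
  s <- simulate_lifting(sc)
  str_ <- strength_model()
  expect_identical(condition_on_injury(s, str_, "none"), s)
  ct <- condition_on_injury(s, str_, "true")
  cf <- condition_on_injury(s, str_, "false")
  expect_identical(ct$compression_n, s$compression_n)
  expect_identical(ct$shear_n, s$shear_n)
  expect_equal(ct$weight + cf$weight, s$weight)  # likelihoods sum to 1
  # impossible evidence -> inference error with diagnostic
  low <- compression_samples(rep(0, 10))
  expect_error(condition_on_injury(low, strength_model(1e6, 1), "true"),
               "impossible under the prior")
})

test_that("Gaussian toy case matches the closed-form skew posterior", {
  # C ~ N(0,1), S ~ N(0,1): conditioning on C > S tilts the prior by
  # Phi(c); the posterior is skew-normal with mean 1/sqrt(pi) and
  # variance 1 - 1/pi
  n <- 2e5
  set.seed(12)
  s <- compression_samples(rnorm(n))
  toy <- strength_model(0, 1)
  post_t <- posterior_summary(s, toy, "true")
  post_f <- posterior_summary(s, toy, "false")
  se <- sqrt((1 - 1 / pi) / post_t$ess)
  expect_equal(post_t$mean, 1 / sqrt(pi), tolerance = 4 * se / (1 / sqrt(pi)))
  expect_equal(post_f$mean, -1 / sqrt(pi), tolerance = 4 * se / (1 / sqrt(pi)))
  expect_equal(post_t$sd, sqrt(1 - 1 / pi), tolerance = 0.01)
  # evidence certain: degenerate strength far below every draw
  high <- compression_samples(rnorm(100, 50, 1))
  sure <- strength_model(0, 1e-9)
  expect_equal(posterior_summary(high, sure, "true")$mean,
               summarize_samples(high)$mean)
})

test_that("posterior ordering and the law of total expectation hold", {
  sc <- fixture_scenario(n = 2e4, seed = 6)
  s <- simulate_lifting(sc)
  str_ <- strength_model()
  p <- injury_probability(s, str_)
  for (field in c("compression_n", "shear_n")) {
    prior <- summarize_samples(s, field)$mean
    m_t <- posterior_summary(s, str_, "true", field)$mean
    m_f <- posterior_summary(s, str_, "false", field)$mean
    # descendant evidence propagates through the shared draws
    expect_equal(p * m_t + (1 - p) * m_f, prior, tolerance = 1e-6)
    if (field == "compression_n") {
      expect_gt(m_t, prior)
      expect_gt(prior, m_f)
    } else {
      # shear shifts in the direction of its weighted covariance with the
      # injury likelihood
      w <- liftbn:::.exceedance(s$compression_n, str_)
      cov_sign <- sign(mean(w * s$shear_n) - mean(w) * mean(s$shear_n))
      expect_equal(sign(m_t - m_f), cov_sign)
    }
  }
})

test_that("strength-sampling mode agrees with the analytic weights", {
  sc <- fixture_scenario(n = 2e4, seed = 13)
  s <- simulate_lifting(sc)
  str_ <- strength_model()
  m_analytic <- posterior_summary(s, str_, "true")$mean
  m_sampled <- posterior_summary(s, str_, "true", method = "sample", seed = 99)$mean
  # the sampled route is unbiased but noisier; agree within ~3 x its SE
  expect_equal(m_sampled, m_analytic, tolerance = 3 * 0.02)
})
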