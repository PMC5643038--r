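test_that("mad_to_sd is the exact closed form for a normal distribution", {
  expect_identical(mad_to_sd(0), 0)
  expect_identical(mad_to_sd(1), sqrt(pi / 2))
  expect_equal(mad_to_sd(1), 1.2533141, tolerance = 1e-7)
  x <- c(0.3, 2.7, 9.4)
  expect_identical(mad_to_sd(2 * x), 2 * mad_to_sd(x))  # scale equivariance
  expect_error(mad_to_sd(-1), ">= 0")
})

test_that("zero SDs collapse the simulation onto the deterministic value", {
  sc <- random_scenario(fixture_posture(), setNames(rep(0, 5), names(fixture_sds)),
                        53.1, 0, fixture_subject(), n_iterations = 50, seed = 3)
  s <- simulate_lifting(sc, vary = "both")
  det <- fixture_linkage()
  expect_equal(s$compression_n, rep(det$compression_n, 50))
  expect_equal(s$shear_n, rep(det$shear_n, 50))
  expect_true(all(s$weight == 1))
})

test_that("sample sets are bit-identical under the same seed, and substreams
           keep hand-load draws stable across vary modes", {
  sc <- fixture_scenario(n = 500, seed = 42)
  s1 <- simulate_lifting(sc, vary = "both")
  s2 <- simulate_lifting(sc, vary = "both")
  expect_identical(s1, s2)
  s3 <- simulate_lifting(sc, vary = "both", seed = 43)
  expect_false(identical(s1$compression_n, s3$compression_n))
  # per-input substreams: the hand-mass stream does not depend on whether
  # posture is also varied
  s_hand <- simulate_lifting(sc, vary = "hand_load")
  expect_identical(s1$hand_mass_kg, s_hand$hand_mass_kg)
  expect_true(all(s_hand$torso_deg == 40))
})

test_that("negative hand-mass draws are clamped to zero and counted", {
  sc <- random_scenario(fixture_posture(), fixture_sds, 1, 5, fixture_subject(),
                        n_iterations = 2000, seed = 9)
  s <- simulate_lifting(sc, vary = "hand_load")
  expect_gt(attr(s, "n_clamped_hand_mass"), 0)
  expect_true(all(s$hand_mass_kg >= 0))
  expect_equal(sum(s$hand_mass_kg == 0), attr(s, "n_clamped_hand_mass"))
})

test_that("negative SDs are rejected", {
  expect_error(random_scenario(fixture_posture(),
                               c(ankle = -1, knee = 9.4, torso = 6.3,
                                 shoulder = 7.9, elbow = 11.8),
                               53.1, 12.8, fixture_subject()),
               ">= 0")
  expect_error(random_scenario(fixture_posture(), fixture_sds, 53.1, -2,
                               fixture_subject()), ">= 0")
})

test_that("weighted summaries reduce to unweighted statistics for uniform weights", {
  set.seed(5)
  x <- rnorm(501, 10, 2)
  s_w <- summarize_samples(x, weights = rep(2.5, 501))
  expect_equal(s_w$mean, mean(x))
  expect_equal(s_w$sd, sd(x))
  expect_equal(s_w$p50, unname(quantile(x, 0.5, type = 1)))
  expect_equal(s_w$p25, unname(quantile(x, 0.25, type = 1)))
  expect_equal(s_w$p75, unname(quantile(x, 0.75, type = 1)))
  expect_equal(s_w$ess, 501)

  const <- summarize_samples(rep(7, 20))
  expect_equal(const$mean, 7)
  expect_equal(const$sd, 0)
  expect_equal(c(const$p25, const$p50, const$p75), c(7, 7, 7))
})

test_that("weighted quantiles match the expanded-sample brute-force oracle", {
  set.seed(8)
  for (rep_i in 1:5) {
    x <- round(rnorm(12, 0, 5), 2)
    w <- sample(1:4, 12, replace = TRUE)
    expanded <- rep(x, w)
    probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    expect_equal(weighted_quantile(x, w, probs),
                 unname(quantile(expanded, probs, type = 1)))
  }
  expect_error(weighted_quantile(1:3, c(0, 0, 0), 0.5), "zero")
})

test_that("Monte Carlo mean converges with shrinking standard error", {
  sc <- fixture_scenario(seed = 21)
  ref <- simulate_lifting(sc, vary = "both", n = 2e5)
  m_ref <- mean(ref$compression_n)
  for (n in c(1e3, 1e4)) {
    s <- simulate_lifting(sc, vary = "both", n = n, seed = 22)
    se <- sd(s$compression_n) / sqrt(n)
    expect_lt(abs(mean(s$compression_n) - m_ref), 4 * se + 4 * sd(ref$compression_n) / sqrt(2e5))
  }
})

test_that("with only hand load random the output SD follows the affine slope", {
  slope <- (fixture_linkage(54.1)$compression_n - fixture_linkage(53.1)$compression_n)
  sc <- fixture_scenario(seed = 31)
  s <- simulate_lifting(sc, vary = "hand_load", n = 2e5)
  expect_equal(sd(s$compression_n), abs(slope) * 12.8, tolerance = 0.01)
})

test_that("posture randomness shifts the mean away from the deterministic value", {
  # the angle-to-moment map is nonlinear (cosine), so E[f(X)] != f(E[X])
  sc <- fixture_scenario(seed = 41)
  s <- simulate_lifting(sc, vary = "posture", n = 2e5)
  gap <- abs(mean(s$compression_n) - fixture_linkage()$compression_n)
  se <- sd(s$compression_n) / sqrt(2e5)
  expect_gt(gap, 3 * se)
})
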