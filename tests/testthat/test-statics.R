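test_that("no load and weightless segments give zero moments everywhere", {
  a <- weightless_anthro()
  p <- fixture_posture()
  el <- elbow_load(p, 0, a)
  sh <- shoulder_load(el, p, a)
  l5 <- l5s1_load(sh, p, a)
  expect_equal(el$moment, 0)
  expect_equal(sh$moment, 0)
  expect_equal(l5$moment, 0)
  expect_equal(erector_force(l5), 0)
  disc <- disc_angle(p)
  cs <- compression_shear(l5, erector_force(l5), disc)
  expect_equal(cs$compression_n, 0)
  expect_equal(cs$shear_n, 0)
})

test_that("elbow moment scales with the cosine of the forearm angle", {
  a <- weightless_anthro()  # isolate the hand-load lever
  m0 <- elbow_load(posture(82, 114, 40, 192, 0), 20, a)$moment
  m60 <- elbow_load(posture(82, 114, 40, 192, 60), 20, a)$moment
  expect_equal(m0 / m60, cos(0) / cos(60 * pi / 180), tolerance = 1e-12)
  # horizontal forearm maximises the lever
  expect_gt(abs(m0), abs(elbow_load(posture(82, 114, 40, 192, 30), 20, a)$moment))
})

test_that("chained top-down moments equal one-shot free-body summation", {
  for (seed in 1:5) {
    rc <- random_case(200, seed)
    a <- resolve_anthropometry(rc$subject)
    el <- elbow_load(rc$posture, rc$hand, a)
    sh <- shoulder_load(el, rc$posture, a)
    l5 <- l5s1_load(sh, rc$posture, a)
    expect_equal(el$moment,
                 free_body_moment("elbow", rc$posture, rc$hand, rc$subject),
                 tolerance = 1e-9)
    expect_equal(sh$moment,
                 free_body_moment("shoulder", rc$posture, rc$hand, rc$subject),
                 tolerance = 1e-9)
    expect_equal(l5$moment,
                 free_body_moment("l5s1", rc$posture, rc$hand, rc$subject),
                 tolerance = 1e-9)
  }
})

test_that("L5/S1 vertical reaction equals the total supported weight", {
  rc <- random_case(50, 7)
  a <- resolve_anthropometry(rc$subject)
  l5 <- l5s1_load(shoulder_load(elbow_load(rc$posture, rc$hand, a), rc$posture, a),
                  rc$posture, a)
  supported <- rc$hand * 9.81 +
    (2 * sum(a$weights[c("hand", "forearm", "upper_arm")]) + a$weights[["torso"]])
  expect_equal(-l5$fy, unname(supported), tolerance = 1e-12)
})

test_that("disc-angle geometry identities and coefficient handling", {
  p <- fixture_posture()
  d <- disc_angle(p)
  expect_equal(d$T_deg, 50)       # T = 90 - torso
  expect_equal(d$K_deg, 148)      # interior thigh-shank angle
  # zero coefficients give no deviation from 40 degrees
  zero <- setNames(rep(0, 6), c("b0", "bT", "bK", "bTK", "bT2", "bK2"))
  expect_equal(disc_angle(p, zero)$disc_angle_deg, 40)
  expect_equal(disc_angle(p, zero)$beta_deg, 0)
  expect_error(disc_angle(p, c(b0 = 1)), "missing beta regression")
})

test_that("erector force is |moment| / arm and inversely proportional to the arm", {
  l5 <- list(fx = 0, fy = -500, moment = 150.9)
  expect_equal(erector_force(l5, 0.053), 150.9 / 0.053)
  expect_equal(erector_force(l5, 0.053 / 2), 2 * erector_force(l5, 0.053))
  expect_error(erector_force(l5, 0), "> 0")
})

test_that("disc-frame rotation preserves the reaction-force norm", {
  set.seed(11)
  n <- 1000
  fx <- rnorm(n, 0, 300)
  fy <- rnorm(n, -600, 300)
  ang <- runif(n, -180, 180)
  disc <- list(disc_angle_deg = ang)
  cs <- compression_shear(list(fx = fx, fy = fy, moment = 0), 0, disc)
  expect_equal(cs$compression_n^2 + cs$shear_n^2, fx^2 + fy^2, tolerance = 1e-12)
})

test_that("compression is affine in hand mass with constant slope", {
  masses <- seq(0, 80, by = 10)
  comp <- vapply(masses, function(m) fixture_linkage(m)$compression_n, numeric(1))
  slopes <- diff(comp) / diff(masses)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
  expect_gt(slopes[1], 0)
})

test_that("identical inputs give bit-identical linkage results", {
  r1 <- fixture_linkage()
  r2 <- fixture_linkage()
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("vectorized and scalar evaluation agree", {
  p <- posture(c(82, 70), c(114, 100), c(40, 55), c(192, 200), c(-56, 10))
  res <- linkage(p, c(53.1, 20), fixture_subject())
  df <- as.data.frame(res)
  one <- as.data.frame(linkage(posture(70, 100, 55, 200, 10), 20, fixture_subject()))
  expect_equal(df[2, ], one, ignore_attr = TRUE)
})
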