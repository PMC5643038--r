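# Shared builders for the test suite. The "fixture" scenario is the packaged
# heavy-lift task: 161.8 cm / 65.6 kg subject, hand load N(53.1, 12.8) kg,
# measured posture (deg from horizontal) with assessment-error SDs.

fixture_subject <- function() subject(1.618, 65.6)

fixture_posture <- function() posture(82, 114, 40, 192, -56)

fixture_sds <- c(ankle = 9.4, knee = 9.4, torso = 6.3, shoulder = 7.9, elbow = 11.8)

fixture_scenario <- function(n = 1e4, seed = 1L) {
  random_scenario(fixture_posture(), fixture_sds, 53.1, 12.8,
                  fixture_subject(), n_iterations = n, seed = seed)
}

fixture_linkage <- function(hand = 53.1) {
  linkage(fixture_posture(), hand, fixture_subject())
}

# anthropometry stripped of gravity loads: every segment weightless.
# Bypasses table validation on purpose (a real table cannot have zero mass
# fractions) to probe the statics in isolation.
weightless_anthro <- function() {
  a <- resolve_anthropometry(fixture_subject())
  a$weights[] <- 0
  a$masses[] <- 0
  a
}

# a small synthetic sample_set wrapping arbitrary compression draws, for
# injury-inference tests that do not need the linkage model
compression_samples <- function(x, weight = rep.int(1, length(x))) {
  out <- data.frame(compression_n = x, weight = weight)
  class(out) <- c("sample_set", "data.frame")
  out
}

# random scenario generator for property tests (wide but physical ranges)
random_case <- function(n, seed) {
  set.seed(seed)
  list(posture = posture(runif(n, 40, 120), runif(n, 60, 170), runif(n, 0, 90),
                         runif(n, 120, 260), runif(n, -90, 90)),
       hand = runif(n, 0, 80),
       subject = subject(runif(1, 1.4, 2.0), runif(1, 45, 110)))
}
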