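test_that("evaluation sign favours the heavier side, ties to aligned", {
  expect_equal(evaluation_sign(belief_state("oppose", 3, 1)), 1)
  expect_equal(evaluation_sign(belief_state("oppose", 0, 0)), 1)
  expect_equal(evaluation_sign(belief_state("oppose", 1, 2.5)), -1)
})

test_that("keep and flip forces follow the linear gain form", {
  # neutral gains: masses pass through (sign = -1, no K3 term on either side)
  b <- belief_state("oppose", aligned_mass = 2, opposing_mass = 3)
  p0 <- personality_profile(K = 1, K1 = 0, K2 = 0, K3 = 0)
  expect_equal(keep_force(b, p0), 3)
  expect_equal(flip_force(b, p0), 3)
  expect_equal(decide(b, p0), "keep_stance")   # tie keeps prior stance

  # persistent agent holds out against a heavier opposing mass
  b1 <- belief_state("oppose", aligned_mass = 1, opposing_mass = 3)
  pp <- personality_profile(K = 0, K1 = 10, K2 = 0, K3 = 0)
  expect_equal(keep_force(b1, pp), 11)
  expect_equal(flip_force(b1, pp), 3)
  expect_equal(decide(b1, pp), "keep_stance")

  # open agent flips on balanced masses
  b2 <- belief_state("oppose", aligned_mass = 1, opposing_mass = 1)
  po <- personality_profile(K = 0, K1 = 0, K2 = 10, K3 = 0)
  expect_equal(keep_force(b2, po), 1)
  expect_equal(flip_force(b2, po), 11)
  expect_equal(decide(b2, po), "flip_stance")
})

test_that("critical thinking amplifies the evaluation-favoured side", {
  pc <- personality_profile(K = 0, K1 = 0, K2 = 0, K3 = 2)
  b_plus <- belief_state("oppose", aligned_mass = 3, opposing_mass = 1)
  expect_equal(keep_force(b_plus, pc), 3 + 2 * 3)
  expect_equal(flip_force(b_plus, pc), 1)
  b_minus <- belief_state("oppose", aligned_mass = 1, opposing_mass = 3)
  expect_equal(keep_force(b_minus, pc), 1)
  expect_equal(flip_force(b_minus, pc), 3 + 2 * 3)
})

test_that("flip indicator is monotone in persistence and openness gains", {
  grid <- seq(0, 9, by = 1)
  for (masses in list(c(2, 3), c(1, 4), c(3, 3), c(4, 1))) {
    b <- belief_state("oppose", masses[1], masses[2])
    for (K3 in c(0, 1, 2)) {
      flips_k1 <- vapply(grid, function(k1)
        decide(b, personality_profile(K = 1, K1 = k1, K2 = 1, K3 = K3)) ==
          "flip_stance", logical(1))
      expect_true(all(diff(as.integer(flips_k1)) <= 0))   # non-increasing
      flips_k2 <- vapply(grid, function(k2)
        decide(b, personality_profile(K = 1, K1 = 1, K2 = k2, K3 = K3)) ==
          "flip_stance", logical(1))
      expect_true(all(diff(as.integer(flips_k2)) >= 0))   # non-decreasing
    }
  }
})

test_that("at balanced masses K3 only ever reinforces keeping", {
  # a tie evaluates +1, so K3 amplifies the aligned side: it can pull a
  # flip back to keep but never push a keep into a flip
  for (m in c(0, 1, 2.5)) {
    b <- belief_state("oppose", m, m)
    for (K1 in c(0, 1)) for (K2 in c(0, 1, 3)) {
      flips <- vapply(c(0, 0.5, 1, 5, 50), function(k3)
        decide(b, personality_profile(K = 0, K1 = K1, K2 = K2, K3 = k3)) ==
          "flip_stance", logical(1))
      expect_true(all(diff(as.integer(flips)) <= 0))
      if (!flips[1L]) expect_false(any(flips))
    }
  }
})

test_that("with K = K3 = 0 the decision depends only on the gain ratio", {
  set.seed(3)
  for (k in 1:50) {
    al <- runif(1, 0.1, 5); op <- runif(1, 0.1, 5)
    K1 <- runif(1, 0, 4); K2 <- runif(1, 0, 4)
    b <- belief_state("oppose", al, op)
    p <- personality_profile(K = 0, K1 = K1, K2 = K2, K3 = 0)
    expected <- if ((1 + K2) * op / ((1 + K1) * al) > 1)
      "flip_stance" else "keep_stance"
    expect_equal(decide(b, p), expected)
  }
})

test_that("argument accumulation is additive and stance-preserving", {
  b <- belief_state("oppose", 2, 3)
  b2 <- apply_arguments(b, 1, "aligned")
  expect_equal(c(b2$aligned_mass, b2$opposing_mass), c(3, 3))
  expect_equal(apply_arguments(b, numeric()), b)
  b3 <- apply_arguments(belief_state("oppose"), c(0.5, 1.5), "opposing")
  expect_equal(c(b3$aligned_mass, b3$opposing_mass), c(0, 2))
  expect_equal(b3$stance, "oppose")
  expect_error(apply_arguments(b, c(1, -1), "aligned"), "positive")
})

test_that("profiles validate and presets exist for the three archetypes", {
  expect_error(personality_profile(K = -1), ">= 0")
  expect_error(personality_profile(K1 = Inf), ">= 0")
  pp <- personality_preset("persistent")
  po <- personality_preset("open")
  expect_gt(pp$K1, pp$K2)
  expect_gt(po$K2, po$K1)
  expect_gt(personality_preset("critical")$K3, pp$K3)
})
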