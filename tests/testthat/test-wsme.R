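test_that("chain free energy matches term-by-term evaluation on explicit vectors", {
  for (seed in 1:5) {
    m <- toy_dimer(sample(2:6, 1), "random", seed = seed)
    n <- m$chain_A$n_units
    conf <- enumerate_conformations(n)
    for (r in seq_len(nrow(conf))) {
      v <- conf_to_v(conf[r, 1L], conf[r, 2L], n)
      expect_equal(
        chain_free_energy(conf[r, ], m$chain_A, m$intra_A, m$epsilon,
                          m$temperature),
        bf_chain_free_energy(v, m$chain_A$unit_entropies, m$intra_A,
                             m$epsilon, m$temperature),
        tolerance = 1e-12)
    }
  }
})

test_that("chain free energy limiting cases", {
  s <- c(10, 20, 30, 40, 50)
  intra <- contact_set(2L, 4L, 1L, "intra_A")
  # fully unfolded: pure entropy term
  expect_equal(chain_free_energy(c(1, 0), s, intra, 2000, 310), -310 * sum(s))
  # fully folded: pure contact term
  expect_equal(chain_free_energy(c(1, 5), s, intra, 2000, 310), -2000)
  # stretch [2,4] with the single entry (2,4): contact formed, ends unfolded
  expect_equal(chain_free_energy(c(2, 4), s, intra, 2000, 310),
               -2000 - 310 * (s[1] + s[5]))
})

test_that("interaction energy requires only the endpoint units folded", {
  inter <- contact_set(2L, 5L, 3L, "inter")
  expect_equal(interaction_energy(c(1, 0), c(1, 0), inter, 1000), 0)
  expect_equal(interaction_energy(c(2, 2), c(4, 6), inter, 1000), -3000)
  expect_equal(interaction_energy(c(2, 2), c(1, 3), inter, 1000), 0)
  # fully folded pair forms everything
  inter2 <- contact_set(c(1L, 3L), c(2L, 1L), c(1L, 2L), "inter")
  expect_equal(interaction_energy(c(1, 6), c(1, 6), inter2, 1000), -3000)
  # and matches the explicit-vector oracle on random conformations
  for (seed in 1:3) {
    m <- toy_dimer(4, "random", seed = seed)
    conf <- enumerate_conformations(4)
    for (a in seq_len(nrow(conf))) for (b in seq_len(nrow(conf))) {
      expect_equal(
        interaction_energy(conf[a, ], conf[b, ], m$inter, m$epsilon),
        bf_interaction_energy(conf_to_v(conf[a, 1], conf[a, 2], 4),
                              conf_to_v(conf[b, 1], conf[b, 2], 4),
                              m$inter, m$epsilon))
    }
  }
})

test_that("microstate free energy applies the dissociation entropy to layer 0", {
  m <- toy_dimer(3, "hairpin", unit_entropy = c(10, 20, 30))
  sa <- sum(m$chain_A$unit_entropies)
  # dissociated, both unfolded
  expect_equal(microstate_free_energy(c(1, 0), c(1, 0), 0, m),
               -m$temperature * (2 * sa) - m$temperature * m$s_diss)
  # associated, both fully folded: intra + inter contacts only
  expect_equal(microstate_free_energy(c(1, 3), c(1, 3), 1, m),
               -m$epsilon * (sum(m$intra_A$m) + sum(m$intra_B$m) +
                               sum(m$inter$m)))
  # layer gap at fixed conformations = interaction + T * S_diss
  for (cfA in list(c(1, 0), c(2, 2), c(1, 3))) {
    gap <- microstate_free_energy(cfA, c(1, 3), 1, m) -
      microstate_free_energy(cfA, c(1, 3), 0, m)
    expect_equal(gap, interaction_energy(cfA, c(1, 3), m$inter, m$epsilon) +
                   m$temperature * m$s_diss)
  }
})

test_that("native product set enumerates all-contacts-formed associated states", {
  # contacts span units 1..3: a single product state
  m_full <- toy_dimer(3, "hairpin")
  expect_identical(nrow(native_product_set(m_full)), 1L)
  # contacts confined to units 2..3: stretches [2,3] and [1,3] qualify per chain
  m_part <- toy_dimer(3, "hairpin",
                      intra_A = contact_set(2L, 3L, 1L, "intra_A"),
                      intra_B = contact_set(2L, 3L, 1L, "intra_B"),
                      inter = contact_set(2L, 2L, 1L, "inter"))
  ps <- native_product_set(m_part)
  expect_identical(nrow(ps), 4L)
  expect_true(all(ps$delta == 1L))
  # oracle: brute-force predicate over all conformation pairs
  conf <- enumerate_conformations(3)
  ok <- function(cf, intra, side) {
    v <- conf_to_v(cf[1L], cf[2L], 3)
    all(apply(intra, 1L, function(e) all(v[e["i"]:e["j"]] == 1L))) &&
      all(v[m_part$inter[[side]]] == 1L)
  }
  expected <- 0L
  for (a in seq_len(nrow(conf))) for (b in seq_len(nrow(conf)))
    if (ok(conf[a, ], m_part$intra_A, "i") && ok(conf[b, ], m_part$intra_B, "j"))
      expected <- expected + 1L
  expect_identical(nrow(ps), expected)
})

test_that("native dimer probability matches the 8-state closed form", {
  m <- toy_dimer(1, "interface-only", unit_entropy = 0, s_diss = 0,
                 epsilon = 1)  # epsilon overridden per evaluation
  # all 8 microstates degenerate at epsilon -> 0: product weight 1/8
  expect_equal(native_dimer_probability(m, epsilon = 1e-12), 0.125,
               tolerance = 1e-6)
  # closed form at arbitrary epsilon: P = x / (x + 3 + 4 d), x = exp(eps/RT)
  RT <- m$gas_constant * m$temperature
  for (eps in c(500, 2000, 8000)) {
    x <- exp(eps / RT)
    expect_equal(native_dimer_probability(m, eps), x / (x + 3 + 4),
                 tolerance = 1e-12)
  }
  # with a dissociation entropy: d = exp(s_diss / R) per dissociated state
  m87 <- toy_dimer(1, "interface-only", unit_entropy = 0, s_diss = 87,
                   epsilon = 1)
  d <- exp(87 / m87$gas_constant)
  x <- exp(3000 / RT)
  expect_equal(native_dimer_probability(m87, 3000), x / (x + 3 + 4 * d),
               tolerance = 1e-12)
})

test_that("native dimer probability is monotone in epsilon and in S_diss", {
  m <- toy_dimer(3, "hairpin")
  eps_grid <- seq(1000, 40000, length.out = 12)
  p <- vapply(eps_grid, function(e) native_dimer_probability(m, e), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_gt(native_dimer_probability(m, 1e5), 0.999)
  # larger S_diss stabilises the dissociated layer only
  p_sd <- vapply(c(0, 40, 87, 130), function(sd) {
    ms <- toy_dimer(3, "hairpin", s_diss = sd)
    native_dimer_probability(ms, 20000)
  }, numeric(1))
  expect_true(all(diff(p_sd) < 0))
})

test_that("epsilon calibration hits the analytic root and is idempotent", {
  m <- toy_dimer(1, "interface-only", unit_entropy = 0, s_diss = 87,
                 epsilon = 1)
  RT <- m$gas_constant * m$temperature
  d <- exp(87 / m$gas_constant)
  analytic <- RT * log(3 + 4 * d)        # P = 0.5  =>  x = 3 + 4 d
  eps <- calibrate_epsilon(m)
  expect_equal(eps, analytic, tolerance = 1e-5)
  expect_lt(abs(native_dimer_probability(m, eps) - 0.5), 1e-6)
  # monotonicity of the target
  expect_gt(calibrate_epsilon(m, target = 0.999), eps)
  expect_error(calibrate_epsilon(m, target = 1.5), "target")
  # a non-bracketing target reports the probabilities at both ends
  expect_error(calibrate_epsilon(m, target = 0.5, upper = 1), "sign change")
})
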