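test_that("tail coefficients satisfy the continuity identities", {
  p <- interaction_params()
  expect_equal(p$alpha * 2^(1 / 3) + p$beta, pi, tolerance = 1e-12)
  expect_equal(p$alpha * 2.25 + p$beta, 2 * pi, tolerance = 1e-12)
  expect_error(interaction_params(phi = -0.1))
})

test_that("pair potential and first derivative are continuous at both matching points", {
  h <- 1e-7
  for (phi in c(0, 0.6, 1.2, 1.5)) {
    p <- interaction_params(phi = phi)
    for (r0 in c(2^(1 / 6), 1.5)) {
      vl <- nonbonded_potential(r0 - h, p)
      vr <- nonbonded_potential(r0 + h, p)
      expect_lt(abs(vr - vl), 1e-6)   # value continuity (O(h) gap)
      dl <- (nonbonded_potential(r0 - h, p) -
               nonbonded_potential(r0 - 3 * h, p)) / (2 * h)
      dr <- (nonbonded_potential(r0 + 3 * h, p) -
               nonbonded_potential(r0 + h, p)) / (2 * h)
      expect_lt(abs(dr - dl), 1e-4)   # slope continuity at fd accuracy
    }
  }
})

test_that("pair potential takes its known values", {
  expect_equal(nonbonded_potential(2^(1 / 6), interaction_params(0)), 0)
  expect_equal(nonbonded_potential(2^(1 / 6), interaction_params(1.2)), -1.2)
  expect_equal(nonbonded_potential(1.5, interaction_params(1.5)), 0,
               tolerance = 1e-12)
  expect_equal(nonbonded_potential(2, interaction_params(1.5)), 0)
  # cosine tail at r = 1.2, phi = 1: frozen from symbolic evaluation
  expect_equal(nonbonded_potential(1.2, interaction_params(1)),
               -0.92057141, tolerance = 1e-7)
  # phi = 0 recovers pure WCA everywhere
  r <- seq(0.8, 2, by = 0.01)
  p0 <- interaction_params(0)
  wca <- ifelse(r <= 2^(1 / 6), 4 * (r^-12 - r^-6 + 0.25), 0)
  expect_equal(nonbonded_potential(r, p0), wca, tolerance = 1e-12)
})

test_that("FENE potential matches closed form and flags broken bonds", {
  p <- interaction_params()
  expect_equal(fene_potential(0, p), 0)
  expect_equal(fene_potential(0.95, p), -33.75 * log(1 - 0.95^2 / 2.25),
               tolerance = 1e-12)
  expect_equal(fene_potential(0.95, p), 17.3029, tolerance = 1e-4)
  expect_error(fene_potential(1.5, p), "broken bond")
  # monotone increasing
  r <- seq(0.05, 1.45, by = 0.05)
  expect_true(all(diff(fene_potential(r, p)) > 0))
})

test_that("bonded FENE+pair minimum sits near 0.96 sigma, independent of phi", {
  m0 <- bonded_pair_minimum(interaction_params(0))
  m15 <- bonded_pair_minimum(interaction_params(1.5))
  expect_equal(m0, 0.96, tolerance = 0.01)
  expect_equal(m0, m15, tolerance = 1e-5)
  # infinitely stiff spring limit pulls the minimum toward zero
  stiff <- bonded_pair_minimum(interaction_params(k_fene = 3e4))
  expect_lt(stiff, 0.8)
})

test_that("bending and wall potentials take their simple values", {
  p5 <- interaction_params(k_bend = 5)
  expect_equal(bending_potential(0, p5), 0)
  expect_equal(bending_potential(pi / 2, p5), 5)
  expect_equal(bending_potential(pi, p5), 10)
  expect_equal(wall_potential(2^(1 / 6)), 0)
  expect_equal(wall_potential(1), 1)
  expect_equal(wall_potential(2), 0)
  expect_error(wall_potential(-0.1), "outside cavity")
})

test_that("forces equal minus the numerical gradient of the oracle energy", {
  set.seed(7)
  ch <- build_linear_chain(10, semiflexible = TRUE)
  for (phi in c(0, 1.2)) {
    pars <- interaction_params(phi = phi, k_bend = 5)
    f <- total_forces(ch$frame, ch$topology, pars)
    g <- oracle_gradient(ch$frame$positions, ch$topology, pars)
    expect_lt(max(abs(f + g)), 1e-6)
    expect_equal(attr(f, "potential"),
                 oracle_energy(ch$frame$positions, ch$topology, pars),
                 tolerance = 1e-9)
    # net force on an isolated molecule vanishes
    expect_lt(max(abs(colSums(f))), 1e-9)
  }
})

test_that("cutoff and straight-trimer configurations give zero force", {
  top2 <- topology(2, matrix(0L, 0, 2))
  fr2 <- frame(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  f <- total_forces(fr2, top2, interaction_params(1.2))
  expect_equal(max(abs(f)), 0, tolerance = 1e-12)
  # straight semiflexible trimer: bending at its minimum
  top3 <- topology(3, rbind(c(1L, 2L), c(2L, 3L)),
                   angles = matrix(c(1L, 2L, 3L), 1))
  fr3 <- frame(cbind(c(0, 0.97, 1.94), 0, 0))
  pars <- interaction_params(0, k_bend = 5)
  f3 <- total_forces(fr3, top3, pars)
  f3_flex <- total_forces(fr3, top3, interaction_params(0))
  expect_equal(f3, f3_flex, tolerance = 1e-10)  # no bending contribution
})

test_that("observables have the right degenerate values", {
  d <- 1.7
  fr <- frame(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(radius_of_gyration(fr), d / 2)
  expect_equal(hydrodynamic_radius(fr), d)
  # symmetric shell: asphericity vanishes (octahedron vertices)
  oct <- frame(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  expect_equal(asphericity(oct), 0, tolerance = 1e-12)
  # rod limit: asphericity -> 1
  rod <- frame(cbind(seq_len(50), 0, 0))
  expect_gt(asphericity(rod), 0.95)
  expect_lte(asphericity(rod), 1)
})
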