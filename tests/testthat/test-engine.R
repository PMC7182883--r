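test_that("identical seed and inputs give a bit-identical trajectory", {
  ch <- local({set.seed(4); build_linear_chain(20)})
  pars <- interaction_params(1.2)
  lng <- langevin_params(seed = 99)
  t1 <- integrate_langevin(ch$frame, ch$topology, pars, lng, 2000)
  t2 <- integrate_langevin(ch$frame, ch$topology, pars, lng, 2000)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
  t3 <- integrate_langevin(ch$frame, ch$topology, pars,
                           langevin_params(seed = 100), 2000)
  expect_false(identical(t1$positions[[length(t1$positions)]],
                         t3$positions[[length(t3$positions)]]))
})

test_that("gamma = 0 integration conserves energy (NVE limit)", {
  top <- topology(2, matrix(c(1L, 2L), 1))
  # start at the bonded minimum with small thermal velocities
  r0 <- bonded_pair_minimum(interaction_params(1.2))
  fr <- frame(rbind(c(0, 0, 0), c(r0, 0, 0)),
              rbind(c(0.05, 0.08, 0), c(-0.05, 0, 0.03)))
  tr <- integrate_langevin(fr, top, interaction_params(1.2),
                           langevin_params(gamma = 0, seed = 1), 10000,
                           snapshot_steps = seq(0, 10000, by = 100))
  etot <- tr$pe + tr$ke
  expect_lt(max(abs(etot - etot[1])) / 2, 1e-3)
})

test_that("thermostat reproduces equipartition and free diffusion", {
  # beads start on a sparse grid: no overlaps, effectively ideal; the
  # run is long enough that the MSD fit window sits well past the
  # inertial crossover at 1/gamma = 20 tau, and the ensemble is large
  # because the origin-averaged slope has ~5% scatter per 150 beads
  g <- as.matrix(expand.grid(x = 0:6, y = 0:6, z = 0:6)) * 3
  top <- topology(nrow(g), matrix(0L, 0, 2))
  tr <- integrate_langevin(frame(g), top, interaction_params(),
                           langevin_params(seed = 11), 120000,
                           snapshot_steps = seq(0, 120000, by = 500))
  ke <- mean(tr$ke[tr$times > 50]) / nrow(g)
  expect_equal(ke, 1.5, tolerance = 0.02)
  d <- msd_and_diffusivity(tr)
  expect_equal(d$D, 20, tolerance = 0.06)
})

test_that("broken bonds and missing diffusive windows raise errors", {
  top <- topology(2, matrix(c(1L, 2L), 1))
  fr <- frame(rbind(c(0, 0, 0), c(1.49, 0, 0)),
              rbind(c(-3, 0, 0), c(3, 0, 0)))   # flying apart
  expect_error(
    integrate_langevin(fr, top, interaction_params(),
                       langevin_params(gamma = 0, seed = 1), 1000),
    "broken bond")
  short <- integrate_langevin(frame(matrix(0, 1, 3)),
                              topology(1, matrix(0L, 0, 2)),
                              interaction_params(), langevin_params(), 40,
                              snapshot_steps = seq(0, 40, by = 10))
  expect_error(msd_and_diffusivity(short), "too short")
})

test_that("dimer bond length samples the Boltzmann distribution of the bonded pair", {
  # independent oracle: 1-D Boltzmann average of r over the bonded
  # potential (Jacobian r^2), evaluated by quadrature
  pars <- interaction_params(0)
  vb <- function(r) vapply(r, function(ri) {
    fene_potential(ri, pars) + nonbonded_potential(ri, pars)
  }, numeric(1))
  num <- stats::integrate(function(r) r^3 * exp(-vb(r)), 0.5, 1.49)$value
  den <- stats::integrate(function(r) r^2 * exp(-vb(r)), 0.5, 1.49)$value
  r_mean_exact <- num / den
  top <- topology(2, matrix(c(1L, 2L), 1))
  fr <- frame(rbind(c(0, 0, 0), c(0.96, 0, 0)))
  tr <- integrate_langevin(fr, top, pars, langevin_params(seed = 21), 200000,
                           snapshot_steps = seq(1000, 200000, by = 200))
  rb <- vapply(tr$positions, function(p) {
    sqrt(sum((p[1, ] - p[2, ])^2))
  }, numeric(1))
  expect_equal(mean(rb), r_mean_exact, tolerance = 0.01)
})

test_that("quench to phi = 0 does not collapse the chain", {
  ch <- local({set.seed(9); build_linear_chain(60)})
  eq <- equilibrate_good_solvent(ch$topology, ch$frame,
                                 langevin_params(seed = 3),
                                 block_steps = 5000L, min_steps = 30000L)
  tr <- run_quench(eq$frame, ch$topology, quench_protocol(0),
                   langevin_params(seed = 4), t_max = 200,
                   stop_when_collapsed = FALSE)
  rg <- vapply(tr$positions, polycollapse:::rg_of_matrix, numeric(1))
  expect_gt(min(rg), 0.6 * eq$rg)   # stays swollen, fluctuating
  expect_lt(max(rg), 1.6 * eq$rg)
})

test_that("theta-point scan plumbing finds a synthetic transition and rejects bad grids", {
  expect_error(theta_from_rg_scan(rep(0, 6), rep(10, 6)), "increasing")
  expect_error(theta_from_rg_scan(seq(0, 1, by = 0.2), rep(10, 6)),
               "no transition")
  # synthetic Rg(phi) with a smooth collapse step centered at 0.6
  grid <- seq(0, 1.2, by = 0.15)
  rg <- 7 - 3 * tanh((grid - 0.6) / 0.1)
  est <- theta_from_rg_scan(grid, rg)
  expect_equal(est$phi_theta, 0.6, tolerance = 1e-12)
})

test_that("log-spaced schedules start at zero and end at the final step", {
  s <- log_schedule(1000, 0.005, per_decade = 20)
  expect_identical(s[1], 0L)
  expect_identical(s[length(s)], as.integer(1000 / 0.005))
  expect_true(all(diff(s) > 0))
  lt <- log10(s[s > 200] * 0.005)
  expect_equal(mean(diff(lt)), 1 / 20, tolerance = 0.3)
})
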