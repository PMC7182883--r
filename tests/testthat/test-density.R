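test_that("raw density counts monomers in spheres around cell centers", {
  fp <- field_params(r_c = 1.0, rho_min = 0.6)
  # one monomer placed exactly at a cell center of an explicit grid
  pos <- matrix(c(1.25, 1.25, 1.25), 1)
  fld <- local_density(pos, fp, origin = c(0, 0, 0), dims = c(5, 5, 5))
  expect_equal(fld$rho[3, 3, 3], 3 / (4 * pi), tolerance = 1e-12)
  # cells beyond r_c of the monomer are empty
  expect_equal(fld$rho[1, 1, 1], 0)
  expect_equal(sum(fld$rho > 0),
               sum(oracle_cell_density(pos, c(0, 0, 0), 0.5,
                                       c(5, 5, 5), 1.0) > 0))
})

test_that("cell counting matches the brute-force oracle on a random cloud", {
  set.seed(31)
  pos <- matrix(stats::runif(300, 0, 6), 100, 3)
  for (rc in c(1.0, 1.2)) {
    fp <- field_params(r_c = rc, rho_min = 0.3)
    fld <- local_density(pos, fp)
    oracle <- oracle_cell_density(pos, fld$origin, fld$delta, fld$dims, rc)
    expect_equal(fld$rho, oracle, tolerance = 1e-12)
  }
})

test_that("smoothing reproduces the face-neighbour stencil", {
  # uniform interior stays uniform (weights sum to 1)
  u <- array(3.7, c(6, 6, 6))
  su <- smooth_density(u)
  expect_equal(su[3, 3, 3], 3.7, tolerance = 1e-12)
  # single spike of 8: center 2, face neighbours 1, elsewhere 0
  z <- array(0, c(5, 5, 5)); z[3, 3, 3] <- 8
  sz <- smooth_density(z)
  expect_equal(sz[3, 3, 3], 2)
  expect_equal(sz[2, 3, 3], 1)
  expect_equal(sz[3, 4, 3], 1)
  expect_equal(sum(sz), 8)
  # random grid vs loop oracle
  set.seed(8)
  r <- array(stats::runif(4 * 5 * 6), c(4, 5, 6))
  expect_equal(smooth_density(r), oracle_smooth(r), tolerance = 1e-12)
})

test_that("classification is strict and flags empty masks", {
  fld <- list(rho_bar = array(0.6, c(3, 3, 3)),
              params = field_params(rho_min = 0.6))
  class(fld) <- "density_field"
  expect_warning(out <- classify_density(fld), "no filled cells")
  expect_identical(out$n_filled, 0L)   # rho_bar == rho_min is empty
  fld$rho_bar[2, 2, 2] <- 0.601
  out2 <- classify_density(fld)
  expect_identical(out2$n_filled, 1L)
})

test_that("filled mask is invariant under integer-cell translations", {
  set.seed(12)
  pos <- matrix(stats::rnorm(150, sd = 1.2), 50, 3)
  fp <- field_params(1.0, 0.2)
  f0 <- density_field(pos, fp)
  shift <- c(3, -2, 5) * fp$delta
  f1 <- density_field(sweep(pos, 2, shift, "+"), fp)
  expect_identical(dim(f0$filled), dim(f1$filled))
  expect_identical(f0$filled, f1$filled)
  expect_identical(f0$n_filled, f1$n_filled)
})

test_that("grids cover all particles with an empty margin on every face", {
  set.seed(13)
  pos <- matrix(stats::rnorm(90, sd = 2), 30, 3)
  fld <- density_field(pos, field_params(1.2, 0.3))
  m <- fld$filled
  d <- dim(m)
  expect_false(any(m[1, , ]) || any(m[d[1], , ]))
  expect_false(any(m[, 1, ]) || any(m[, d[2], ]))
  expect_false(any(m[, , 1]) || any(m[, , d[3]]))
  # all particles inside the grid
  rel <- sweep(pos, 2, fld$origin)
  expect_true(all(rel > 0))
  expect_true(all(rel < rep(d, each = nrow(pos)) * fld$delta))
})

test_that("dense and dilute fixtures classify as expected", {
  ball <- make_fixture("solid_ball", radius = 3, spacing = 0.5)
  fld <- density_field(ball$frame, field_params(1.0, 0.6))
  lab <- label_clusters(fld)
  expect_identical(attr(lab, "n_clusters"), 1L)
  # a dilute gas at the same threshold stays mostly empty
  gas <- make_fixture("random_gas", n = 50, side = 20, seed = 2)
  fldg <- suppressWarnings(density_field(gas$frame, field_params(1.0, 0.6)))
  expect_lt(fldg$n_filled, 10)
})
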