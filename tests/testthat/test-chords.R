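test_that("chord enumeration handles canonical masks exactly", {
  delta <- 0.5
  # single filled cell: one chord of length delta per axis
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(sort(enumerate_chords(m, delta)), rep(delta, 3))
  # solid 3x3x3 cube: 9 lines x 3 axes, all of length 3*delta
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  ch <- enumerate_chords(cube, delta)
  expect_length(ch, 27)
  expect_true(all(ch == 3 * delta))
  # two separated cubes: chord multiset is the union
  two <- array(FALSE, c(12, 5, 5))
  two[2:4, 2:4, 2:4] <- TRUE; two[8:10, 2:4, 2:4] <- TRUE
  expect_equal(sort(enumerate_chords(two, delta)),
               sort(c(ch, ch)))
  # empty mask: no chords
  expect_length(enumerate_chords(array(FALSE, c(3, 3, 3)), delta), 0)
})

test_that("chord enumeration matches the brute-force scanner on random masks", {
  for (s in 1:5) {
    m <- random_mask(c(14, 17, 12), p = 0.25 + 0.1 * (s %% 3), seed = s)
    expect_equal(sort(enumerate_chords(m, 0.5)),
                 sort(oracle_chords(m, 0.5)))
  }
  m20 <- random_mask(c(20, 20, 20), p = 0.45, seed = 99)
  expect_equal(sort(enumerate_chords(m20, 0.5)),
               sort(oracle_chords(m20, 0.5)))
})

test_that("chord distributions normalize and average correctly", {
  ball <- make_fixture("solid_ball", radius = 4, spacing = 0.5)
  cd <- chord_distribution(ball$frame, field_params(1.0, 0.6),
                           n_rotations = 3, seed = 2)
  expect_equal(sum(cd$p), 1, tolerance = 1e-12)
  expect_true(all(cd$L > 0))
  expect_equal(mean_chord(cd), cd$mean)
  # rotation robustness of a rotation-invariant body: mean chord stable
  cd2 <- chord_distribution(ball$frame, field_params(1.0, 0.6),
                            n_rotations = 3, seed = 77)
  expect_equal(cd$mean, cd2$mean, tolerance = 0.05)
})

test_that("relative domain size normalizes a synthetic ramp", {
  tt <- c(0, 10^seq(0, 3, length.out = 30))
  L <- c(2, 2 + 8 * pmin(tt[-1] / 100, 1))   # ramp 2 -> 10
  dg <- relative_domain_size(data.frame(time = tt, L = L))
  expect_equal(dg$curve$C[1], 0)
  expect_equal(dg$L0, 2)
  expect_equal(dg$Linf, 10, tolerance = 1e-6)
  expect_equal(utils::tail(dg$curve$C, 1), 1, tolerance = 1e-6)
  # tau_half where L crosses 6
  i <- which(L >= 6)[1]
  expect_gte(dg$tau_half, tt[i - 1]); expect_lte(dg$tau_half, tt[i])
  # degenerate normalization errors out
  expect_error(relative_domain_size(data.frame(time = tt,
                                               L = rep(2, length(tt)))),
               "degenerate")
})

test_that("power-law fitter is exact on noise-free data and warns on short windows", {
  d <- make_growth_series(0.56, noise = 0)
  d$C <- d$value / max(d$value) * 0.9
  fit <- fit_power_law(d, window = c(0.01, 0.5))
  expect_equal(fit$exponent, 0.56, tolerance = 1e-10)
  expect_equal(fit$se, 0, tolerance = 1e-8)
  expect_error(fit_power_law(d, window = c(0.889, 0.9)), "too few")
  short <- data.frame(time = c(10, 12, 15, 18), C = c(0.1, 0.12, 0.2, 0.3))
  expect_warning(fit_power_law(short, window = c(0.05, 0.5)),
                 "less than one decade")
})
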