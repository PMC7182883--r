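# build a tiny trajectory object around a list of position matrices
traj_from_positions <- function(poslist, times) {
  structure(list(times = times, positions = poslist,
                 velocities = lapply(poslist, function(p) p * 0),
                 pe = rep(NA_real_, length(times)),
                 ke = rep(NA_real_, length(times)),
                 phi = NA_real_, dt = 0.005, seed = 1L,
                 n_beads = nrow(poslist[[1]])),
            class = "trajectory")
}

test_that("a static configuration keeps Ps at its initial value", {
  ball <- make_fixture("solid_ball", radius = 3, spacing = 0.5)
  pos <- ball$frame$positions
  tr <- traj_from_positions(list(pos, pos, pos, pos),
                            c(0, 1, 10, 100))
  sp <- spin_autocorrelation(tr, field_params(1.0, 0.6))
  expect_equal(sp$series$Ps, rep(sp$Ps0, 4), tolerance = 1e-12)
  # Ps(0) = <S>(1-<S>) for a binary field, averaged over the bounding
  # region of the filled set
  fld <- density_field(sweep(pos, 2, colMeans(pos)), field_params(1.0, 0.6))
  idx <- which(fld$filled, arr.ind = TRUE)
  box <- fld$filled[min(idx[, 1]):max(idx[, 1]),
                    min(idx[, 2]):max(idx[, 2]),
                    min(idx[, 3]):max(idx[, 3])]
  p <- mean(box)
  expect_equal(sp$Ps0, p * (1 - p), tolerance = 1e-12)
})

test_that("independently resampled homogeneous configurations decorrelate", {
  # statistically homogeneous gas: independent draws share no structure,
  # so the cell-ensemble covariance vanishes (unlike centred clouds,
  # which stay correlated through their radial profile)
  mk <- function(s) {
    set.seed(s)
    matrix(stats::runif(1200, 0, 12), 400, 3)
  }
  tr <- traj_from_positions(lapply(1:6, mk), c(0, 1, 2, 4, 8, 16))
  sp <- spin_autocorrelation(tr, field_params(1.2, 0.15))
  # a small positive floor remains from the always-empty border cells of
  # the common region; decorrelation still means far below the static
  # value Ps0
  expect_lt(mean(abs(sp$series$Ps[-1])), 0.5 * sp$Ps0)
})

test_that("Ps is bounded by Ps(0) and mismatched schedules error", {
  ball <- make_fixture("solid_ball", radius = 3, spacing = 0.5)
  set.seed(9)
  poslist <- list(ball$frame$positions)
  for (k in 2:5) {
    poslist[[k]] <- poslist[[k - 1]] +
      matrix(stats::rnorm(3 * nrow(poslist[[1]]), sd = 0.3), ncol = 3)
  }
  tr <- traj_from_positions(poslist, c(0, 1, 2, 4, 8))
  sp <- spin_autocorrelation(tr, field_params(1.0, 0.6))
  expect_true(all(abs(sp$series$Ps) <= sp$Ps0 + 1e-12))
  tr2 <- traj_from_positions(poslist, c(0, 2, 3, 4, 8))
  expect_error(spin_autocorrelation(list(tr, tr2), field_params(1.0, 0.6)),
               "common snapshot schedule")
})

test_that("paired (L, Ps) relation yields a negative power-law slope on a shrinking-memory series", {
  # synthetic coarsening caricature: growing ball plus independent noise
  set.seed(10)
  poslist <- list(); LL <- numeric(0); tt <- c(0, 2^(0:6))
  base <- make_fixture("solid_ball", radius = 2.2, spacing = 0.5)$frame$positions
  for (k in seq_along(tt)) {
    jitter <- matrix(stats::rnorm(3 * nrow(base), sd = 0.12 * k), ncol = 3)
    poslist[[k]] <- (base + jitter) * (1 + 0.1 * k)
  }
  tr <- traj_from_positions(poslist, tt)
  dl <- domain_length_series(tr, field_params(1.0, 0.4), n_rotations = 1)
  sp <- spin_autocorrelation(tr, field_params(1.0, 0.4), L = dl)
  expect_true(is.data.frame(sp$pairs))
  if (!is.null(sp$L_exponent)) expect_lt(sp$L_exponent, 0)
})
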