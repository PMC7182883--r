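test_that("cluster labeling follows 6-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- m[3, 2, 2] <- TRUE       # face-adjacent pair
  lab <- label_clusters(m)
  expect_identical(attr(lab, "n_clusters"), 1L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[2, 2, 2] <- m2[3, 3, 2] <- TRUE     # edge diagonal: not connected
  expect_identical(attr(label_clusters(m2), "n_clusters"), 2L)
  expect_identical(attr(label_clusters(array(FALSE, c(3, 3, 3))),
                        "n_clusters"), 0L)
})

test_that("cluster partition equals the flood-fill oracle on random masks", {
  for (s in 1:4) {
    m <- random_mask(c(20, 20, 20), p = 0.2 + 0.15 * s, seed = 100 + s)
    lab <- label_clusters(m)
    oracle <- oracle_flood_fill(m)
    expect_identical(attr(lab, "n_clusters"), max(oracle))
    expect_true(same_partition(lab, oracle))
  }
})

test_that("cluster size and radius are exact for tiny clusters", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  st <- cluster_size_radius(label_clusters(m), delta = 0.5)
  expect_equal(st$clusters$n, 1)
  expect_equal(st$clusters$rg, 0)
  m[3, 2, 2] <- TRUE
  st2 <- cluster_size_radius(label_clusters(m), delta = 0.5)
  expect_equal(st2$clusters$n, 2)
  expect_equal(st2$clusters$rg, 0.25)    # delta/2
  expect_error(cluster_size_radius(label_clusters(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("compact lattice balls scale as Rclus ~ Nclus^(1/3)", {
  pts <- list()
  for (rad in 2:10) {
    m <- array(FALSE, c(25, 25, 25))
    ctr <- c(13, 13, 13)
    for (i in 1:25) for (j in 1:25) for (k in 1:25) {
      if (sum((c(i, j, k) - ctr)^2) <= rad^2) m[i, j, k] <- TRUE
    }
    st <- cluster_size_radius(label_clusters(m), delta = 1)
    pts[[length(pts) + 1]] <- c(st$clusters$n[1], st$clusters$rg[1])
  }
  pts <- do.call(rbind, pts)
  nu <- stats::coef(stats::lm(log(pts[, 2]) ~ log(pts[, 1])))[2]
  expect_equal(unname(nu), 1 / 3, tolerance = 0.02)
})

test_that("fractal fit recovers synthetic two-regime data", {
  set.seed(5)
  N <- 10^seq(0.5, 4, length.out = 80)
  R <- ifelse(N < 400, N^0.5, 400^0.5 * (N / 400)^0.25)
  ff <- fractal_fit(N, R)
  # breakpoint search has grid resolution; slopes recovered to ~1e-3
  expect_equal(ff$nu_small, 0.5, tolerance = 5e-3)
  expect_equal(ff$nu_large, 0.25, tolerance = 5e-3)
  expect_equal(ff$N_star, 400, tolerance = 0.25)
  # fixed-threshold variant on noise-free data is exact
  ff2 <- suppressWarnings(fractal_fit(N, R, N_star = 400))
  expect_equal(ff2$nu_small, 0.5, tolerance = 1e-6)
  expect_equal(ff2$nu_large, 0.25, tolerance = 0.01)
  # single-regime data flags
  ff3 <- suppressWarnings(fractal_fit(N[N < 300], R[N < 300], N_star = 400))
  expect_true(ff3$single_regime)
})

test_that("normalized growth recovers exact exponents and detects degeneracy", {
  tt <- 10^seq(-1, 2, length.out = 60)
  Nc <- 5 + 995 * pmin((tt / 50)^1.2, 1)
  Rc <- 1 + 19 * pmin((tt / 50)^0.6, 1)
  ser <- data.frame(time = c(0, tt), Nclus = c(5, Nc), Rclus = c(1, Rc))
  ng <- normalized_growth(ser, N_star = 400)
  expect_equal(ng$beta, 1.2, tolerance = 0.05)
  expect_equal(ng$gamma_growth, 0.6, tolerance = 0.05)
  expect_equal(ng$ratio, 0.5, tolerance = 0.05)
  bad <- data.frame(time = c(0, tt), Nclus = rep(7, 61), Rclus = c(1, Rc))
  expect_error(normalized_growth(bad), "degenerate")
})
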