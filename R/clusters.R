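#' Label clusters of filled cells
#'
#' Connected components of the filled mask under 6-connectivity (two
#' filled cells belong to the same cluster iff they differ by one cell
#' along exactly one axis; diagonals do not connect). Labels are assigned
#' deterministically in cell-discovery order.
#'
#' @param mask logical 3-D array or a `density_field` with `filled`.
#' @return integer array of the same shape, 0 for empty cells, with
#'   attribute `n_clusters`.
#' @export
label_clusters <- function(mask) {
  if (inherits(mask, "density_field")) mask <- mask$filled
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  lab <- cpp_label_clusters(mask, dim(mask))
  nc <- attr(lab, "n_clusters")
  dim(lab) <- dim(mask)
  attr(lab, "n_clusters") <- nc
  lab
}

#' Per-cluster population and radius
#'
#' For every cluster: the population `Nclus` (number of cells) and the
#' radius of gyration over the cell centers with unit weight per cell.
#' The mean population is the unweighted average over clusters and the
#' mean radius is the root mean square `<Rg^2>^(1/2)` over clusters; set
#' `mass_weighted = TRUE` to weight each cluster by its population.
#'
#' @param labels integer label array from [label_clusters()].
#' @param delta cell side in sigma.
#' @param mass_weighted weight cluster averages by population?
#' @return list: data.frame `clusters` (label, n, rg), `n_clusters`,
#'   `mean_n`, `mean_r`.
#' @export
cluster_size_radius <- function(labels, delta = 0.5, mass_weighted = FALSE) {
  d <- dim(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) stop("no clusters: empty mask")
  lab <- labels[idx]
  ix <- (idx - 1) %% d[1]
  iy <- ((idx - 1) %/% d[1]) %% d[2]
  iz <- (idx - 1) %/% (d[1] * d[2])
  cx <- (ix + 0.5) * delta; cy <- (iy + 0.5) * delta; cz <- (iz + 0.5) * delta
  n <- as.vector(rowsum(rep(1, length(lab)), lab))
  mx <- as.vector(rowsum(cx, lab)) / n
  my <- as.vector(rowsum(cy, lab)) / n
  mz <- as.vector(rowsum(cz, lab)) / n
  s2 <- as.vector(rowsum(cx^2 + cy^2 + cz^2, lab)) / n -
    (mx^2 + my^2 + mz^2)
  s2[s2 < 0] <- 0
  clusters <- data.frame(label = sort(unique(lab)), n = n, rg = sqrt(s2))
  w <- if (mass_weighted) clusters$n else rep(1, nrow(clusters))
  list(clusters = clusters, n_clusters = nrow(clusters),
       mean_n = sum(w * clusters$n) / sum(w),
       mean_r = sqrt(sum(w * clusters$rg^2) / sum(w)))
}

#' Cluster statistics along a quench trajectory
#'
#' Builds the density field for every snapshot and records the mean
#' cluster population `Nclus(t)` and mean radius `Rclus(t)`; substitution
#' of time gives the fractal relation Rclus(Nclus).
#'
#' @param trajectories a trajectory or list of trajectories with matching
#'   snapshot times (realizations are averaged per time).
#' @param params a [field_params()].
#' @return data.frame: `time`, `Nclus`, `Rclus`, `n_clusters`.
#' @export
cluster_series <- function(trajectories, params = field_params()) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  times <- common_times(trajectories)
  out <- lapply(seq_along(times), function(i) {
    per <- vapply(trajectories, function(tr) {
      fld <- density_field(tr$positions[[i]], params)
      if (fld$n_filled == 0) return(c(NA_real_, NA_real_, 0))
      st <- cluster_size_radius(label_clusters(fld), params$delta)
      c(st$mean_n, st$mean_r, st$n_clusters)
    }, numeric(3))
    data.frame(time = times[i], Nclus = mean(per[1, ], na.rm = TRUE),
               Rclus = mean(per[2, ], na.rm = TRUE),
               n_clusters = mean(per[3, ]))
  })
  do.call(rbind, out)
}

#' Fractal scaling of clusters: Rclus ~ Nclus^nu
#'
#' Fits the two power-law regimes of the cluster radius versus population
#' relation. Small clusters are approximately Gaussian (`nu ~ 0.5`); the
#' large compact clusters of the late coarsening give `nu ~ 0.25`, with a
#' crossover population `N* ~ 400` cells. With `N_star = NULL` the
#' breakpoint of a continuous two-segment log-log fit is located by 1-D
#' search; otherwise the two slopes are fitted on either side of the
#' supplied threshold.
#'
#' @param Nclus,Rclus paired mean population / mean radius values (pooled
#'   over time and realizations).
#' @param N_star fixed crossover, or NULL to fit it.
#' @return list: `nu_small`, `nu_large`, `N_star`, `se_small`, `se_large`,
#'   `single_regime` flag.
#' @export
fractal_fit <- function(Nclus, Rclus, N_star = NULL) {
  ok <- is.finite(Nclus) & is.finite(Rclus) & Nclus > 0 & Rclus > 0
  x <- log(Nclus[ok]); y <- log(Rclus[ok])
  if (length(x) < 4) stop("too few cluster points for a fractal fit")
  slope <- function(sel) {
    if (sum(sel) < 3) return(c(NA_real_, NA_real_))
    f <- stats::lm(y[sel] ~ x[sel])
    c(unname(stats::coef(f)[2]), summary(f)$coefficients[2, 2])
  }
  if (is.null(N_star)) {
    # continuous two-segment fit, breakpoint by grid search
    cand <- stats::quantile(x, seq(0.15, 0.85, by = 0.05), names = FALSE)
    rss <- vapply(cand, function(bp) {
      z <- pmax(x - bp, 0)
      sum(stats::resid(stats::lm(y ~ x + z))^2)
    }, numeric(1))
    bp <- cand[which.min(rss)]
    z <- pmax(x - bp, 0)
    f <- stats::lm(y ~ x + z)
    co <- stats::coef(f)
    sm <- summary(f)$coefficients
    return(list(nu_small = unname(co[2]),
                nu_large = unname(co[2] + co[3]),
                N_star = exp(bp),
                se_small = sm[2, 2],
                se_large = sqrt(sm[2, 2]^2 + sm[3, 2]^2),
                single_regime = FALSE))
  }
  lo <- slope(x < log(N_star))
  hi <- slope(x > log(N_star))
  single <- any(is.na(c(lo[1], hi[1])))
  list(nu_small = lo[1], nu_large = hi[1], N_star = N_star,
       se_small = lo[2], se_large = hi[2], single_regime = single)
}

#' Normalized cluster growth n(t), r(t) and their exponents
#'
#' `n(t) = (Nclus(t) - Nclus(0)) / (Nclus(Inf) - Nclus(0))` and the
#' analogous r(t) for the radius; both grow from 0 to ~1 (microgels
#' overshoot before saturating). Power laws `n ~ t^beta` and `r ~ t^gamma`
#' are fitted over the pre-crossover window (times with mean cluster
#' population below `N_star`); `gamma / beta` reflects the small-cluster
#' fractal exponent (~0.5).
#'
#' @param series data.frame from [cluster_series()].
#' @param N_star crossover population bounding the fit window (~400).
#' @return list: `curve` (time, n, r), `beta`, `gamma_growth`, `ratio`,
#'   plus standard errors.
#' @export
normalized_growth <- function(series, N_star = 400) {
  stopifnot(all(c("time", "Nclus", "Rclus") %in% names(series)))
  series <- series[is.finite(series$Nclus) & is.finite(series$Rclus), ]
  series <- series[order(series$time), ]
  tmax <- max(series$time)
  plateau <- series$time >= tmax / sqrt(10)
  N0 <- series$Nclus[1]; Ninf <- mean(series$Nclus[plateau])
  R0 <- series$Rclus[1]; Rinf <- mean(series$Rclus[plateau])
  if (abs(Ninf - N0) < .Machine$double.eps^0.5) {
    stop("degenerate normalization: Nclus(Inf) = Nclus(0)")
  }
  n <- (series$Nclus - N0) / (Ninf - N0)
  r <- (series$Rclus - R0) / (Rinf - R0)
  curve <- data.frame(time = series$time, n = n, r = r,
                      Nclus = series$Nclus)
  # both exponents fitted over the same pre-crossover times; require the
  # population to sit clearly above its initial level (noise floor)
  pre <- curve[curve$time > 0 & curve$Nclus < N_star &
                 curve$Nclus >= 1.5 * N0 + 2 &
                 curve$n > 0 & curve$r > 0, ]
  fit_n <- fit_power_law(pre, window = c(0, Inf), value = "n")
  fit_r <- fit_power_law(pre, window = c(0, Inf), value = "r")
  list(curve = curve, beta = fit_n$exponent, beta_se = fit_n$se,
       gamma_growth = fit_r$exponent, gamma_se = fit_r$se,
       ratio = fit_r$exponent / fit_n$exponent,
       N0 = N0, Ninf = Ninf, R0 = R0, Rinf = Rinf)
}
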