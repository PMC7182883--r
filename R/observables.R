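rg_of_matrix <- function(pos) {
  cm <- colMeans(pos)
  sqrt(mean((pos[, 1] - cm[1])^2 + (pos[, 2] - cm[2])^2 +
              (pos[, 3] - cm[3])^2))
}

#' Radius of gyration
#' @param frame a [frame()] (or bare n x 3 matrix).
#' @return Rg in sigma.
#' @export
radius_of_gyration <- function(frame) {
  pos <- if (inherits(frame, "frame")) frame$positions else as.matrix(frame)
  rg_of_matrix(pos)
}

#' Hydrodynamic radius
#'
#' `Rh = <r_ij^-1>^-1`, the inverse of the mean inverse distance over all
#' bead pairs (Kirkwood estimate).
#'
#' @param frame a [frame()] (or n x 3 matrix) with at least 2 beads.
#' @return Rh in sigma.
#' @export
hydrodynamic_radius <- function(frame) {
  pos <- if (inherits(frame, "frame")) frame$positions else as.matrix(frame)
  stopifnot(nrow(pos) >= 2)
  1 / mean(1 / stats::dist(pos))
}

#' Asphericity of the mass distribution
#'
#' `a = 3/2 * sum_i (lambda_i - lambda_bar)^2 / (sum_i lambda_i)^2` from
#' the gyration-tensor eigenvalues; 0 for spherically symmetric objects,
#' 1 for a rod. Swollen disordered microgels typically sit at 0.02-0.14.
#'
#' @param frame a [frame()] (or n x 3 matrix).
#' @return dimensionless asphericity in `[0, 1]`.
#' @export
asphericity <- function(frame) {
  pos <- if (inherits(frame, "frame")) frame$positions else as.matrix(frame)
  q <- sweep(pos, 2, colMeans(pos))
  g <- crossprod(q) / nrow(q)
  lam <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  1.5 * sum((lam - mean(lam))^2) / sum(lam)^2
}

#' Mean-squared displacement and diffusivity
#'
#' Bead-averaged MSD `<dr^2(t)> = mean_i |r_i(t) - r_i(0)|^2`; when the
#' snapshots are uniformly spaced the average additionally runs over all
#' time origins. The diffusion coefficient `D = <dr^2>/(6 t)` comes from
#' the least-squares slope over the diffusive lag window `fit_range`
#' (fractions of the maximum lag, chosen past the inertial crossover at
#' `t ~ 1/gamma` but short enough to keep origin statistics). For a free
#' Langevin bead `D = kT/(m gamma)` (= 20 at the default parameters).
#'
#' @param trajectory a trajectory from [integrate_langevin()].
#' @param fit_range lag window for the linear fit, as fractions of the
#'   maximum lag.
#' @return list: `lag`, `msd`, `D`, `fit` (the lm object).
#' @export
msd_and_diffusivity <- function(trajectory, fit_range = c(0.1, 0.4)) {
  stopifnot(inherits(trajectory, "trajectory"))
  tt <- trajectory$times
  S <- length(tt)
  if (S < 10) stop("trajectory too short to define a diffusive window")
  dts <- diff(tt)
  uniform <- diff(range(dts)) < 1e-9 * max(dts)
  if (uniform) {
    # multiple-time-origin average at each lag index
    lag <- dts[1] * seq_len(S - 1)
    msd <- vapply(seq_len(S - 1), function(k) {
      o <- seq_len(S - k)
      mean(vapply(o, function(i) {
        mean(rowSums((trajectory$positions[[i + k]] -
                        trajectory$positions[[i]])^2))
      }, numeric(1)))
    }, numeric(1))
  } else {
    ref <- trajectory$positions[[1]]
    lag <- tt[-1] - tt[1]
    msd <- vapply(trajectory$positions[-1], function(p) {
      mean(rowSums((p - ref)^2))
    }, numeric(1))
  }
  sel <- lag >= fit_range[1] * max(lag) & lag <= fit_range[2] * max(lag)
  if (sum(sel) < 5) {
    stop("trajectory too short to define a diffusive window")
  }
  fit <- stats::lm(msd[sel] ~ lag[sel])
  list(lag = lag, msd = msd, D = unname(stats::coef(fit)[2]) / 6, fit = fit)
}

#' Per-configuration observables
#'
#' Convenience bundle of Rg, Rh and asphericity for one frame.
#' @param frame a [frame()].
#' @return list with `rg`, `rh`, `asphericity`.
#' @export
observables <- function(frame) {
  list(rg = radius_of_gyration(frame),
       rh = hydrodynamic_radius(frame),
       asphericity = asphericity(frame))
}
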