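#' Non-bonded pair potential with tunable attractive tail
#'
#' Shifted-truncated Lennard-Jones (WCA) core offset by `-epsilon*phi` for
#' `r <= 2^(1/6) sigma`, a cosine attractive tail
#' `phi*epsilon/2 * (cos(alpha (r/sigma)^2 + beta) - 1)` up to the cutoff
#' `1.5 sigma`, and zero beyond. Value and first derivative are continuous
#' at both matching points for any `phi`; `phi = 0` recovers pure WCA.
#'
#' @param r pair distance(s) in sigma; must be positive.
#' @param params an [interaction_params()] object.
#' @return potential energy in epsilon (vectorized over `r`).
#' @export
nonbonded_potential <- function(r, params) {
  stopifnot(inherits(params, "interaction_params"), all(r > 0))
  s <- params$sigma
  eps <- params$epsilon
  rs <- r / s
  out <- numeric(length(r))
  core <- rs <= 2^(1 / 6)
  tail <- !core & rs <= params$r_cut
  if (any(core)) {
    sr6 <- rs[core]^-6
    out[core] <- 4 * eps * (sr6^2 - sr6 + 0.25) - eps * params$phi
  }
  if (any(tail)) {
    out[tail] <- 0.5 * params$phi * eps *
      (cos(params$alpha * rs[tail]^2 + params$beta) - 1)
  }
  out
}

#' FENE bond potential
#'
#' `-epsilon * K * R0^2 / 2 * log(1 - (r / (R0 sigma))^2)`; diverges as the
#' bond approaches its maximum elongation `R0 sigma`.
#'
#' @param r bond length(s) in sigma, `0 <= r < R0 sigma`.
#' @param params an [interaction_params()] object.
#' @return potential energy in epsilon.
#' @export
fene_potential <- function(r, params) {
  stopifnot(inherits(params, "interaction_params"), all(r >= 0))
  rmax <- params$r0_fene * params$sigma
  if (any(r >= rmax)) {
    stop("broken bond: length ", max(r), " >= FENE maximum elongation ", rmax)
  }
  -0.5 * params$epsilon * params$k_fene * params$r0_fene^2 *
    log(1 - (r / rmax)^2)
}

#' Worm-like bending potential
#'
#' `Ks * (1 - cos(theta))` where `theta` is the angle between two successive
#' bond vectors (0 for a straight continuation).
#'
#' @param theta bending angle(s) in radians, in `[0, pi]`.
#' @param params an [interaction_params()] object.
#' @return potential energy in epsilon.
#' @export
bending_potential <- function(theta, params) {
  stopifnot(inherits(params, "interaction_params"),
            all(theta >= 0), all(theta <= pi + 1e-12))
  params$k_bend * (1 - cos(theta))
}

#' Confining spherical wall potential
#'
#' Purely repulsive shifted-truncated LJ acting on the distance
#' `rw = R_cav - |r - center|` from a bead to the spherical wall surface;
#' zero beyond `2^(1/6) sigma`. Used to confine chains during microgel
#' synthesis.
#'
#' @param rw distance(s) to the wall surface in sigma; must be positive
#'   (a non-positive value means the bead has escaped the cavity).
#' @param params an [interaction_params()] object (only epsilon/sigma used).
#' @return potential energy in epsilon.
#' @export
wall_potential <- function(rw, params = interaction_params()) {
  if (any(rw <= 0)) stop("bead outside cavity: wall distance <= 0")
  rs <- rw / params$sigma
  out <- numeric(length(rw))
  act <- rs <= 2^(1 / 6)
  if (any(act)) {
    sr6 <- rs[act]^-6
    out[act] <- 4 * params$epsilon * (sr6^2 - sr6 + 0.25)
  }
  out
}

#' Location of the bonded-pair minimum
#'
#' Bonded neighbours feel the sum of the FENE spring and the non-bonded
#' pair potential (Kremer-Grest convention); the sum has a deep minimum
#' near `r ~ 0.96 sigma` which enforces chain uncrossability. Located by
#' bracketed 1-D minimization.
#'
#' @param params an [interaction_params()] object.
#' @param tol optimization tolerance on r.
#' @return the distance (sigma) minimizing the total bonded interaction.
#' @export
bonded_pair_minimum <- function(params = interaction_params(), tol = 1e-6) {
  f <- function(r) fene_potential(r, params) + nonbonded_potential(r, params)
  stats::optimize(f, c(0.5, params$r0_fene * params$sigma - 1e-8),
                  tol = tol)$minimum
}
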