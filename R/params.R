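#' Interaction parameters in reduced units
#'
#' Collects the parameters of the bead-spring force field: the modified
#' WCA pair potential with a solvophobic attractive tail of depth
#' `epsilon * phi`, the FENE bond potential, and the worm-like bending term.
#' All quantities are in reduced units (`epsilon = sigma = m = tau = 1`).
#'
#' The tail coefficients `alpha = pi / (2.25 - 2^(1/3))` and
#' `beta = 2*pi - 2.25*alpha` make the pair potential and its first
#' derivative continuous both at the WCA minimum `2^(1/6) sigma` and at the
#' non-bonded cutoff `1.5 sigma`.
#'
#' @param phi solvent-quality parameter (>= 0). `phi = 0` is athermal good
#'   solvent (pure WCA); larger values deepen the attractive tail and act as
#'   an effective inverse temperature. The collapse (theta) point of long
#'   flexible chains sits near `phi ~ 0.6`.
#' @param epsilon,sigma energy and length units (reduced; keep at 1).
#' @param k_fene FENE spring constant (30).
#' @param r0_fene FENE maximum elongation in units of sigma (1.5).
#' @param k_bend bending strength of the worm-like term `Ks (1 - cos theta)`;
#'   0 for fully flexible strands, 5 for the semiflexible chains.
#' @param r_cut non-bonded cutoff (1.5 sigma).
#' @return an object of class `interaction_params`.
#' @examples
#' p <- interaction_params(phi = 1.2)
#' nonbonded_potential(2^(1/6), p)  # -phi at the WCA minimum
#' @export
interaction_params <- function(phi = 0, epsilon = 1, sigma = 1,
                               k_fene = 30, r0_fene = 1.5,
                               k_bend = 0, r_cut = 1.5) {
  stopifnot(is.numeric(phi), length(phi) == 1L, phi >= 0,
            epsilon > 0, sigma > 0, k_fene > 0, r0_fene > 0,
            k_bend >= 0, r_cut > 0)
  alpha <- pi / (2.25 - 2^(1 / 3))
  beta <- 2 * pi - 2.25 * alpha
  structure(list(phi = phi, epsilon = epsilon, sigma = sigma,
                 alpha = alpha, beta = beta, r_cut = r_cut,
                 k_fene = k_fene, r0_fene = r0_fene, k_bend = k_bend),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Bead-spring interaction parameters (reduced units)\n")
  cat(sprintf("  solvent quality phi = %g  (theta-point ~ 0.6)\n", x$phi))
  cat(sprintf("  FENE: K = %g, R0 = %g; bending Ks = %g; cutoff = %g\n",
              x$k_fene, x$r0_fene, x$k_bend, x$r_cut))
  invisible(x)
}

#' Langevin thermostat parameters
#'
#' @param kT thermal energy (1.0).
#' @param gamma friction coefficient in 1/tau (0.05): high enough for good
#'   thermalization, low enough not to overdamp the collapse dynamics.
#' @param dt integration time step in tau (0.005).
#' @param seed integer RNG seed recorded with every trajectory.
#' @return an object of class `langevin_params`.
#' @export
langevin_params <- function(kT = 1, gamma = 0.05, dt = 0.005, seed = 1L) {
  stopifnot(kT >= 0, gamma >= 0, dt > 0)
  structure(list(kT = kT, gamma = gamma, dt = dt, seed = as.integer(seed)),
            class = "langevin_params")
}

#' @export
print.langevin_params <- function(x, ...) {
  cat(sprintf("Langevin parameters: kT = %g, gamma = %g/tau, dt = %g tau, seed = %d\n",
              x$kT, x$gamma, x$dt, x$seed))
  invisible(x)
}

#' Instantaneous quench protocol
#'
#' Describes a quench from good solvent (`phi_initial`, normally 0) to bad
#' solvent (`phi_target`, beyond the theta point ~0.6) performed in a single
#' integration step; the time origin `t = 0` is the quench instant.
#'
#' @param phi_target target solvent-quality parameter (e.g. 1.2 or 1.5).
#' @param phi_initial initial value (default 0, good solvent).
#' @return an object of class `quench_protocol`.
#' @export
quench_protocol <- function(phi_target, phi_initial = 0) {
  stopifnot(phi_target >= 0, phi_initial >= 0)
  structure(list(phi_initial = phi_initial, phi_target = phi_target,
                 quench_mode = "instantaneous", t0 = 0),
            class = "quench_protocol")
}

#' Density-field construction parameters
#'
#' @param delta cubic cell side in sigma (default 0.5).
#' @param r_c radius of the density-counting sphere in sigma; canonical
#'   values are 1.0 and 1.2.
#' @param rho_min fill threshold on the smoothed density; canonical pairs
#'   are (r_c = 1.0, rho_min = 0.6) and (r_c = 1.2, rho_min = 0.3 or 0.35).
#' @return an object of class `field_params`.
#' @export
field_params <- function(r_c = 1.0, rho_min = 0.6, delta = 0.5) {
  stopifnot(delta > 0, r_c >= delta, rho_min > 0)
  structure(list(delta = delta, r_c = r_c, rho_min = rho_min),
            class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("Density field: delta = %g, r_c = %g, rho_min = %g\n",
              x$delta, x$r_c, x$rho_min))
  invisible(x)
}
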