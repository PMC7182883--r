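as_int_matrix <- function(m, ncol) {
  if (is.null(m) || nrow(m) == 0) return(matrix(0L, 0, ncol))
  matrix(as.integer(m), ncol = ncol)
}

as_restraints <- function(r) {
  if (is.null(r)) return(matrix(0, 0, 4))
  matrix(as.numeric(r), ncol = 4)
}

#' Total forces on every bead
#'
#' Minus the gradient of the total potential: non-bonded pairs within the
#' 1.5 sigma cutoff (bonded pairs included, Kremer-Grest convention), FENE
#' bonds, bending triples and, when `wall` is given, the confining cavity.
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param params an [interaction_params()].
#' @param wall optional list `list(center = c(x,y,z), radius = R)`.
#' @param restraints optional numeric matrix with columns (i, j, k, r0) of
#'   temporary harmonic pair restraints.
#' @return n x 3 matrix of forces with attribute `"potential"` holding the
#'   total potential energy.
#' @export
total_forces <- function(frame, topology, params, wall = NULL,
                         restraints = NULL) {
  stopifnot(inherits(frame, "frame"), inherits(topology, "topology"),
            inherits(params, "interaction_params"))
  res <- cpp_forces(frame$positions,
                    as_int_matrix(topology$bonds, 2),
                    as_int_matrix(topology$angles, 3),
                    as_restraints(restraints),
                    params$phi, params$k_fene, params$r0_fene, params$k_bend,
                    !is.null(wall),
                    if (is.null(wall)) c(0, 0, 0) else wall$center,
                    if (is.null(wall)) 0 else wall$radius)
  f <- res$forces
  attr(f, "potential") <- res$potential
  f
}

#' Log-spaced snapshot schedule
#'
#' Step indices approximately log-spaced between `t_min` and `t_max`
#' (about `per_decade` points per decade), always including step 0 and the
#' final step. All analyses of the coarsening are log-time power laws, so
#' this is the natural sampling.
#'
#' @param t_max final time; @param dt time step; @param per_decade points
#'   per decade; @param t_min first positive snapshot time.
#' @return sorted integer vector of step indices.
#' @export
log_schedule <- function(t_max, dt, per_decade = 20, t_min = 1) {
  stopifnot(t_max > t_min, t_min > 0)
  tt <- 10^seq(log10(t_min), log10(t_max),
               length.out = max(2, ceiling(per_decade *
                                             log10(t_max / t_min)) + 1))
  steps <- unique(c(0L, pmax(1L, as.integer(round(tt / dt))),
                    as.integer(round(t_max / dt))))
  sort(steps)
}

#' Integrate the Langevin equations of motion
#'
#' Advances the system with the Gronbech-Jensen-Farago discretization of
#' the Langevin equation at `kT`, friction `gamma` and step `dt`; for
#' `gamma = 0` the scheme reduces to symplectic velocity Verlet (NVE).
#' A broken FENE bond (r >= R0 sigma) or a non-finite coordinate aborts
#' with the offending step in the message.
#'
#' @param frame starting [frame()].
#' @param topology a [topology()].
#' @param params an [interaction_params()].
#' @param langevin a [langevin_params()].
#' @param n_steps number of integration steps.
#' @param snapshot_steps integer step indices at which to record snapshots
#'   (defaults to ~100 evenly spaced).
#' @param wall,restraints as in [total_forces()].
#' @param seed RNG seed set before integrating; `NULL` continues the
#'   current RNG stream (used when chaining segments).
#' @return a `trajectory`: times, list of position/velocity matrices, and
#'   per-snapshot potential and kinetic energies.
#' @export
integrate_langevin <- function(frame, topology, params, langevin,
                               n_steps, snapshot_steps = NULL,
                               wall = NULL, restraints = NULL,
                               seed = langevin$seed) {
  stopifnot(inherits(frame, "frame"), inherits(topology, "topology"))
  if (is.null(snapshot_steps)) {
    snapshot_steps <- unique(c(0L, as.integer(
      round(seq(0, n_steps, length.out = min(101, n_steps + 1))))))
  }
  snapshot_steps <- sort(unique(as.integer(snapshot_steps)))
  stopifnot(all(snapshot_steps >= 0), max(snapshot_steps) <= n_steps)
  if (max(snapshot_steps) < n_steps) {
    snapshot_steps <- c(snapshot_steps, as.integer(n_steps))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_langevin(frame$positions, frame$velocities,
                          as_int_matrix(topology$bonds, 2),
                          as_int_matrix(topology$angles, 3),
                          as_restraints(restraints),
                          params$phi, params$k_fene, params$r0_fene,
                          params$k_bend,
                          !is.null(wall),
                          if (is.null(wall)) c(0, 0, 0) else wall$center,
                          if (is.null(wall)) 0 else wall$radius,
                          langevin$kT, langevin$gamma, langevin$dt,
                          snapshot_steps, frame$time)
  structure(list(times = res$times, positions = res$positions,
                 velocities = res$velocities, pe = res$pe, ke = res$ke,
                 phi = params$phi, dt = langevin$dt,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 n_beads = nrow(frame$positions)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d beads, %d snapshots, t in [%g, %g], phi = %g\n",
              x$n_beads, length(x$times), min(x$times), max(x$times), x$phi))
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param trajectory a trajectory; @param i snapshot index (default last).
#' @return a [frame()].
#' @export
trajectory_frame <- function(trajectory, i = length(trajectory$times)) {
  frame(trajectory$positions[[i]], trajectory$velocities[[i]],
        time = trajectory$times[i])
}

#' Equilibrate in good solvent
#'
#' Runs blocks of Langevin dynamics at `phi = 0` until the radius-of-
#' gyration time series is stationary: after discarding the first third,
#' the first- and second-half means must agree within twice their combined
#' block standard errors (and a minimum number of blocks must have run).
#'
#' @param topology,frame system to equilibrate.
#' @param langevin a [langevin_params()]; its seed starts the RNG.
#' @param params an [interaction_params()]; `phi` is forced to 0.
#' @param block_steps integration steps per block.
#' @param min_blocks,max_blocks convergence window and budget.
#' @param min_steps minimum total steps before the stationarity test may
#'   end the run; defaults to one Rouse time `gamma N^2 b^2/(3 pi^2 kT)`
#'   (in steps), the slowest conformational relaxation of a free chain.
#' @param wall optional confining cavity (microgel synthesis).
#' @return list: `frame` (final), `rg` (mean), `rg_se` (block standard
#'   error), `rg_series`, `times`, `converged`.
#' @export
equilibrate_good_solvent <- function(topology, frame, langevin,
                                     params = interaction_params(),
                                     block_steps = 20000L,
                                     min_blocks = 6L, max_blocks = 40L,
                                     min_steps = NULL, wall = NULL) {
  params$phi <- 0
  set.seed(langevin$seed)
  if (is.null(min_steps)) {
    # networks relax on the strand scale, not N^2; cap the default
    min_steps <- min(400000, ceiling(langevin$gamma * topology$n_beads^2 /
                                       (3 * pi^2 * langevin$kT) /
                                       langevin$dt))
  }
  min_blocks <- max(min_blocks, ceiling(min_steps / block_steps))
  rg_series <- numeric(0)
  tt <- numeric(0)
  cur <- frame
  converged <- FALSE
  for (blk in seq_len(max_blocks)) {
    traj <- integrate_langevin(cur, topology, params, langevin, block_steps,
                               snapshot_steps = seq(0L, block_steps,
                                                    by = block_steps %/% 10L),
                               wall = wall, seed = NULL)
    cur <- trajectory_frame(traj)
    keep <- -1L   # drop the snapshot duplicating the previous block end
    rg_series <- c(rg_series, vapply(traj$positions[keep], rg_of_matrix,
                                     numeric(1)))
    tt <- c(tt, traj$times[keep])
    if (blk >= min_blocks) {
      s <- rg_series[-seq_len(length(rg_series) %/% 3)]
      h <- length(s) %/% 2
      m1 <- mean(s[seq_len(h)]); m2 <- mean(s[(h + 1):length(s)])
      se <- sqrt(stats::var(s[seq_len(h)]) / h +
                   stats::var(s[(h + 1):length(s)]) / h)
      if (is.finite(se) && abs(m1 - m2) <= 2 * se) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warning("equilibration did not reach stationarity within budget; ",
            "returning best frame")
  }
  tail_s <- rg_series[-seq_len(length(rg_series) %/% 3)]
  nb <- max(2L, length(tail_s) %/% 10L)
  blocks <- split(tail_s, cut(seq_along(tail_s), nb))
  bm <- vapply(blocks, mean, numeric(1))
  cur$time <- 0
  list(frame = cur, rg = mean(tail_s),
       rg_se = stats::sd(bm) / sqrt(length(bm)),
       rg_series = rg_series, times = tt, converged = converged)
}

#' Quench to bad solvent and follow the collapse
#'
#' Switches `phi` to the protocol target in a single step (instantaneous
#' quench, t = 0 at the switch) and integrates with snapshots on a
#' log-spaced schedule until `t_max`. With `stop_when_collapsed = TRUE`
#' the run ends early once the radius of gyration has drifted by less than
#' `rg_drift_tol` over the trailing decade of log-time (collapsed plateau).
#'
#' @param frame equilibrated good-solvent configuration.
#' @param topology a [topology()].
#' @param protocol a [quench_protocol()].
#' @param params an [interaction_params()] (phi is overridden).
#' @param langevin a [langevin_params()]; its seed starts the RNG.
#' @param t_max latest time to simulate.
#' @param per_decade snapshots per decade of time.
#' @param stop_when_collapsed end at the collapsed plateau?
#' @param rg_drift_tol relative Rg drift per decade regarded as a plateau.
#' @return a `trajectory` starting at the quench instant.
#' @export
run_quench <- function(frame, topology, protocol, langevin,
                       params = interaction_params(), t_max = 2000,
                       per_decade = 20, stop_when_collapsed = TRUE,
                       rg_drift_tol = 0.005) {
  stopifnot(inherits(protocol, "quench_protocol"))
  params$phi <- protocol$phi_target
  frame$time <- 0
  set.seed(langevin$seed)
  steps <- log_schedule(t_max, langevin$dt, per_decade)
  # run in half-decade segments so the plateau check can stop the run early
  t_bounds <- 10^seq(0, ceiling(log10(t_max)), by = 0.5)
  t_bounds <- c(t_bounds[t_bounds < t_max], t_max)
  traj <- NULL
  done <- 0L
  cur <- frame
  for (tb in t_bounds) {
    seg_steps <- steps[steps > done & steps <= round(tb / langevin$dt)]
    if (!length(seg_steps)) next
    seg <- integrate_langevin(cur, topology, params, langevin,
                              max(seg_steps) - done,
                              snapshot_steps = seg_steps - done,
                              seed = NULL)
    seg$times <- seg$times   # t_offset already carried by frame time
    cur <- trajectory_frame(seg)
    traj <- if (is.null(traj)) seg else concat_trajectories(traj, seg)
    done <- max(seg_steps)
    if (stop_when_collapsed && max(traj$times) >= 10) {
      rg <- vapply(traj$positions, rg_of_matrix, numeric(1))
      dec <- traj$times >= max(traj$times) / 10
      # a flat Rg alone is not enough: before the collapse sets in the
      # swollen chain also has a (fluctuating) Rg plateau, so require the
      # molecule to have contracted well below its initial size too
      if (sum(dec) >= 6 && rg[length(rg)] < 0.45 * rg[1]) {
        rgd <- rg[dec]
        h <- length(rgd) %/% 2
        drift <- abs(log(mean(rgd[(h + 1):length(rgd)]) /
                           mean(rgd[seq_len(h)])))
        if (drift < rg_drift_tol) break
      }
    }
  }
  traj$phi <- params$phi
  traj$seed <- langevin$seed
  traj
}

# shared snapshot times of a set of realizations: they must agree on the
# common prefix (same log schedule, possibly truncated at collapse)
common_times <- function(trajectories) {
  n <- min(vapply(trajectories, function(tr) length(tr$times), integer(1)))
  times <- trajectories[[1]]$times[seq_len(n)]
  for (tr in trajectories) {
    if (!isTRUE(all.equal(tr$times[seq_len(n)], times))) {
      stop("trajectories do not share a common snapshot schedule")
    }
  }
  times
}

concat_trajectories <- function(a, b) {
  # b starts where a ended; drop b's duplicated first snapshot
  drop1 <- length(b$times) > 1 && abs(b$times[1] - a$times[length(a$times)]) <
    b$dt / 2
  sel <- if (drop1) -1L else TRUE
  a$times <- c(a$times, b$times[sel])
  a$positions <- c(a$positions, b$positions[sel])
  a$velocities <- c(a$velocities, b$velocities[sel])
  a$pe <- c(a$pe, b$pe[sel])
  a$ke <- c(a$ke, b$ke[sel])
  a
}

#' Locate the theta point from an Rg(phi) scan
#'
#' Equilibrates the same molecule at each value of `phi_grid` (annealing
#' from one grid point to the next) and estimates the collapse transition
#' as the maximum of |dRg/dphi| by central finite differences on the grid.
#' For long flexible chains this sits near phi ~ 0.6.
#'
#' @param topology,frame system to scan.
#' @param phi_grid increasing grid of solvent-quality values (>= 5 points).
#' @param langevin a [langevin_params()].
#' @param block_steps,max_blocks per-phi equilibration budget (see
#'   [equilibrate_good_solvent()]).
#' @return list: `phi_theta`, `phi_grid`, `rg`, `rg_se`, `dRg_dphi`.
#' @export
theta_point_scan <- function(topology, frame, phi_grid, langevin,
                             block_steps = 20000L, max_blocks = 30L) {
  stopifnot(length(phi_grid) >= 5)
  if (any(diff(phi_grid) <= 0)) {
    stop("phi_grid must be strictly increasing")
  }
  rg <- rg_se <- numeric(length(phi_grid))
  cur <- frame
  for (k in seq_along(phi_grid)) {
    p <- interaction_params(phi = phi_grid[k],
                            k_bend = 0)
    lng <- langevin
    lng$seed <- langevin$seed + k   # fresh stream per grid point
    eq <- equilibrate_phi(topology, cur, lng, p, block_steps, max_blocks)
    rg[k] <- eq$rg; rg_se[k] <- eq$rg_se
    cur <- eq$frame
  }
  est <- theta_from_rg_scan(phi_grid, rg)
  c(est, list(rg_se = rg_se))
}

#' Theta-point estimate from a tabulated Rg(phi) scan
#'
#' The collapse transition is located at the maximum of |dRg/dphi|,
#' evaluated by central finite differences on the (possibly non-uniform)
#' grid.
#'
#' @param phi_grid strictly increasing solvent-quality grid.
#' @param rg equilibrium radii of gyration at each grid point.
#' @return list: `phi_theta`, `phi_grid`, `rg`, `dRg_dphi`.
#' @export
theta_from_rg_scan <- function(phi_grid, rg) {
  stopifnot(length(phi_grid) == length(rg), length(phi_grid) >= 5)
  if (any(diff(phi_grid) <= 0)) stop("phi_grid must be strictly increasing")
  nk <- length(phi_grid)
  d <- numeric(nk)
  for (k in 2:(nk - 1)) {
    d[k] <- (rg[k + 1] - rg[k - 1]) / (phi_grid[k + 1] - phi_grid[k - 1])
  }
  d[1] <- (rg[2] - rg[1]) / (phi_grid[2] - phi_grid[1])
  d[nk] <- (rg[nk] - rg[nk - 1]) / (phi_grid[nk] - phi_grid[nk - 1])
  if (max(abs(d)) == 0) stop("no transition: Rg(phi) is flat on this grid")
  if (any(diff(rg) > 0.1 * max(rg))) {
    warning("Rg(phi) is non-monotone beyond noise")
  }
  k_max <- which.max(abs(d))
  list(phi_theta = phi_grid[k_max], phi_grid = phi_grid, rg = rg,
       dRg_dphi = d)
}

# equilibrate at arbitrary phi (same stationarity rule as good solvent)
equilibrate_phi <- function(topology, frame, langevin, params,
                            block_steps, max_blocks) {
  set.seed(langevin$seed)
  rg_series <- numeric(0)
  cur <- frame
  converged <- FALSE
  for (blk in seq_len(max_blocks)) {
    traj <- integrate_langevin(cur, topology, params, langevin, block_steps,
                               snapshot_steps = seq(0L, block_steps,
                                                    by = block_steps %/% 10L),
                               seed = NULL)
    cur <- trajectory_frame(traj)
    rg_series <- c(rg_series, vapply(traj$positions[-1L], rg_of_matrix,
                                     numeric(1)))
    if (blk >= 6L) {
      s <- rg_series[-seq_len(length(rg_series) %/% 3)]
      h <- length(s) %/% 2
      m1 <- mean(s[seq_len(h)]); m2 <- mean(s[(h + 1):length(s)])
      se <- sqrt(stats::var(s[seq_len(h)]) / h +
                   stats::var(s[(h + 1):length(s)]) / h)
      if (is.finite(se) && abs(m1 - m2) <= 2 * se) { converged <- TRUE; break }
    }
  }
  tail_s <- rg_series[-seq_len(length(rg_series) %/% 3)]
  nb <- max(2L, length(tail_s) %/% 10L)
  bm <- vapply(split(tail_s, cut(seq_along(tail_s), nb)), mean, numeric(1))
  list(frame = cur, rg = mean(tail_s),
       rg_se = stats::sd(bm) / sqrt(length(bm)), converged = converged)
}
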