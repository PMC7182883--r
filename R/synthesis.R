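#' Parameters of the in-cavity cross-linking synthesis
#'
#' Disordered microgels are generated by confining pre-built linear chains
#' in a spherical cavity and letting randomly placed reactive beads form
#' irreversible FENE cross-links on contact, mimicking microfluidic
#' droplet synthesis. Reference values: 36 chains of 600 beads with 12
#' reactive groups each in a cavity of radius 55 sigma, which gives a
#' cross-link fraction f = Nr/N = 0.02 and a number density
#' `3 Ncha N / (4 pi Rcav^3) ~ 0.03`.
#'
#' @param n_chains number of confined chains (Ncha).
#' @param beads_per_chain beads per chain (N).
#' @param reactive_per_chain reactive beads per chain (Nr); placed
#'   uniformly at random with at least one inert bead between consecutive
#'   reactive ones. `n_chains * reactive_per_chain` must be even so the
#'   reaction can complete.
#' @param cavity_radius confining cavity radius (sigma).
#' @param capture_distance two unreacted groups closer than this bond
#'   (1.3 sigma).
#' @param endgame_threshold remaining unbonded groups at which the
#'   assisted endgame (harmonic pull) starts (6).
#' @param seed RNG seed of the whole synthesis.
#' @return object of class `synthesis_params`.
#' @export
synthesis_params <- function(n_chains = 36, beads_per_chain = 600,
                             reactive_per_chain = 12, cavity_radius = 55,
                             capture_distance = 1.3, endgame_threshold = 6,
                             seed = 1L) {
  stopifnot(n_chains >= 1, beads_per_chain >= 4,
            reactive_per_chain >= 1,
            reactive_per_chain < beads_per_chain / 2,
            (n_chains * reactive_per_chain) %% 2 == 0,
            cavity_radius > 2, capture_distance > 0)
  structure(list(n_chains = n_chains, beads_per_chain = beads_per_chain,
                 reactive_per_chain = reactive_per_chain,
                 cavity_radius = cavity_radius,
                 capture_distance = capture_distance,
                 endgame_threshold = endgame_threshold,
                 seed = as.integer(seed)),
            class = "synthesis_params")
}

#' @export
print.synthesis_params <- function(x, ...) {
  dens <- 3 * x$n_chains * x$beads_per_chain / (4 * pi * x$cavity_radius^3)
  cat(sprintf(
    "Synthesis: %d chains x %d beads (%d reactive each), Rcav = %g\n",
    x$n_chains, x$beads_per_chain, x$reactive_per_chain, x$cavity_radius))
  cat(sprintf("  f = %.4g, number density = %.4g\n",
              x$reactive_per_chain / x$beads_per_chain, dens))
  invisible(x)
}

# reactive positions along one chain: uniform without adjacency
place_reactive <- function(n, nr) {
  repeat {
    r <- sort(sample.int(n, nr))
    if (nr == 1 || min(diff(r)) >= 2) return(r)
  }
}

#' Synthesize a disordered microgel by confined cross-linking
#'
#' Builds `n_chains` self-avoiding chains inside the cavity, equilibrates
#' them against the repulsive spherical wall in good solvent, then runs
#' the reaction: every `sweep_steps` MD steps, unreacted reactive pairs
#' within the capture distance are bonded (random order among candidates;
#' a group reacts at most once). When at most `endgame_threshold` groups
#' remain, a random unreacted pair is pulled together by a temporary
#' harmonic restraint (k = 0.5 epsilon/sigma^2, rest length ramped down)
#' until capture, bonded, and the system re-equilibrated; this repeats to
#' full conversion. The cavity is then removed.
#'
#' @param params a [synthesis_params()].
#' @param langevin a [langevin_params()] (seed is taken from `params`).
#' @param interaction an [interaction_params()] (good solvent enforced).
#' @param equil_steps cavity pre-equilibration steps.
#' @param sweep_steps MD steps between capture checks (10).
#' @param max_sweeps reaction budget before aborting with a
#'   partial-conversion report.
#' @param endgame_segment MD steps per restraint ramp segment.
#' @param reequil_steps re-equilibration after each endgame bond.
#' @return list: `topology` (with `crosslinks` records), `frame` (cavity
#'   removed), `report` (class `microgel_report`: f, loop_fraction,
#'   n_elastic_crosslinks, conversion, asphericity).
#' @export
synthesize_disordered_microgel <- function(params,
                                           langevin = langevin_params(),
                                           interaction = interaction_params(),
                                           equil_steps = 20000L,
                                           sweep_steps = 10L,
                                           max_sweeps = 200000L,
                                           endgame_segment = 2000L,
                                           reequil_steps = 5000L) {
  stopifnot(inherits(params, "synthesis_params"))
  set.seed(params$seed)
  interaction$phi <- 0
  ncha <- params$n_chains; nb <- params$beads_per_chain
  n <- ncha * nb
  rcav <- params$cavity_radius
  wall <- list(center = c(0, 0, 0), radius = rcav)

  # chains grown inside the cavity; reactive beads without adjacency
  pos <- matrix(NA_real_, n, 3)
  bonds <- matrix(0L, 0, 2)
  chain_of <- rep(seq_len(ncha), each = nb)
  reactive <- integer(0)
  for (c in seq_len(ncha)) {
    off <- (c - 1L) * nb
    repeat {
      o <- stats::runif(3, -1, 1) * (rcav - 2)
      if (sqrt(sum(o^2)) >= rcav - 2) next
      if (off > 0) {   # chain roots must not overlap earlier chains
        d2 <- (pos[seq_len(off), 1] - o[1])^2 +
          (pos[seq_len(off), 2] - o[2])^2 +
          (pos[seq_len(off), 3] - o[3])^2
        if (min(d2) < 0.85^2) next
      }
      break
    }
    pos[off + seq_len(nb), ] <-
      saw_coordinates(nb, origin = o,
                      existing = pos[seq_len(off), , drop = FALSE],
                      confine_radius = rcav - 1, persist = 1.2)
    bonds <- rbind(bonds, cbind(off + seq_len(nb - 1), off + seq_len(nb - 1) + 1L))
    reactive <- c(reactive, off + place_reactive(nb, params$reactive_per_chain))
  }
  top <- topology(n, bonds, architecture = "disordered_microgel",
                  chain_of_bead = chain_of)
  cur <- frame(pos)

  # cavity pre-equilibration in good solvent
  if (equil_steps > 0) {
    tr <- integrate_langevin(cur, top, interaction, langevin, equil_steps,
                             snapshot_steps = c(0L, equil_steps),
                             wall = wall, seed = NULL)
    cur <- trajectory_frame(tr)
  }

  unreacted <- reactive
  cl <- data.frame(i = integer(0), j = integer(0), intra = logical(0))
  add_bond <- function(i, j) {
    top$bonds <<- rbind(top$bonds, c(i, j))
    cl <<- rbind(cl, data.frame(i = i, j = j,
                                intra = chain_of[i] == chain_of[j]))
    unreacted <<- setdiff(unreacted, c(i, j))
  }

  # diffusion-limited capture loop
  sweeps <- 0L
  while (length(unreacted) > params$endgame_threshold &&
         sweeps < max_sweeps) {
    tr <- integrate_langevin(cur, top, interaction, langevin, sweep_steps,
                             snapshot_steps = c(0L, sweep_steps),
                             wall = wall, seed = NULL)
    cur <- trajectory_frame(tr)
    sweeps <- sweeps + 1L
    p <- cur$positions[unreacted, , drop = FALSE]
    d <- as.matrix(stats::dist(p))
    cand <- which(d < params$capture_distance & upper.tri(d), arr.ind = TRUE)
    if (nrow(cand) > 0) {
      for (k in sample.int(nrow(cand))) {
        i <- unreacted[cand[k, 1]]; j <- unreacted[cand[k, 2]]
        if (i %in% unreacted && j %in% unreacted) add_bond(i, j)
      }
    }
  }

  # assisted endgame: pull random pairs to capture distance. The rest
  # length ratchets down monotonically and the spring stiffens if the pair
  # resists, so thermal fluctuations (rms sqrt(3kT/k)) cannot stall it.
  while (length(unreacted) >= 2 && sweeps < max_sweeps) {
    pick <- sample(seq_along(unreacted), 2)
    i <- unreacted[pick[1]]; j <- unreacted[pick[2]]
    rest <- Inf
    kk <- 0.5
    repeat {
      rij <- sqrt(sum((cur$positions[i, ] - cur$positions[j, ])^2))
      if (rij < params$capture_distance) break
      rest <- max(0, 0.8 * min(rest, rij))
      tr <- integrate_langevin(cur, top, interaction, langevin,
                               endgame_segment,
                               snapshot_steps = c(0L, endgame_segment),
                               wall = wall,
                               restraints = matrix(c(i, j, kk, rest), 1),
                               seed = NULL)
      cur <- trajectory_frame(tr)
      kk <- min(30, kk * 1.5)
      sweeps <- sweeps + endgame_segment %/% sweep_steps
      if (sweeps >= max_sweeps) break
    }
    if (sqrt(sum((cur$positions[i, ] - cur$positions[j, ])^2)) <
        params$capture_distance * 1.001) {
      add_bond(i, j)
      if (reequil_steps > 0 && length(unreacted) > 0) {
        tr <- integrate_langevin(cur, top, interaction, langevin,
                                 reequil_steps,
                                 snapshot_steps = c(0L, reequil_steps),
                                 wall = wall, seed = NULL)
        cur <- trajectory_frame(tr)
      }
    }
  }

  conversion <- 1 - length(unreacted) / length(reactive)
  if (length(unreacted) > 0) {
    warning("reaction stalled at ", round(100 * conversion, 1),
            "% conversion within the sweep budget")
  }
  top$crosslinks <- cl
  report <- structure(list(
    f = params$reactive_per_chain / params$beads_per_chain,
    loop_fraction = if (nrow(cl)) mean(cl$intra) else NA_real_,
    n_elastic_crosslinks = sum(!cl$intra),
    n_crosslinks = nrow(cl),
    conversion = conversion,
    asphericity = asphericity(cur),
    seed = params$seed), class = "microgel_report")
  cur$time <- 0
  list(topology = top, frame = cur, report = report)
}

#' @export
print.microgel_report <- function(x, ...) {
  cat(sprintf("Microgel synthesis report (seed %d)\n", x$seed))
  cat(sprintf("  f = %.4g, conversion = %.1f%%\n", x$f, 100 * x$conversion))
  cat(sprintf("  %d cross-links: %.0f%% loops, %d elastically active\n",
              x$n_crosslinks, 100 * x$loop_fraction,
              x$n_elastic_crosslinks))
  cat(sprintf("  asphericity = %.3f\n", x$asphericity))
  invisible(x)
}
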