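#' Bead-spring topology
#'
#' Container for the connectivity of a macromolecule: bead count, FENE
#' bonds, bending-angle triples (semiflexible strands only), cross-link
#' records and an architecture tag. Bonds are 1-based index pairs.
#'
#' @param n_beads number of beads.
#' @param bonds integer matrix with 2 columns (one row per bond).
#' @param angles integer matrix with 3 columns (consecutive bond triples),
#'   or NULL.
#' @param crosslinks data.frame with columns `i`, `j`, `intra` (logical:
#'   TRUE if both reactive groups belong to the same source chain), or NULL.
#' @param architecture one of "chain", "star", "diamond_microgel",
#'   "disordered_microgel".
#' @param chain_of_bead optional integer map bead -> source chain id
#'   (used during microgel synthesis).
#' @return an object of class `topology`.
#' @export
topology <- function(n_beads, bonds, angles = NULL, crosslinks = NULL,
                     architecture = "chain", chain_of_bead = NULL) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  stopifnot(n_beads >= 1, all(bonds >= 1), all(bonds <= n_beads),
            all(bonds[, 1] != bonds[, 2]))
  key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  if (anyDuplicated(key)) stop("duplicate bonds in topology")
  if (!is.null(angles)) {
    angles <- matrix(as.integer(angles), ncol = 3)
    stopifnot(all(angles >= 1), all(angles <= n_beads))
  }
  structure(list(n_beads = as.integer(n_beads), bonds = bonds,
                 angles = angles, crosslinks = crosslinks,
                 architecture = architecture,
                 chain_of_bead = chain_of_bead),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology <%s>: %d beads, %d bonds, %d angles",
              x$architecture, x$n_beads, nrow(x$bonds),
              if (is.null(x$angles)) 0L else nrow(x$angles)))
  if (!is.null(x$crosslinks) && nrow(x$crosslinks) > 0) {
    cat(sprintf(", %d cross-links (%.0f%% loops)",
                nrow(x$crosslinks), 100 * mean(x$crosslinks$intra)))
  }
  cat("\n")
  invisible(x)
}

#' Snapshot of a configuration
#'
#' @param positions numeric n x 3 matrix of bead coordinates (sigma).
#' @param velocities numeric n x 3 matrix; defaults to zero.
#' @param time reduced time since the quench instant.
#' @return an object of class `frame`.
#' @export
frame <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  }
  velocities <- as.matrix(velocities)
  stopifnot(dim(velocities)[1] == nrow(positions), ncol(velocities) == 3)
  structure(list(time = time, positions = positions,
                 velocities = velocities), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("Frame: %d beads at t = %g (Rg = %.3f)\n",
              nrow(x$positions), x$time, radius_of_gyration(x)))
  invisible(x)
}

# angle triples from a bond list along one strand: every pair of bonds
# sharing a bead (i, j), (j, k) -> (i, j, k)
consecutive_angles <- function(bonds) {
  n <- max(bonds)
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      out[[length(out) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# self-avoiding random-walk coordinates for a strand of n beads:
# fixed step `bond`, accepts a step if no previously placed bead of this
# or other strands is closer than `excl`; backtracks on dead ends.
saw_coordinates <- function(n, bond = 0.96, excl = 0.85, origin = c(0, 0, 0),
                            existing = NULL, max_tries = 60L,
                            confine_radius = Inf, center = c(0, 0, 0),
                            bias_origin = NULL, persist = 0) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- origin
  d_prev <- stats::rnorm(3)
  d_prev <- d_prev / sqrt(sum(d_prev^2))
  all_prev <- function(k) {
    if (is.null(existing)) pos[seq_len(k), , drop = FALSE]
    else rbind(existing, pos[seq_len(k), , drop = FALSE])
  }
  i <- 2L
  tries <- integer(n)
  total <- 0L
  budget <- 40L * n * max_tries
  while (i <= n) {
    total <- total + 1L
    if (total > budget) {
      stop("could not grow self-avoiding walk: geometry too crowded")
    }
    # direction persistence tunes the generated chain's Kuhn length to
    # the model's equilibrium statistics, so MD equilibration only has to
    # relax the large-scale modes
    u <- stats::rnorm(3) + persist * d_prev
    if (!is.null(bias_origin)) {
      # push the walk away from a crowded core (star centers): strong
      # radial bias near the origin, negligible far away
      rad <- pos[i - 1L, ] - bias_origin
      rn <- sqrt(sum(rad^2))
      if (rn > 1e-9) u <- u + (2.5 / max(rn, 0.75)) * rad / rn
    }
    u <- u / sqrt(sum(u^2))
    cand <- pos[i - 1L, ] + bond * u
    prev <- all_prev(i - 1L)
    d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
      (prev[, 3] - cand[3])^2
    # excl < bond, so the bonded predecessor never trips this check
    ok <- !any(d2 < excl^2) &&
      sqrt(sum((cand - center)^2)) < confine_radius
    if (ok) {
      pos[i, ] <- cand
      d_prev <- u
      tries[i] <- 0L
      i <- i + 1L
    } else {
      tries[i] <- tries[i] + 1L
      if (tries[i] > max_tries) {   # dead end: step back
        tries[i] <- 0L
        i <- max(2L, i - 1L)
      }
    }
  }
  pos
}

#' Build a linear bead-spring chain
#'
#' A string of `n` beads joined by FENE bonds; when `semiflexible = TRUE`
#' every pair of consecutive bonds carries the worm-like bending term.
#' Initial coordinates are a self-avoiding random walk at the bonded-pair
#' minimum distance (~0.96 sigma).
#'
#' @param n number of beads (>= 2).
#' @param semiflexible add bending-angle triples?
#' @param typical redraw the initial conformation until its radius of
#'   gyration is within 15% of the model's equilibrium mean? The
#'   generated ensemble has a broad size distribution; when only a few
#'   realizations are affordable, conditioning the starting states on a
#'   typical global size keeps an unlucky extreme draw from dominating
#'   pooled quench statistics.
#' @return list with elements `topology` and `frame`.
#' @details Initial coordinates come from a self-avoiding walk whose
#'   direction persistence is calibrated to the model's equilibrium
#'   statistics (effective Kuhn length of the flexible Kremer-Grest
#'   chain, or the worm-like persistence length `lp ~ 4.3 sigma` at
#'   `Ks = 5`), so equilibration only has to relax local detail. The
#'   equilibrium size references are the self-avoiding `0.52 N^0.588`
#'   (flexible) and the ideal worm-like `sqrt(lp b N / 3)`
#'   (semiflexible, whose excluded volume is weak at these lengths);
#'   both match long direct equilibrations of the model.
#' @examples
#' ch <- build_linear_chain(50)
#' ch$topology
#' @export
build_linear_chain <- function(n, semiflexible = FALSE, typical = FALSE) {
  stopifnot(n >= 2)
  bonds <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  angles <- if (semiflexible && n >= 3) {
    cbind(seq_len(n - 2), seq_len(n - 2) + 1L, seq_len(n - 2) + 2L)
  } else NULL
  top <- topology(n, bonds, angles, architecture = "chain")
  persist <- if (semiflexible) 2.5 else 1.6
  rg_ref <- if (semiflexible) sqrt(4.3 * 0.96 * n / 3) else 0.52 * n^0.588
  pos <- saw_coordinates(n, persist = persist)
  if (typical) {
    for (try in 1:30) {
      if (abs(rg_of_matrix(pos) / rg_ref - 1) <= 0.15) break
      pos <- saw_coordinates(n, persist = persist)
    }
  }
  list(topology = top, frame = frame(pos))
}

#' Build a star polymer
#'
#' `n_arms` flexible linear arms of `arm_length` beads each, bonded to a
#' single central bead; total `n_arms * arm_length + 1` beads.
#'
#' @param n_arms number of arms.
#' @param arm_length beads per arm (>= 1).
#' @return list with elements `topology` and `frame`.
#' @export
build_star <- function(n_arms, arm_length) {
  stopifnot(n_arms >= 1, arm_length >= 1)
  n <- n_arms * arm_length + 1L
  bonds <- matrix(0L, 0, 2)
  pos <- matrix(0, n, 3)
  placed <- matrix(0, 1, 3)   # center at origin
  # arm roots leave the center along well-separated (Fibonacci sphere)
  # directions so dense stars can always be grown
  golden <- pi * (3 - sqrt(5))
  for (a in seq_len(n_arms)) {
    first <- 1L + (a - 1L) * arm_length + 1L
    idx <- first:(first + arm_length - 1L)
    z <- if (n_arms == 1) 1 else 1 - 2 * (a - 1) / (n_arms - 1)
    rxy <- sqrt(max(0, 1 - z^2))
    u <- c(rxy * cos(golden * (a - 1)), rxy * sin(golden * (a - 1)), z)
    arm <- NULL
    for (attempt in 1:8) {
      arm <- tryCatch(
        saw_coordinates(arm_length, origin = 0.96 * u,
                        existing = placed, bias_origin = c(0, 0, 0),
                        persist = 1.2),
        error = function(e) NULL)
      if (!is.null(arm)) break
    }
    if (is.null(arm)) stop("could not grow star arm ", a)
    pos[idx, ] <- arm
    placed <- rbind(placed, arm)
    bonds <- rbind(bonds, c(1L, first))
    if (arm_length > 1) {
      bonds <- rbind(bonds, cbind(idx[-arm_length], idx[-1]))
    }
  }
  top <- topology(n, bonds, architecture = "star")
  list(topology = top, frame = frame(pos))
}

#' Build a diamond-lattice microgel
#'
#' Cross-links sit on the nodes of a regular diamond lattice; every pair of
#' nearest-neighbour nodes is joined by a straight bead-spring strand of
#' `strand_length` beads. The lattice constant is set so the strand rest
#' length matches the node spacing with bonds at ~0.96 sigma (unstrained
#' network). A sphere around the lattice center containing approximately
#' `n_nodes_target` nodes is carved out; beads outside are removed and the
#' largest connected component is kept. The network contains no loops, so
#' all cross-links are elastically active.
#'
#' @param n_nodes_target number of 4-functional nodes to retain (~78 for
#'   the reference network paired with 138-bead strands, giving ~21.6k beads).
#' @param strand_length beads per strand between bonded nodes.
#' @param bond rest bond length (sigma).
#' @return list with `topology`, `frame`, `n_nodes` (nodes kept) and
#'   `node_beads` (their bead indices).
#' @export
build_diamond_microgel <- function(n_nodes_target, strand_length,
                                   bond = 0.96) {
  stopifnot(n_nodes_target >= 2, strand_length >= 1)
  # nearest-neighbour node distance must equal the strand contour length
  d_nn <- (strand_length + 1) * bond
  a <- d_nn * 4 / sqrt(3)          # diamond nn distance = a*sqrt(3)/4
  # enough conventional cells to contain the target node count
  n_cells <- max(2L, ceiling((n_nodes_target / 8)^(1 / 3)) + 2L)
  rng <- -(n_cells):(n_cells)
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(basis, sweep(basis, 2, c(.25, .25, .25), "+"))
  cells <- as.matrix(expand.grid(x = rng, y = rng, z = rng))
  nodes <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    sweep(cells, 2, basis[b, ], "+")
  })) * a
  # keep the n_nodes_target nodes closest to the lattice center
  d <- sqrt(rowSums(sweep(nodes, 2, c(a / 8, a / 8, a / 8), "-")^2))
  keep <- order(d)[seq_len(min(n_nodes_target, nrow(nodes)))]
  nodes <- nodes[keep, , drop = FALSE]
  nn <- nrow(nodes)
  # nearest-neighbour pairs among kept nodes
  pairs <- which(as.matrix(stats::dist(nodes)) < d_nn * 1.01 &
                   upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("no bonded node pairs: target too small")
  pos <- nodes
  bonds <- matrix(0L, 0, 2)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    ts <- seq_len(strand_length) / (strand_length + 1)
    strand <- outer(1 - ts, nodes[i, ]) + outer(ts, nodes[j, ])
    idx <- nrow(pos) + seq_len(strand_length)
    pos <- rbind(pos, strand)
    path <- c(i, idx, j)
    bonds <- rbind(bonds, cbind(path[-length(path)], path[-1]))
  }
  # largest connected component (peripheral fragments may be carved off)
  comp <- graph_components(nrow(pos), bonds)
  big <- which.max(tabulate(comp))
  keep_b <- which(comp == big)
  remap <- integer(nrow(pos)); remap[keep_b] <- seq_along(keep_b)
  bonds <- bonds[comp[bonds[, 1]] == big & comp[bonds[, 2]] == big, ,
                 drop = FALSE]
  bonds <- cbind(remap[bonds[, 1]], remap[bonds[, 2]])
  pos <- pos[keep_b, , drop = FALSE]
  node_beads <- remap[seq_len(nn)[comp[seq_len(nn)] == big]]
  cl <- data.frame(i = integer(0), j = integer(0), intra = logical(0))
  top <- topology(nrow(pos), bonds, architecture = "diamond_microgel",
                  crosslinks = cl)
  list(topology = top, frame = frame(sweep(pos, 2, colMeans(pos))),
       n_nodes = length(node_beads), node_beads = node_beads)
}

# connected components over an explicit bond list (plain BFS)
graph_components <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- adj[[v]]
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  comp
}
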