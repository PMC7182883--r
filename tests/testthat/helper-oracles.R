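# Independent brute-force oracles used across the test files. They share
# no code with the package internals they check.

# total potential energy by direct summation over all pairs/bonds/angles
oracle_energy <- function(pos, topology, params, wall = NULL) {
  n <- nrow(pos)
  e <- 0
  d <- as.matrix(stats::dist(pos))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= params$r_cut * params$sigma) {
        e <- e + nonbonded_potential(d[i, j], params)
      }
    }
  }
  for (b in seq_len(nrow(topology$bonds))) {
    e <- e + fene_potential(d[topology$bonds[b, 1], topology$bonds[b, 2]],
                            params)
  }
  if (!is.null(topology$angles)) {
    for (a in seq_len(nrow(topology$angles))) {
      i <- topology$angles[a, 1]; j <- topology$angles[a, 2]
      k <- topology$angles[a, 3]
      b1 <- pos[j, ] - pos[i, ]; b2 <- pos[k, ] - pos[j, ]
      ct <- sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
      e <- e + bending_potential(acos(pmin(1, pmax(-1, ct))), params)
    }
  }
  if (!is.null(wall)) {
    rw <- wall$radius - sqrt(rowSums(sweep(pos, 2, wall$center)^2))
    e <- e + sum(wall_potential(rw, params))
  }
  e
}

# central-difference gradient of oracle_energy
oracle_gradient <- function(pos, topology, params, h = 1e-6) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (dd in 1:3) {
      pp <- pos; pp[i, dd] <- pp[i, dd] + h
      e1 <- oracle_energy(pp, topology, params)
      pp[i, dd] <- pp[i, dd] - 2 * h
      e2 <- oracle_energy(pp, topology, params)
      g[i, dd] <- (e1 - e2) / (2 * h)
    }
  }
  g
}

# per-cell monomer count by scanning every (cell, particle) pair
oracle_cell_density <- function(pos, origin, delta, dims, r_c) {
  rho <- array(0, dims)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    for (iz in seq_len(dims[3])) {
      ctr <- origin + delta * (c(ix, iy, iz) - 0.5)
      dd <- sqrt(colSums((t(pos) - ctr)^2))
      rho[ix, iy, iz] <- sum(dd <= r_c)
    }
  }
  rho * 3 / (4 * pi * r_c^3)
}

# smoothing stencil written as an explicit loop
oracle_smooth <- function(rho) {
  d <- dim(rho)
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) 0
    else rho[i, j, k]
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    out[i, j, k] <- (2 * rho[i, j, k] + at(i - 1, j, k) + at(i + 1, j, k) +
                       at(i, j - 1, k) + at(i, j + 1, k) +
                       at(i, j, k - 1) + at(i, j, k + 1)) / 8
  }
  out
}

# chord multiset by walking every grid line cell by cell
oracle_chords <- function(mask, delta) {
  d <- dim(mask)
  lens <- integer(0)
  scan_line <- function(cells) {
    r <- 0L
    for (v in c(cells, FALSE)) {
      if (v) r <- r + 1L
      else { if (r > 0L) lens <<- c(lens, r); r <- 0L }
    }
  }
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) scan_line(mask[, j, k])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) scan_line(mask[i, , k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) scan_line(mask[i, j, ])
  as.numeric(lens) * delta
}

# 6-connected components by an explicit queue flood fill
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      i <- (c0 - 1) %% d[1] + 1
      j <- ((c0 - 1) %/% d[1]) %% d[2] + 1
      k <- (c0 - 1) %/% (d[1] * d[2]) + 1
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3] && mask[ii, jj, kk] &&
            lab[ii, jj, kk] == 0L) {
          lab[ii, jj, kk] <- cur
          queue <- c(queue, (kk - 1) * d[1] * d[2] + (jj - 1) * d[1] + ii)
        }
      }
    }
  }
  lab
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  key <- paste(a[a > 0], b[b > 0])
  length(unique(key)) == length(unique(a[a > 0])) &&
    length(unique(key)) == length(unique(b[b > 0]))
}

random_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  m <- array(stats::runif(prod(dims)) < p, dims)
  # empty one-cell margin like a padded density field
  m[1, , ] <- m[dims[1], , ] <- FALSE
  m[, 1, ] <- m[, dims[2], ] <- FALSE
  m[, , 1] <- m[, , dims[3]] <- FALSE
  m
}
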