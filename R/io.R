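#' Write a trajectory as extended XYZ
#'
#' One block per snapshot: bead count, a comment line with
#' `Properties=species:S:1:pos:R:3:vel:R:3 Time=<t>`, then one line per
#' bead. Round-trips losslessly through [read_xyz()] at full double
#' precision.
#'
#' @param trajectory a trajectory (or a single [frame()]).
#' @param path output file.
#' @export
write_xyz <- function(trajectory, path) {
  if (inherits(trajectory, "frame")) {
    trajectory <- list(times = trajectory$time,
                       positions = list(trajectory$positions),
                       velocities = list(trajectory$velocities))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(trajectory$times)) {
    p <- trajectory$positions[[i]]; v <- trajectory$velocities[[i]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf(
      "Properties=species:S:1:pos:R:3:vel:R:3 Time=%.17g",
      trajectory$times[i]), con)
    writeLines(sprintf("A %.17g %.17g %.17g %.17g %.17g %.17g",
                       p[, 1], p[, 2], p[, 3], v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#' @param path file written by [write_xyz()] (or compatible).
#' @return a `trajectory` (times, positions, velocities; energies NA).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  times <- numeric(0); positions <- list(); velocities <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop("malformed XYZ at line ", i, ": expected bead count")
    }
    n <- as.integer(lines[i])
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ file: frame starting at line ", i,
           " is incomplete (last good frame: ", length(times), ")")
    }
    cm <- lines[i + 1L]
    tm <- regmatches(cm, regexec("Time=([-0-9.eE+]+)", cm))[[1]][2]
    t <- if (is.na(tm)) NA_real_ else as.numeric(tm)
    block <- lines[(i + 2L):(i + 1L + n)]
    m <- matrix(scan(text = sub("^\\S+\\s+", "", block), quiet = TRUE),
                nrow = n, byrow = TRUE)
    if (ncol(m) < 3) stop("malformed XYZ frame at line ", i)
    positions[[length(positions) + 1L]] <- m[, 1:3, drop = FALSE]
    velocities[[length(velocities) + 1L]] <-
      if (ncol(m) >= 6) m[, 4:6, drop = FALSE] else matrix(0, n, 3)
    times <- c(times, t)
    i <- i + 2L + n
  }
  structure(list(times = times, positions = positions,
                 velocities = velocities,
                 pe = rep(NA_real_, length(times)),
                 ke = rep(NA_real_, length(times)),
                 phi = NA_real_, dt = NA_real_, seed = NA_integer_,
                 n_beads = nrow(positions[[1]])),
            class = "trajectory")
}

#' Binary trajectory container
#'
#' Serialized container (RDS) holding times, positions, velocities and
#' energies with a format tag; bit-identical round-trip.
#'
#' @param trajectory a trajectory; @param path file path.
#' @export
write_trajectory_bin <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  saveRDS(c(list(format = "polycollapse-trajectory-1"),
            unclass(trajectory)), path)
  invisible(path)
}

#' @rdname write_trajectory_bin
#' @export
read_trajectory_bin <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "polycollapse-trajectory-1")) {
    stop("not a polycollapse trajectory container: ", path)
  }
  x$format <- NULL
  structure(x, class = "trajectory")
}

#' Import a LAMMPS-style dump (read-only)
#'
#' Parses `ITEM: TIMESTEP / NUMBER OF ATOMS / ATOMS id ... x y z [vx vy vz]`
#' blocks; atoms are re-ordered by id. Times are `timestep * dt`.
#'
#' @param path dump file; @param dt time per step used to convert
#'   timesteps to reduced time.
#' @return a `trajectory`.
#' @export
read_lammps_dump <- function(path, dt = 0.005) {
  lines <- readLines(path)
  times <- numeric(0); positions <- list(); velocities <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^ITEM: TIMESTEP", lines[i])) {
      stop("malformed dump at line ", i, ": expected ITEM: TIMESTEP")
    }
    step <- as.numeric(lines[i + 1L])
    j <- i + 2L
    while (j <= length(lines) && !grepl("^ITEM: NUMBER OF ATOMS", lines[j])) {
      j <- j + 1L
    }
    n <- as.integer(lines[j + 1L])
    k <- j + 2L
    while (k <= length(lines) && !grepl("^ITEM: ATOMS", lines[k])) k <- k + 1L
    cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[k]), "\\s+")[[1]]
    if (k + n > length(lines)) {
      stop("truncated dump: frame at line ", i, " (last good frame: ",
           length(times), ")")
    }
    m <- matrix(scan(text = lines[(k + 1L):(k + n)], quiet = TRUE),
                nrow = n, byrow = TRUE)
    colnames(m) <- cols[seq_len(ncol(m))]
    need <- c("id", "x", "y", "z")
    if (!all(need %in% cols)) {
      stop("dump frame at line ", i, " lacks columns: ",
           paste(setdiff(need, cols), collapse = ", "))
    }
    ord <- order(m[, "id"])
    positions[[length(positions) + 1L]] <-
      unname(m[ord, c("x", "y", "z"), drop = FALSE])
    velocities[[length(velocities) + 1L]] <-
      if (all(c("vx", "vy", "vz") %in% cols)) {
        unname(m[ord, c("vx", "vy", "vz"), drop = FALSE])
      } else matrix(0, n, 3)
    times <- c(times, step * dt)
    i <- k + n + 1L
  }
  structure(list(times = times, positions = positions,
                 velocities = velocities,
                 pe = rep(NA_real_, length(times)),
                 ke = rep(NA_real_, length(times)),
                 phi = NA_real_, dt = dt, seed = NA_integer_,
                 n_beads = nrow(positions[[1]])),
            class = "trajectory")
}

#' Topology persistence (JSON)
#'
#' Plain-text JSON with beads, bonds, angles, cross-link records and the
#' architecture tag; identical round-trip.
#'
#' @param topology a [topology()]; @param path file path.
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "topology"))
  obj <- list(format = "polycollapse-topology-1",
              n_beads = topology$n_beads,
              architecture = topology$architecture,
              bonds = topology$bonds,
              angles = topology$angles,
              crosslinks = topology$crosslinks,
              chain_of_bead = topology$chain_of_bead)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "polycollapse-topology-1")) {
    stop("not a polycollapse topology file: ", path)
  }
  cl <- x$crosslinks
  if (!is.null(cl) && length(cl) == 0) cl <- NULL
  topology(x$n_beads, matrix(as.integer(x$bonds), ncol = 2),
           angles = if (is.null(x$angles)) NULL else
             matrix(as.integer(x$angles), ncol = 3),
           crosslinks = cl,
           architecture = x$architecture,
           chain_of_bead = x$chain_of_bead)
}

#' Export a topology + frame as a LAMMPS data file
#'
#' Writes the `atoms`, `bonds` and `angles` sections in LAMMPS
#' `data`-style format (atom style molecular) for interoperability with
#' other MD tools.
#'
#' @param topology a [topology()]; @param frame a [frame()];
#' @param path output file.
#' @export
write_lammps_data <- function(topology, frame, path) {
  stopifnot(inherits(topology, "topology"), inherits(frame, "frame"))
  p <- frame$positions
  pad <- 2
  lim <- rbind(apply(p, 2, min) - pad, apply(p, 2, max) + pad)
  n_ang <- if (is.null(topology$angles)) 0L else nrow(topology$angles)
  mol <- if (is.null(topology$chain_of_bead)) rep(1L, topology$n_beads)
         else topology$chain_of_bead
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("LAMMPS data file (polycollapse export)", "",
               sprintf("%d atoms", topology$n_beads),
               sprintf("%d bonds", nrow(topology$bonds)),
               sprintf("%d angles", n_ang), "",
               "1 atom types", "1 bond types",
               if (n_ang > 0) "1 angle types", "",
               sprintf("%.8g %.8g xlo xhi", lim[1, 1], lim[2, 1]),
               sprintf("%.8g %.8g ylo yhi", lim[1, 2], lim[2, 2]),
               sprintf("%.8g %.8g zlo zhi", lim[1, 3], lim[2, 3]), "",
               "Masses", "", "1 1.0", "", "Atoms", ""), con)
  writeLines(sprintf("%d %d 1 %.10g %.10g %.10g",
                     seq_len(topology$n_beads), mol,
                     p[, 1], p[, 2], p[, 3]), con)
  writeLines(c("", "Bonds", ""), con)
  writeLines(sprintf("%d 1 %d %d", seq_len(nrow(topology$bonds)),
                     topology$bonds[, 1], topology$bonds[, 2]), con)
  if (n_ang > 0) {
    writeLines(c("", "Angles", ""), con)
    writeLines(sprintf("%d 1 %d %d %d", seq_len(n_ang),
                       topology$angles[, 1], topology$angles[, 2],
                       topology$angles[, 3]), con)
  }
  invisible(path)
}

#' Declarative run configuration
#'
#' A fully serializable description of one simulation/analysis run:
#' architecture, interaction, thermostat, quench protocol, density-field
#' parameter pairs and the seed. Round-trips identically through YAML.
#'
#' @param architecture list, e.g. `list(kind = "chain", n = 400,
#'   semiflexible = TRUE)`.
#' @param phi_target quench target solvent parameter.
#' @param field_pairs list of `c(r_c, rho_min)` pairs.
#' @param langevin a [langevin_params()].
#' @param t_max quench duration cap.
#' @param seed run seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(architecture, phi_target = 1.2,
                       field_pairs = list(c(1.0, 0.6), c(1.2, 0.35)),
                       langevin = langevin_params(), t_max = 2000,
                       seed = 1L) {
  structure(list(architecture = architecture, phi_target = phi_target,
                 field_pairs = field_pairs,
                 langevin = unclass(langevin), t_max = t_max,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`; @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  lng <- do.call(langevin_params, x$langevin)
  run_config(architecture = x$architecture, phi_target = x$phi_target,
             field_pairs = x$field_pairs, langevin = lng,
             t_max = x$t_max, seed = x$seed)
}

#' Write an analysis table as headered TSV
#' @param df data.frame; @param path file path.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
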