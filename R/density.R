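#' Coarse-grained density field of a configuration
#'
#' Converts a particle frame into a smooth density field on a cubic grid
#' of spacing `delta`: the raw per-cell density is the number of monomers
#' within `r_c` of the cell center divided by the sphere volume,
#' `rho = 3 n / (4 pi r_c^3)`; the smoothed density is a weighted average
#' over the cell and its six face neighbours,
#' `rho_bar = (2 rho + sum_k rho_k) / 8`; cells are classified filled when
#' `rho_bar > rho_min` (strict). The grid is anchored to the centre of
#' mass (cell boundaries at COM + integer multiples of delta), which
#' removes diffusive drift between frames, and is padded so every face has
#' an empty margin.
#'
#' @param frame a [frame()] or n x 3 coordinate matrix.
#' @param params a [field_params()].
#' @param smooth,classify compute the smoothed field / filled mask?
#' @return an object of class `density_field`: `origin`, `delta`, `dims`,
#'   arrays `rho`, `rho_bar`, logical array `filled`, `n_filled`, `params`.
#' @export
density_field <- function(frame, params = field_params(),
                          smooth = TRUE, classify = TRUE) {
  pos <- if (inherits(frame, "frame")) frame$positions else as.matrix(frame)
  stopifnot(nrow(pos) >= 1)
  fld <- local_density(pos, params)
  if (smooth) fld$rho_bar <- smooth_density(fld$rho)
  if (smooth && classify) {
    fld <- classify_density(fld, params$rho_min)
  }
  fld
}

#' Raw local density on a COM-anchored grid
#'
#' @param frame a [frame()] or coordinate matrix.
#' @param params a [field_params()].
#' @param origin,dims optional explicit grid (origin corner and cell
#'   counts); by default the grid is COM-anchored and padded.
#' @return a `density_field` with the raw `rho` array only.
#' @export
local_density <- function(frame, params = field_params(),
                          origin = NULL, dims = NULL) {
  pos <- if (inherits(frame, "frame")) frame$positions else as.matrix(frame)
  delta <- params$delta
  pad <- params$r_c + 2 * delta
  com <- colMeans(pos)
  if (is.null(origin) != is.null(dims)) {
    stop("supply both origin and dims, or neither")
  }
  if (is.null(origin)) {
    lo <- apply(pos, 2, min) - pad
    hi <- apply(pos, 2, max) + pad
    n_lo <- ceiling((com - lo) / delta)
    n_hi <- ceiling((hi - com) / delta)
    origin <- com - n_lo * delta
    dims <- as.integer(n_lo + n_hi)
  } else {
    dims <- as.integer(dims)
  }
  rho <- cpp_cell_counts(pos, origin, delta, dims, params$r_c) *
    (3 / (4 * pi * params$r_c^3))
  dim(rho) <- dims
  structure(list(origin = origin, delta = delta, dims = dims, com = com,
                 rho = rho, rho_bar = NULL, filled = NULL,
                 n_filled = NA_integer_, params = params),
            class = "density_field")
}

#' Smooth a raw density grid with the face-neighbour stencil
#'
#' `rho_bar(r) = (1/8) [2 rho(r) + sum over the 6 face neighbours]`;
#' cells outside the grid contribute zero.
#'
#' @param rho 3-D numeric array (or a `density_field`).
#' @return smoothed array of the same shape.
#' @export
smooth_density <- function(rho) {
  if (inherits(rho, "density_field")) rho <- rho$rho
  d <- dim(rho)
  stopifnot(length(d) == 3)
  out <- cpp_smooth(as.numeric(rho), as.integer(d))
  dim(out) <- d
  out
}

#' Threshold the smoothed field into filled/empty cells
#'
#' @param field a `density_field` with `rho_bar` computed.
#' @param rho_min fill threshold; a cell is filled iff `rho_bar > rho_min`
#'   (strict inequality).
#' @return the field with `filled` and `n_filled` set; zero filled cells
#'   raises a warning.
#' @export
classify_density <- function(field, rho_min = field$params$rho_min) {
  stopifnot(inherits(field, "density_field"), !is.null(field$rho_bar))
  field$filled <- field$rho_bar > rho_min
  field$n_filled <- sum(field$filled)
  if (field$n_filled == 0) {
    warning("no filled cells at rho_min = ", rho_min)
  }
  field
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("Density field: %d x %d x %d cells (delta = %g, r_c = %g)",
              x$dims[1], x$dims[2], x$dims[3], x$delta, x$params$r_c))
  if (!is.na(x$n_filled)) {
    cat(sprintf(", %d filled (rho_min = %g)", x$n_filled, x$params$rho_min))
  }
  cat("\n")
  invisible(x)
}

#' Uniform random 3-D rotation matrix
#'
#' Drawn from the Haar measure on SO(3) (QR of a Gaussian matrix with the
#' sign fix, determinant +1). Used to orient configurations randomly
#' before gridding in the chord analysis.
#'
#' @return 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
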