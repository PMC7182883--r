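#' Synthetic geometric fixtures with known ground truth
#'
#' Generates particle configurations or filled-cell masks whose analysis
#' results are known by construction, so the density-field, chord and
#' cluster operators can be validated without running dynamics.
#'
#' Kinds:
#' \describe{
#'   \item{solid_ball}{beads on a dense cubic lattice inside a sphere of
#'     radius `radius`; one connected cluster.}
#'   \item{rod}{beads on a straight line, spacing `spacing`, count `n`.}
#'   \item{multi_sphere}{`k` solid balls with centers `centers` (k x 3);
#'     cluster count = k when well separated.}
#'   \item{pearl_necklace}{`k` balls of radius `radius` equally spaced by
#'     `separation` along a line (collapsing-chain caricature).}
#'   \item{random_gas}{`n` beads uniform in a cube of side `side`.}
#'   \item{exact_mask}{passes through a logical array given as `mask`;
#'     truth holds its exact chord multiset and cluster count.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed RNG seed (random_gas only).
#' @param ... geometric parameters per kind.
#' @return list: `frame` (or `mask` for exact_mask) and `truth`, a list of
#'   machine-checkable expectations (e.g. `n_clusters`, `chords`).
#' @export
make_fixture <- function(kind, ..., seed = 1L) {
  args <- list(...)
  g <- function(name, default = NULL) {
    if (!is.null(args[[name]])) args[[name]] else
      if (!is.null(default)) default else
        stop("fixture '", kind, "' needs parameter '", name, "'")
  }
  ball <- function(center, radius, spacing) {
    rng <- seq(-radius, radius, by = spacing)
    gpts <- as.matrix(expand.grid(x = rng, y = rng, z = rng))
    gpts <- gpts[rowSums(gpts^2) <= radius^2, , drop = FALSE]
    sweep(gpts, 2, center, "+")
  }
  switch(kind,
    solid_ball = {
      r <- g("radius", 3); sp <- g("spacing", 0.5)
      pos <- ball(c(0, 0, 0), r, sp)
      list(frame = frame(pos), truth = list(n_clusters = 1L))
    },
    rod = {
      n <- g("n", 20); sp <- g("spacing", 0.96)
      pos <- cbind(seq_len(n) * sp, 0, 0)
      list(frame = frame(pos), truth = list(n_clusters = 1L))
    },
    multi_sphere = {
      centers <- as.matrix(g("centers"))
      r <- g("radius", 2); sp <- g("spacing", 0.5)
      if (nrow(centers) > 1 &&
          min(stats::dist(centers)) <= 2 * r + 2) {
        stop("inconsistent geometry: spheres overlap or nearly touch")
      }
      pos <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
        ball(centers[k, ], r, sp)
      }))
      list(frame = frame(pos), truth = list(n_clusters = nrow(centers)))
    },
    pearl_necklace = {
      k <- g("k", 4); r <- g("radius", 1.5); sep <- g("separation", 8)
      if (sep <= 2 * r) stop("inconsistent geometry: pearls overlap")
      centers <- cbind((seq_len(k) - 1) * sep, 0, 0)
      pos <- do.call(rbind, lapply(seq_len(k), function(i) {
        ball(centers[i, ], r, g("spacing", 0.5))
      }))
      list(frame = frame(pos), truth = list(n_clusters = k))
    },
    random_gas = {
      set.seed(seed)
      n <- g("n", 100); side <- g("side", 10)
      pos <- matrix(stats::runif(3 * n, 0, side), n, 3)
      list(frame = frame(pos), truth = list(fill_fraction_max = 1))
    },
    exact_mask = {
      mask <- g("mask")
      stopifnot(is.logical(mask), length(dim(mask)) == 3)
      delta <- g("delta", 0.5)
      lab <- label_clusters(mask)
      list(mask = mask, delta = delta,
           truth = list(n_clusters = attr(lab, "n_clusters"),
                        chords = sort(enumerate_chords(mask, delta)),
                        n_filled = sum(mask)))
    },
    stop("unknown fixture kind: ", kind)
  )
}

#' Synthetic power-law growth series for fitter validation
#'
#' `value(t) = t^exponent * exp(noise * N(0,1))` on a log-spaced time
#' grid; with zero noise every fitter must recover the exponent exactly.
#'
#' @param exponent power-law exponent (> 0).
#' @param noise multiplicative log-normal noise amplitude (sd of log).
#' @param seed RNG seed.
#' @param times time grid (positive); default 60 log-spaced points over
#'   three decades.
#' @return data.frame with columns `time`, `value`.
#' @export
make_growth_series <- function(exponent, noise = 0, seed = 1L,
                               times = 10^seq(0, 3, length.out = 60)) {
  if (exponent <= 0) stop("exponent must be positive")
  if (any(times < 0)) stop("negative times are not allowed")
  set.seed(seed)
  data.frame(time = times,
             value = times^exponent * exp(noise * stats::rnorm(length(times))))
}
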