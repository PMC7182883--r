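#' Enumerate chords of a filled-cell mask
#'
#' A chord is a maximal straight run of consecutive filled cells along one
#' of the three grid axes; its two end cells are interfacial (their
#' axis-neighbour is empty, the grid boundary counting as empty). Returns
#' the multiset of chord lengths, `run length * delta`, pooled over the
#' three axes.
#'
#' @param mask logical 3-D array (or a `density_field` with `filled`).
#' @param delta cell side (taken from the field when one is supplied).
#' @return numeric vector of chord lengths (empty for an empty mask).
#' @export
enumerate_chords <- function(mask, delta = 0.5) {
  if (inherits(mask, "density_field")) {
    delta <- mask$delta
    mask <- mask$filled
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  as.numeric(cpp_chords(as.logical(mask), as.integer(dim(mask)))) * delta
}

#' Chord-length distribution of a configuration
#'
#' Pools chords over `n_rotations` orientations of the particle
#' configuration (the original orientation plus uniform random rotations),
#' each gridded independently, and over any number of additional
#' realization frames, then normalizes the histogram to unit sum.
#'
#' @param frames a [frame()], coordinate matrix, or list of them
#'   (independent realizations at the same time).
#' @param params a [field_params()].
#' @param n_rotations orientations per frame (>= 1; the first is the
#'   identity).
#' @param seed RNG seed for the rotations (logged in the result).
#' @return object of class `chord_distribution`: `L` (lengths, multiples
#'   of delta), `p` (probabilities, unit sum), `n_chords`, `mean`, `seed`.
#' @export
chord_distribution <- function(frames, params = field_params(),
                               n_rotations = 5, seed = 1L) {
  if (!is.list(frames) || inherits(frames, "frame")) frames <- list(frames)
  set.seed(seed)
  lens <- list()
  for (fr in frames) {
    pos <- if (inherits(fr, "frame")) fr$positions else as.matrix(fr)
    cm <- colMeans(pos)
    centered <- sweep(pos, 2, cm)
    for (k in seq_len(n_rotations)) {
      rot <- if (k == 1) diag(3) else random_rotation()
      fld <- density_field(centered %*% t(rot), params)
      lens[[length(lens) + 1L]] <- enumerate_chords(fld)
    }
  }
  lens <- unlist(lens)
  if (length(lens) == 0) {
    return(structure(list(L = numeric(0), p = numeric(0), n_chords = 0L,
                          mean = NA_real_, seed = seed),
                     class = "chord_distribution"))
  }
  tab <- table(lens)
  L <- as.numeric(names(tab))
  p <- as.numeric(tab) / length(lens)
  structure(list(L = L, p = p, n_chords = length(lens),
                 mean = sum(L * p), seed = seed),
            class = "chord_distribution")
}

#' @export
print.chord_distribution <- function(x, ...) {
  cat(sprintf("Chord-length distribution: %d chords, mean L = %.3f\n",
              x$n_chords, x$mean))
  invisible(x)
}

#' Mean chord length (first moment)
#' @param p a `chord_distribution`.
#' @return `sum(L * P(L))` in sigma.
#' @export
mean_chord <- function(p) {
  stopifnot(inherits(p, "chord_distribution"))
  sum(p$L * p$p)
}

#' Mean domain length over a quench trajectory
#'
#' Computes the chord-length distribution at every snapshot and returns
#' the mean chord L(t). Several realization trajectories (same snapshot
#' schedule) may be supplied; their frames are pooled per time.
#'
#' @param trajectories a trajectory or list of trajectories with matching
#'   snapshot times.
#' @param params a [field_params()].
#' @param n_rotations orientations per frame (see [chord_distribution()]).
#' @param seed rotation RNG seed.
#' @param t_min ignore snapshots earlier than this (t = 0 is always kept
#'   as the initial reference).
#' @param thin analyze every `thin`-th positive-time snapshot (the
#'   reference frame and the final one are always kept); snapshots are
#'   log-spaced, so thinning keeps the log-time coverage uniform.
#' @return data.frame with columns `time`, `L`, `n_chords`.
#' @export
domain_length_series <- function(trajectories, params = field_params(),
                                 n_rotations = 2, seed = 1L, t_min = 0,
                                 thin = 1L) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  times <- common_times(trajectories)
  keep <- which(times <= 0 | times >= t_min)
  if (thin > 1L) {
    pos <- keep[times[keep] > 0]
    sel <- pos[unique(c(seq(1L, length(pos), by = thin), length(pos)))]
    keep <- sort(c(keep[times[keep] <= 0], sel))
  }
  out <- lapply(seq_along(keep), function(ii) {
    i <- keep[ii]
    frs <- lapply(trajectories, function(tr) tr$positions[[i]])
    cd <- chord_distribution(frs, params, n_rotations,
                             seed = seed + ii)
    data.frame(time = times[i], L = cd$mean, n_chords = cd$n_chords)
  })
  do.call(rbind, out)
}

#' Relative domain size C(t)
#'
#' `C(t) = (L(t) - L(0)) / (L(Inf) - L(0))`, a normalized mean chord
#' length growing from 0 at the quench instant to 1 at the collapsed
#' plateau. `L(0)` is the first post-quench value; `L(Inf)` is the average
#' over the final collapsed plateau (the trailing half decade of log
#' time). The half-collapse time `tau_half`, defined by
#' `C(tau_half) = 0.5`, is found by linear interpolation of C versus
#' log t; it is the natural unit for comparing quenches (time-temperature
#' superposition).
#'
#' @param series data.frame with columns `time` and `L` (from
#'   [domain_length_series()]), or separate vectors via `L`.
#' @param L optional numeric vector when `series` is a time vector.
#' @return object of class `domain_growth`: data.frame `curve`
#'   (time, L, C), `L0`, `Linf`, `tau_half`.
#' @export
relative_domain_size <- function(series, L = NULL) {
  if (!is.null(L)) series <- data.frame(time = series, L = L)
  stopifnot(all(c("time", "L") %in% names(series)))
  if (anyNA(series$L)) {
    warning("dropping ", sum(is.na(series$L)),
            " frames with no chords (empty mask)")
    series <- series[is.finite(series$L), ]
  }
  series <- series[order(series$time), ]
  tmax <- max(series$time)
  L0 <- series$L[1]
  plateau <- series$time >= tmax / sqrt(10)
  Linf <- mean(series$L[plateau])
  if (abs(Linf - L0) < .Machine$double.eps^0.5) {
    stop("degenerate normalization: L(Inf) = L(0)")
  }
  C <- (series$L - L0) / (Linf - L0)
  pos <- series$time > 0
  th <- NA_real_
  cross <- which(C[pos] >= 0.5)
  if (length(cross)) {
    i2 <- which(pos)[cross[1]]
    if (cross[1] == 1L || C[i2 - 1L] >= 0.5) {
      th <- series$time[i2]
    } else {
      i1 <- i2 - 1L
      w <- (0.5 - C[i1]) / (C[i2] - C[i1])
      th <- exp((1 - w) * log(series$time[i1]) + w * log(series$time[i2]))
    }
  } else {
    warning("C(t) never reaches 0.5; tau_half undefined")
  }
  structure(list(curve = data.frame(time = series$time, L = series$L, C = C),
                 L0 = L0, Linf = Linf, tau_half = th),
            class = "domain_growth")
}

#' @export
print.domain_growth <- function(x, ...) {
  cat(sprintf("Domain growth: L %g -> %g, tau_half = %g (%d points)\n",
              x$L0, x$Linf, x$tau_half, nrow(x$curve)))
  invisible(x)
}

#' Power-law exponent of a growth curve
#'
#' Least-squares slope of log(value) versus log(time) inside a window on
#' the value; the default window `0.05 <= C <= 0.5` selects the
#' intermediate coarsening regime. For collapsing flexible systems the
#' relative domain size grows as `C ~ t^0.56`; semiflexible chains are
#' steeper (`~ t^0.8`) and microgels slightly above the flexible value.
#'
#' @param curve a `domain_growth` object, or a data.frame with `time` and
#'   a value column named by `value`.
#' @param window inclusive (low, high) window on the value.
#' @param value column to fit (default `"C"`).
#' @return object of class `power_law_fit`: `exponent`, `se`, `r_squared`,
#'   `window`, `n_points`, `t_range`.
#' @export
fit_power_law <- function(curve, window = c(0.05, 0.5), value = "C") {
  df <- if (inherits(curve, "domain_growth")) curve$curve else curve
  sel <- df$time > 0 & df[[value]] >= window[1] & df[[value]] <= window[2] &
    df[[value]] > 0
  if (sum(sel) < 3) {
    stop("too few points (", sum(sel), ") in the fit window [",
         window[1], ", ", window[2], "]")
  }
  tt <- df$time[sel]; vv <- df[[value]][sel]
  if (diff(range(log10(tt))) < 1) {
    warning("fit window spans less than one decade in time")
  }
  fit <- stats::lm(log(vv) ~ log(tt))
  sm <- summary(fit)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 window = window, n_points = sum(sel),
                 t_range = range(tt)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: exponent %.3f +/- %.3f (R2 = %.3f, %d points, t in [%.3g, %.3g])\n",
              x$exponent, x$se, x$r_squared, x$n_points,
              x$t_range[1], x$t_range[2]))
  invisible(x)
}
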