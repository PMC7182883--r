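#' Spin self-correlation of the density field
#'
#' Each cell of the density field carries a spin `S = 1` (filled,
#' `rho_bar > rho_min`) or `S = 0` (empty); the self-correlation
#' `Ps(t) = <S(t) S(0)> - <S(t)> <S(0)>` measures how long the filled
#' structure remembers its initial arrangement. Cell identity across time
#' is defined in the center-of-mass frame with fixed axis orientation (the
#' grid is anchored to the instantaneous COM), and the average runs over a
#' fixed bounding region containing the filled sets of every analyzed
#' frame. `Ps(0) = <S>(1 - <S>)` exactly; a static mask keeps that value
#' forever, while independently reshuffled masks decorrelate to 0. During
#' the collapse Ps decays as a power law `t^-y` (microgels: y >~ 0.5) and
#' scales with the growing domain length as `Ps ~ L^-1.1` for flexible
#' systems.
#'
#' @param trajectories a trajectory or list of trajectories (realizations
#'   with matching snapshot times; Ps is averaged over realizations).
#' @param params a [field_params()].
#' @param L optional data.frame with `time`, `L` (from
#'   [domain_length_series()]) to form the paired (L, Ps) relation.
#' @param t_min first positive time included (t = 0 is the reference).
#' @return object of class `spin_correlation`: data.frame `series`
#'   (time, Ps), `Ps0`, optional `pairs` (L, Ps) and fitted exponents
#'   `decay_exponent` (Ps ~ t^-y) and `L_exponent` (Ps ~ L^slope).
#' @export
spin_autocorrelation <- function(trajectories, params = field_params(),
                                 L = NULL, t_min = 0) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  times <- common_times(trajectories)
  keep <- which(times <= 0 | times >= t_min)

  per_real <- lapply(trajectories, function(tr) {
    # COM-frame filled masks on per-frame grids, then re-embedded into the
    # common bounding region of all frames
    masks <- lapply(keep, function(i) {
      pos <- tr$positions[[i]]
      fld <- density_field(sweep(pos, 2, colMeans(pos)), params)
      # cell index range of this grid in units of delta about the COM
      lo <- round(fld$origin / params$delta)
      list(filled = fld$filled, lo = lo)
    })
    # fixed averaging region: bounding box of the union of filled sets
    # (not whole grids, whose empty margins would swamp the average)
    bounds <- lapply(masks, function(m) {
      idx <- which(m$filled, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      rbind(m$lo + apply(idx, 2, min) - 1L, m$lo + apply(idx, 2, max))
    })
    bounds <- Filter(Negate(is.null), bounds)
    if (length(bounds) == 0) stop("no filled cells in any analyzed frame")
    lo <- apply(do.call(rbind, lapply(bounds, function(b) b[1, ])), 2, min)
    hi <- apply(do.call(rbind, lapply(bounds, function(b) b[2, ])), 2, max)
    dims <- hi - lo
    embed <- function(m) {
      # clipped copy of the frame's mask into the common region
      S <- array(FALSE, dims)
      gs <- m$lo
      d <- dim(m$filled)
      a <- pmax(gs + 1L, lo + 1L)
      b <- pmin(gs + d, hi)
      if (any(a > b)) return(S)
      S[(a[1] - lo[1]):(b[1] - lo[1]),
        (a[2] - lo[2]):(b[2] - lo[2]),
        (a[3] - lo[3]):(b[3] - lo[3])] <-
        m$filled[(a[1] - gs[1]):(b[1] - gs[1]),
                 (a[2] - gs[2]):(b[2] - gs[2]),
                 (a[3] - gs[3]):(b[3] - gs[3])]
      S
    }
    S0 <- embed(masks[[1]])
    m0 <- mean(S0)
    vapply(masks, function(m) {
      S <- embed(m)
      mean(S & S0) - mean(S) * m0
    }, numeric(1))
  })
  ps <- rowMeans(do.call(cbind, per_real))
  series <- data.frame(time = times[keep], Ps = ps)
  out <- list(series = series, Ps0 = ps[1])
  # power-law decay fit over positive times where Ps has dropped clearly
  # below its initial value but is still positive
  sel <- series$time > 0 & series$Ps > 0 &
    series$Ps <= 0.8 * ps[1] & series$Ps >= 0.02 * ps[1]
  if (sum(sel) >= 3) {
    f <- stats::lm(log(series$Ps[sel]) ~ log(series$time[sel]))
    out$decay_exponent <- -unname(stats::coef(f)[2])
    out$decay_se <- summary(f)$coefficients[2, 2]
  }
  if (!is.null(L)) {
    m <- merge(series, L[, c("time", "L")], by = "time")
    # the Ps(L) power law lives in the coarsening regime: once L reaches
    # its collapsed plateau the points stack vertically and would bias
    # the slope
    L0 <- m$L[which.min(m$time)]
    L_hi <- L0 + 0.85 * (max(m$L) - L0)
    m <- m[m$time > 0 & m$Ps > 0 & m$Ps <= 0.8 * ps[1] &
             m$Ps >= 0.02 * ps[1] & m$L > 0 & m$L <= L_hi, ]
    out$pairs <- m
    if (nrow(m) >= 3) {
      f <- stats::lm(log(m$Ps) ~ log(m$L))
      out$L_exponent <- unname(stats::coef(f)[2])
      out$L_se <- summary(f)$coefficients[2, 2]
    }
  }
  class(out) <- "spin_correlation"
  out
}

#' @export
print.spin_correlation <- function(x, ...) {
  cat(sprintf("Spin self-correlation: Ps(0) = %.4f, %d times",
              x$Ps0, nrow(x$series)))
  if (!is.null(x$decay_exponent)) {
    cat(sprintf(", decay exponent y = %.3f", x$decay_exponent))
  }
  if (!is.null(x$L_exponent)) {
    cat(sprintf(", Ps ~ L^%.2f", x$L_exponent))
  }
  cat("\n")
  invisible(x)
}
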