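#' Distinct-part van Hove correlation function
#'
#' The time-lagged generalisation of g(r): for each lag tau, the histogram of
#' minimum-image distances between reference positions at an origin frame t0
#' and target positions at t0 + tau, averaged over origins and normalised so
#' an uncorrelated system gives G(r, tau) = 1 (the standard distinct-part
#' normalisation; the lag-0 slice is the RDF over the origin frames).
#' Identical-atom pairs are excluded at every lag (distinct part). Cross-time
#' displacements are wrapped with the origin frame's cell; `strict_cells`
#' errors if any cell within a lag span deviates from its origin cell by more
#' than 1%.
#'
#' @param traj a [trajectory].
#' @param groups a [particle_groups].
#' @param grid a [radial_grid].
#' @param lags integer frame offsets (>= 0); converted to ps in the output
#'   using the trajectory's time step.
#' @param origin_stride use every `origin_stride`-th frame as a time origin.
#' @param density `"auto"`, a number (nm^-3), or a [bulk_density].
#' @param strict_cells error on cell fluctuation beyond 1% within a lag span.
#' @return object of class `vhf_result`: arrays `G` and `counts` indexed
#'   `[ref, target, lag, bin]`, `lags` (frames), `lags_ps`, origins-per-lag
#'   metadata, and the grid.
#' @export
compute_vhf <- function(traj, groups, grid = radial_grid(), lags = 0L,
                        origin_stride = 1L, density = "auto",
                        strict_cells = FALSE) {
  lags <- as.integer(lags)
  nf <- n_frames(traj)
  if (any(lags < 0L) || any(lags >= nf))
    domain_error("lags must satisfy 0 <= lag < n_frames")
  origin_stride <- as.integer(origin_stride)
  if (origin_stride < 1L) domain_error("origin_stride must be >= 1")
  origins_all <- seq(1L, nf, by = origin_stride)
  check_rmax_guard(traj, seq_len(nf), grid)
  nr <- length(groups$ref); nt <- length(groups$target); nl <- length(lags)
  dn <- list(ref = names(groups$ref), target = names(groups$target),
             lag = NULL, bin = NULL)
  G <- array(NA_real_, c(nr, nt, nl, grid$n_bins), dimnames = dn)
  counts <- array(0L, c(nr, nt, nl, grid$n_bins), dimnames = dn)
  n_origins <- integer(nl)
  for (li in seq_len(nl)) {
    tau <- lags[li]
    origins <- origins_all[origins_all + tau <= nf]
    if (!length(origins)) domain_error(sprintf("no valid origins for lag %d", tau))
    n_origins[li] <- length(origins)
    if (strict_cells) {
      for (t0 in origins) {
        c0 <- frame_cell(traj, t0); c1 <- frame_cell(traj, t0 + tau)
        if (max(abs(c1 - c0)) > 0.01 * max(abs(c0)))
          cell_error(sprintf(
            "cells differ by more than 1%% between frames %d and %d", t0,
            t0 + tau))
      }
    }
    for (a in seq_len(nr)) for (b in seq_len(nt)) {
      ra <- groups$ref[[a]]; tb <- groups$target[[b]]
      acc <- integer(grid$n_bins)
      self <- outer(ra, tb, "==")
      for (t0 in origins) {
        cell <- frame_cell(traj, t0)
        xa <- matrix(traj$xyz[t0, ra, ], length(ra), 3)
        xb <- matrix(traj$xyz[t0 + tau, tb, ], length(tb), 3)
        d <- pair_distances(xa, xb, cell)
        d[self] <- Inf
        acc <- acc + bin_distances(d, grid)
      }
      counts[a, b, li, ] <- acc
      dens <- resolve_density(density, traj, origins, length(tb))
      # divide by the origin count first: a statically frozen trajectory then
      # yields bit-identical G slices at every lag
      G[a, b, li, ] <- (acc / length(origins)) /
        (grid$shell_volumes * dens$value * length(ra))
    }
  }
  structure(list(G = G, counts = counts, grid = grid, lags = lags,
                 lags_ps = lags * if (nf > 1) diff(traj$time[1:2]) else 0,
                 n_origins = n_origins),
            class = "vhf_result")
}

#' @export
print.vhf_result <- function(x, ...) {
  cat(sprintf("<vhf_result> lags (frames): %s; origins per lag: %s\n",
              paste(x$lags, collapse = ", "),
              paste(x$n_origins, collapse = ", ")))
  invisible(x)
}
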