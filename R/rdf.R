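#' Uniform radial histogram grid
#'
#' Half-open bins `[edge_k, edge_{k+1})`; a distance exactly at `r_max` is not
#' counted. Defaults (`r_max` 2 nm, 0.005 nm bins) resolve first and second
#' hydration shells and comfortably contain the 0.70 nm Bjerrum-length cutoff.
#'
#' @param r_min,r_max radial range (nm).
#' @param n_bins number of uniform bins.
#' @return object of class `radial_grid` with `edges`, `centers`, `dr` and the
#'   per-bin shell volumes `shell_volumes` (nm^3).
#' @export
radial_grid <- function(r_min = 0, r_max = 2.0, n_bins = 400L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) domain_error("n_bins must be >= 1")
  if (r_min < 0 || r_max <= r_min) domain_error("need 0 <= r_min < r_max")
  edges <- seq(r_min, r_max, length.out = n_bins + 1L)
  structure(list(r_min = r_min, r_max = r_max, n_bins = n_bins,
                 dr = (r_max - r_min) / n_bins, edges = edges,
                 centers = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                 shell_volumes = shell_volume(edges[-(n_bins + 1L)], edges[-1])),
            class = "radial_grid")
}

#' Histogram a block of pair distances onto a radial grid
#'
#' @param block distance block from [distance_block()], or a bare numeric
#'   matrix/vector of distances (nm).
#' @param grid a [radial_grid].
#' @param exclude_self skip identical-atom pairs (requires a block with
#'   `self_pairs`); a bare matrix has no identity information and is counted
#'   as-is.
#' @return integer vector of per-bin pair counts; distances at or beyond
#'   `r_max` are ignored.
#' @export
bin_distances <- function(block, grid, exclude_self = TRUE) {
  if (is.list(block)) {
    d <- block$values
    if (exclude_self && !is.null(block$self_pairs)) d <- d[!block$self_pairs]
  } else d <- block
  d <- as.numeric(d)
  d <- d[d >= grid$r_min & d < grid$r_max]
  if (!length(d)) return(integer(grid$n_bins))
  idx <- findInterval(d, grid$edges, left.open = FALSE, rightmost.closed = FALSE)
  tabulate(idx, nbins = grid$n_bins)
}

#' Bulk number density of the target species
#'
#' The pair-correlation normalisation needs the density the target species
#' would have far from any reference ("bulk"). By default it is estimated as
#' the target count divided by the mean cell volume over the frames in scope;
#' a user override supports cross-simulation comparability.
#'
#' @param traj a [trajectory].
#' @param frames frame indices in scope.
#' @param n_target number of target particles.
#' @return object of class `bulk_density`: `value` (nm^-3) and `source`.
#' @export
estimate_bulk_density <- function(traj, frames, n_target) {
  if (!length(frames)) domain_error("frame set must be non-empty")
  vols <- vapply(frames, function(f) det(frame_cell(traj, f)), numeric(1))
  if (any(vols <= 0)) cell_error("non-positive cell volume encountered")
  bulk_density(n_target / mean(vols), source = "estimated-from-box")
}

#' @rdname estimate_bulk_density
#' @param value density in particles per nm^3.
#' @param source provenance tag.
#' @export
bulk_density <- function(value, source = "user-supplied") {
  if (!is.finite(value) || value <= 0)
    domain_error("bulk density must be positive")
  structure(list(value = value, source = source), class = "bulk_density")
}

check_rmax_guard <- function(traj, frames, grid) {
  for (f in frames) {
    w <- min_cell_width(frame_cell(traj, f))
    if (grid$r_max > w / 2 + 1e-12)
      pbc_range_error(sprintf(
        "PBC range: r_max = %.4g nm exceeds half the minimal cell width (%.4g nm) at frame %d; minimum-image histograms beyond that are ambiguous",
        grid$r_max, w / 2, f))
  }
  invisible(TRUE)
}

# Shared accumulation: per (ref, target) pair, per frame block of `frames`,
# returns counts summed over the block and the number of self pairs excluded.
accumulate_counts <- function(traj, ref_idx, target_idx, grid, frames) {
  counts <- integer(grid$n_bins)
  n_self <- 0L
  for (f in frames) {
    blk <- distance_block(traj, f, ref_idx, target_idx)
    counts <- counts + bin_distances(blk, grid, exclude_self = TRUE)
    n_self <- n_self + sum(blk$self_pairs)
  }
  list(counts = counts, n_self = n_self)
}

resolve_density <- function(density, traj, frames, n_target) {
  if (inherits(density, "bulk_density")) density
  else if (identical(density, "auto"))
    estimate_bulk_density(traj, frames, n_target)
  else if (is.numeric(density) && length(density) == 1L) bulk_density(density)
  else domain_error("density must be \"auto\", a number, or a bulk_density")
}

#' Whole-trajectory radial distribution function
#'
#' For every (reference group, target group) pair, accumulates minimum-image
#' pair distances over the frames into the radial grid and normalises by the
#' shell volume, the bulk target density, the reference count and the frame
#' count, so an uncorrelated ("ideal gas") system gives g(r) = 1 at every r.
#' Identical-atom pairs (an atom present in both groups) are excluded.
#'
#' @param traj a [trajectory].
#' @param groups a [particle_groups].
#' @param grid a [radial_grid]; `r_max` must not exceed half the minimal cell
#'   width of any frame in scope.
#' @param density `"auto"` (target count over mean cell volume), a number
#'   (nm^-3), or a [bulk_density].
#' @param frames frame indices to use (default: all).
#' @return object of class `rdf_result`: arrays `g` and `counts` indexed
#'   `[ref, target, bin]`, the grid, and normalisation metadata.
#' @export
compute_rdf <- function(traj, groups, grid = radial_grid(), density = "auto",
                        frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  check_rmax_guard(traj, frames, grid)
  nr <- length(groups$ref); nt <- length(groups$target)
  dn <- list(ref = names(groups$ref), target = names(groups$target),
             bin = NULL)
  g <- array(NA_real_, c(nr, nt, grid$n_bins), dimnames = dn)
  counts <- array(0L, c(nr, nt, grid$n_bins), dimnames = dn)
  rho <- matrix(NA_real_, nr, nt,
                dimnames = dn[c("ref", "target")])
  self_excl <- matrix(0L, nr, nt, dimnames = dn[c("ref", "target")])
  for (a in seq_len(nr)) for (b in seq_len(nt)) {
    ra <- groups$ref[[a]]; tb <- groups$target[[b]]
    acc <- accumulate_counts(traj, ra, tb, grid, frames)
    dens <- resolve_density(density, traj, frames, length(tb))
    counts[a, b, ] <- acc$counts
    rho[a, b] <- dens$value
    self_excl[a, b] <- acc$n_self
    g[a, b, ] <- acc$counts /
      (grid$shell_volumes * dens$value * length(ra) * length(frames))
  }
  structure(list(g = g, counts = counts, grid = grid,
                 meta = list(n_frames = length(frames), frames = frames,
                             rho_bulk = rho,
                             n_ref = lengths(groups$ref),
                             n_target = lengths(groups$target),
                             self_pairs_excluded = self_excl,
                             density_source =
                               if (identical(density, "auto"))
                                 "estimated-from-box" else "user-supplied")),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  d <- dim(x$g)
  cat(sprintf("<rdf_result> %d ref x %d target group(s), %d bins (dr = %.4g nm, r_max = %.4g nm), %d frames\n",
              d[1], d[2], x$grid$n_bins, x$grid$dr, x$grid$r_max,
              x$meta$n_frames))
  invisible(x)
}
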