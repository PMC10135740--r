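#' Time-resolved radial distribution function
#'
#' Computes one RDF per contiguous time window, preserving the temporal
#' structure a whole-trajectory mean would average away — the motivating use
#' case being intrinsically disordered proteins transitioning between
#' meta-stable states, where ion environments differ between conformations.
#' Each window is normalised with its own frame count and (in auto mode) its
#' own mean cell volume, so NPT volume fluctuations do not couple windows.
#' Frames are streamed one at a time per (reference, target) pair; the full
#' frames-by-pairs distance tensor is never held in memory.
#'
#' @param traj a [trajectory].
#' @param groups a [particle_groups].
#' @param grid a [radial_grid].
#' @param scheme a [window_scheme].
#' @param density `"auto"`, a number (nm^-3), or a [bulk_density].
#' @return object of class `trrdf_result`: arrays `g` and `counts` indexed
#'   `[ref, target, window, bin]`, per-window metadata (`windows` data frame),
#'   the grid, and normalisation metadata.
#' @export
compute_trrdf <- function(traj, groups, grid = radial_grid(),
                          scheme, density = "auto") {
  blocks <- partition_windows(n_frames(traj), scheme)
  all_frames <- unlist(blocks)
  if (length(all_frames)) check_rmax_guard(traj, all_frames, grid)
  nr <- length(groups$ref); nt <- length(groups$target); nw <- length(blocks)
  dn <- list(ref = names(groups$ref), target = names(groups$target),
             window = NULL, bin = NULL)
  g <- array(NA_real_, c(nr, nt, nw, grid$n_bins), dimnames = dn)
  counts <- array(0L, c(nr, nt, nw, grid$n_bins), dimnames = dn)
  rho <- array(NA_real_, c(nr, nt, nw))
  for (a in seq_len(nr)) for (b in seq_len(nt)) {
    ra <- groups$ref[[a]]; tb <- groups$target[[b]]
    for (w in seq_len(nw)) {
      fr <- blocks[[w]]
      acc <- accumulate_counts(traj, ra, tb, grid, fr)
      dens <- resolve_density(density, traj, fr, length(tb))
      counts[a, b, w, ] <- acc$counts
      rho[a, b, w] <- dens$value
      g[a, b, w, ] <- acc$counts /
        (grid$shell_volumes * dens$value * length(ra) * length(fr))
    }
  }
  structure(list(g = g, counts = counts, grid = grid,
                 frame_blocks = blocks,
                 windows = window_metadata(blocks, traj$time),
                 meta = list(n_ref = lengths(groups$ref),
                             n_target = lengths(groups$target),
                             rho_bulk = rho, scheme = scheme)),
            class = "trrdf_result")
}

#' @export
print.trrdf_result <- function(x, ...) {
  d <- dim(x$g)
  cat(sprintf("<trrdf_result> %d ref x %d target group(s), %d window(s) x %d bins\n",
              d[1], d[2], d[3], d[4]))
  if (nrow(x$windows))
    cat(sprintf("  windows of %d frame(s), starting at %.4g ps\n",
                x$windows$n_frames[1], x$windows$start_time_ps[1]))
  invisible(x)
}

#' Running coordination number n(r)
#'
#' The cumulative expected count of target particles within radius r of a
#' reference particle, per window: the cumulative pair count divided by the
#' reference count and the window's frame count. This count-based form needs
#' no bulk density, which matters when targets belong to a larger biomolecule
#' or the cell volume fluctuates. For dilute targets such as ions the values
#' are typically fractional and read as the likelihood of finding a target
#' within r during the window. Equivalently derivable by integrating g(r)
#' against the shell volumes and the bulk density (`mode = "from-rdf"`); the
#' two routes agree to rounding.
#'
#' @param result a `trrdf_result` or `rdf_result` with raw counts retained.
#' @param mode `"from-counts"` (default, density-free) or `"from-rdf"`.
#' @return object of class `coordination_profile`: array `n` on the same
#'   `[ref, target, window, bin]` (or `[ref, target, bin]`) layout,
#'   non-decreasing in r.
#' @export
running_coordination <- function(result, mode = c("from-counts", "from-rdf")) {
  mode <- match.arg(mode)
  if (is.null(result$counts)) metadata_error("raw counts absent from result")
  grid <- result$grid
  windowed <- inherits(result, "trrdf_result")
  cum_along_bins <- function(x) {
    dims <- dim(x)
    nb <- dims[length(dims)]
    flat <- matrix(x, ncol = nb)
    out <- t(apply(flat, 1, cumsum))
    array(out, dims, dimnames = dimnames(x))
  }
  if (mode == "from-counts") {
    nf <- if (windowed) result$windows$n_frames else result$meta$n_frames
    n <- cum_along_bins(result$counts * 1.0)
    if (windowed) {
      for (a in seq_len(dim(n)[1])) for (w in seq_len(dim(n)[3]))
        n[a, , w, ] <- n[a, , w, , drop = FALSE] /
          (result$meta$n_ref[a] * nf[w])
    } else {
      for (a in seq_len(dim(n)[1]))
        n[a, , ] <- n[a, , , drop = FALSE] / (result$meta$n_ref[a] * nf)
    }
  } else {
    contrib <- result$g
    vr <- grid$shell_volumes
    if (windowed) {
      for (w in seq_len(dim(contrib)[3])) for (k in seq_len(grid$n_bins))
        contrib[, , w, k] <- contrib[, , w, k] *
          vr[k] * result$meta$rho_bulk[, , w]
    } else {
      for (k in seq_len(grid$n_bins))
        contrib[, , k] <- contrib[, , k] * vr[k] * result$meta$rho_bulk
    }
    n <- cum_along_bins(contrib)
  }
  structure(list(n = n, grid = grid,
                 windows = if (windowed) result$windows else NULL,
                 meta = result$meta, mode = mode),
            class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("<coordination_profile> (%s) dims: %s\n", x$mode,
              paste(dim(x$n), collapse = " x ")))
  invisible(x)
}

#' Average a windowed RDF back over time
#'
#' Unweighted mean over windows of g(r, W). When equal-size windows tile all
#' frames under a constant cell this reproduces the whole-trajectory RDF
#' bin-wise.
#'
#' @param result a `trrdf_result` with at least one window.
#' @return an `rdf_result` with summed counts and window-averaged g.
#' @export
window_average_rdf <- function(result) {
  nw <- dim(result$g)[3]
  if (nw < 1L) domain_error("result has no windows")
  g <- apply(result$g, c(1, 2, 4), mean)
  counts <- apply(result$counts, c(1, 2, 4), sum)
  dimnames(g) <- dimnames(counts) <-
    dimnames(result$g)[c("ref", "target", "bin")]
  structure(list(g = g, counts = counts, grid = result$grid,
                 meta = list(n_frames = sum(result$windows$n_frames),
                             rho_bulk = apply(result$meta$rho_bulk, c(1, 2), mean),
                             n_ref = result$meta$n_ref,
                             n_target = result$meta$n_target,
                             averaged_over_windows = nw)),
            class = "rdf_result")
}
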