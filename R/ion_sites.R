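# Protein-facing conventions for ion-distribution profiling: per-residue
# carbon interaction sites, the Bjerrum-length cutoff, mean ion counts per
# residue, window-to-cluster aggregation, and residue distance/contact maps.

#' Bjerrum length
#'
#' The distance at which the electrostatic interaction energy of two unit
#' charges in a dielectric medium equals the thermal energy k_B*T. In water
#' (relative permittivity ~80) at 300 K it is 0.70 nm — a meaningful distance
#' at which to compare local ion distributions around biomolecules, and the
#' package's default ion-shell cutoff.
#'
#' @param temperature absolute temperature (K), > 0.
#' @param relative_permittivity dimensionless dielectric constant, > 0.
#' @return length in nm (CODATA constants).
#' @export
bjerrum_length <- function(temperature = 300, relative_permittivity = 80) {
  if (temperature <= 0) domain_error("temperature must be positive")
  if (relative_permittivity <= 0)
    domain_error("relative permittivity must be positive")
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  kB <- 1.380649e-23        # J/K
  1e9 * e^2 / (4 * pi * eps0 * relative_permittivity * kB * temperature)
}

#' Packaged per-residue ion-interaction site table
#'
#' Maps residue names to the carbon atom used as that residue's
#' ion-interaction site: a carbon two heavy-atom bonds from the residue's
#' charge donor/acceptor. Residues absent from the table fall back to the
#' alpha-carbon. The table is a reconstruction against standard amino-acid
#' connectivity; pass a custom file with the same three-column layout
#' (resname, atom, anchor; tab-separated, `#` comments) to override it.
#'
#' @param path optional path to a user table.
#' @return data.frame with columns `resname`, `atom`, `anchor` and attribute
#'   `provenance` (`"default"` or `"user"`).
#' @export
ion_site_table <- function(path = NULL) {
  provenance <- if (is.null(path)) "default" else "user"
  if (is.null(path))
    path <- system.file("extdata", "ion_sites.tsv", package = "trrdf",
                        mustWork = TRUE)
  tb <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          col.names = c("resname", "atom", "anchor"),
                          stringsAsFactors = FALSE)
  attr(tb, "provenance") <- provenance
  tb
}

#' Resolve per-residue ion-interaction sites against a topology
#'
#' @param traj a [trajectory] (or a topology data.frame).
#' @param table an [ion_site_table()].
#' @param verify_carbon error if a designated site resolves to a non-carbon.
#' @return list with `groups` (named list `res<resid>` -> atom index vector,
#'   suitable as reference groups), `residues` (data.frame resid, resname,
#'   atom used, fallback flag) and the `table` used. Residues without any
#'   carbon atom are skipped with a warning.
#' @export
default_ion_sites <- function(traj, table = ion_site_table(),
                              verify_carbon = TRUE) {
  top <- if (is.data.frame(traj)) traj else traj$topology
  groups <- list(); rows <- list()
  for (rid in unique(top$resid)) {
    sel <- top$resid == rid
    resname <- toupper(top$resname[sel][1])
    hit <- table$atom[match(resname, toupper(table$resname))]
    fallback <- is.na(hit)
    atom <- if (fallback) "CA" else hit
    idx <- which(sel & toupper(top$name) == toupper(atom))
    if (!length(idx)) {  # fall back to alpha-carbon, then any carbon
      idx <- which(sel & toupper(top$name) == "CA")
      atom <- "CA"; fallback <- TRUE
    }
    if (!length(idx)) {
      idx <- which(sel & toupper(top$element) == "C")[1]
      idx <- idx[!is.na(idx)]
      atom <- if (length(idx)) top$name[idx] else NA_character_
      fallback <- TRUE
    }
    if (!length(idx)) {
      warning(sprintf("residue %s %s has no carbon atoms; skipped",
                      resname, rid))
      next
    }
    if (fallback && is.na(match(resname, toupper(table$resname))))
      message(sprintf("residue %s not in site table; using %s", resname, atom))
    if (verify_carbon && any(toupper(top$element[idx]) != "C"))
      topology_error(sprintf(
        "designated site %s of residue %s %s is not a carbon", atom, resname,
        rid))
    groups[[paste0("res", rid)]] <- idx
    rows[[length(rows) + 1L]] <- data.frame(
      resid = rid, resname = resname, atom = atom, fallback = fallback,
      stringsAsFactors = FALSE)
  }
  list(groups = groups, residues = do.call(rbind, rows), table = table)
}

cutoff_bin <- function(grid, cutoff) {
  outer_edges <- grid$edges[-1]
  if (cutoff < outer_edges[1] - 1e-9)
    domain_error("cutoff lies below the first bin's outer edge")
  if (cutoff > grid$r_max + 1e-9)
    domain_error("cutoff exceeds the grid's r_max")
  max(which(outer_edges <= cutoff + 1e-9))
}

#' Mean ion count per residue within a cutoff
#'
#' Reads the running coordination number at the largest bin edge not
#' exceeding the cutoff — the "integral of g(r)" up to the second hydration
#' shell when the default 0.70 nm Bjerrum-length cutoff is used — for every
#' (residue reference group, ion target group, window), then averages over
#' windows, optionally per conformational cluster.
#'
#' @param coord a `coordination_profile` from a windowed analysis whose
#'   reference groups are per-residue site groups named `res<resid>`.
#' @param cutoff shell radius (nm), default 0.70.
#' @param clusters optional per-window cluster labels (NA = unassigned), as
#'   from [assign_windows_to_clusters()].
#' @return data.frame with columns `resid`, `ion` (target group name),
#'   `cluster` (NA when unclustered), `mean_count`, `n_windows`, `cutoff_nm`.
#' @export
per_residue_ion_counts <- function(coord, cutoff = 0.70, clusters = NULL) {
  if (length(dim(coord$n)) != 4L)
    metadata_error("a windowed coordination profile is required")
  k <- cutoff_bin(coord$grid, cutoff)
  dn <- dimnames(coord$n)
  refs <- dn[[1]]; ions <- dn[[2]]
  nw <- dim(coord$n)[3]
  if (is.null(clusters)) clusters <- rep(NA_integer_, nw)
  if (length(clusters) != nw)
    metadata_error("cluster labels must cover every window")
  resid <- suppressWarnings(as.integer(sub("^res", "", refs)))
  out <- list()
  for (cl in unique(clusters)) {
    wsel <- if (is.na(cl)) is.na(clusters) else !is.na(clusters) & clusters == cl
    if (!any(wsel)) next
    for (b in seq_along(ions)) {
      vals <- coord$n[, b, wsel, k, drop = FALSE]
      mean_count <- apply(array(vals, c(length(refs), sum(wsel))), 1, mean)
      out[[length(out) + 1L]] <- data.frame(
        resid = resid, ion = ions[b], cluster = cl,
        mean_count = mean_count, n_windows = sum(wsel), cutoff_nm = cutoff,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Assign time windows to conformational clusters
#'
#' Clusters are consumed as input (e.g., from a published trajectory
#' clustering); each window receives the majority label of the frames it
#' spans, with exact ties left unassigned (NA).
#'
#' @param result a `trrdf_result` (its window frame blocks are used) or a
#'   list of frame-index blocks.
#' @param frame_labels per-frame cluster labels, indexed by trajectory frame.
#' @param frame_map optional function mapping a trajectory frame index to the
#'   index into `frame_labels` (identity by default), for label trajectories
#'   stored at a different interval.
#' @return integer vector of per-window labels (NA = unassigned).
#' @export
assign_windows_to_clusters <- function(result, frame_labels,
                                       frame_map = identity) {
  blocks <- if (inherits(result, "trrdf_result")) result$frame_blocks
            else result
  if (is.null(blocks)) metadata_error("window frame blocks unavailable")
  vapply(blocks, function(b) {
    li <- frame_map(b)
    if (any(li < 1L) || any(li > length(frame_labels)))
      metadata_error("no temporal overlap between labels and windows")
    labs <- frame_labels[li]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) return(NA_integer_)
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) NA_integer_ else as.integer(winners)
  }, integer(1))
}

#' Residue distance map and contact mask
#'
#' Mean over frames of the minimum-image distance between residue
#' representative atoms (alpha-carbon by default, the common convention for
#' residue distance maps; `mode = "min"` instead uses the per-frame minimum
#' over all atom pairs of the two residues). Contacts are residue pairs whose
#' mean distance is at or below the cutoff (default 0.5 nm).
#'
#' @param traj a [trajectory].
#' @param frames frame indices (default: all).
#' @param representative atom name used per residue (first atom of the
#'   residue if absent).
#' @param mode `"representative"` or `"min"` (min over atom pairs per frame).
#' @param contact_cutoff contact threshold (nm).
#' @return list with `distance` (symmetric matrix, nm, zero diagonal),
#'   `contact` (logical matrix), `resid` (residue ids), `contact_cutoff`.
#' @export
residue_distance_map <- function(traj, frames = NULL, representative = "CA",
                                 mode = c("representative", "min"),
                                 contact_cutoff = 0.5) {
  mode <- match.arg(mode)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) domain_error("frame set must be non-empty")
  top <- traj$topology
  rids <- unique(top$resid)
  nres <- length(rids)
  atom_sets <- lapply(rids, function(r) which(top$resid == r))
  reps <- vapply(seq_along(rids), function(i) {
    s <- atom_sets[[i]]
    hit <- s[toupper(top$name[s]) == toupper(representative)]
    if (length(hit)) hit[1] else s[1]
  }, integer(1))
  acc <- matrix(0, nres, nres)
  for (f in frames) {
    cell <- frame_cell(traj, f)
    if (mode == "representative") {
      x <- matrix(traj$xyz[f, reps, ], nres, 3)
      acc <- acc + pair_distances(x, x, cell)
    } else {
      for (i in seq_len(nres - 1L)) for (j in (i + 1L):nres) {
        xi <- matrix(traj$xyz[f, atom_sets[[i]], ], length(atom_sets[[i]]), 3)
        xj <- matrix(traj$xyz[f, atom_sets[[j]], ], length(atom_sets[[j]]), 3)
        m <- min(pair_distances(xi, xj, cell))
        acc[i, j] <- acc[i, j] + m
        acc[j, i] <- acc[j, i] + m
      }
    }
  }
  dist <- acc / length(frames)
  diag(dist) <- 0
  dimnames(dist) <- list(rids, rids)
  contact <- dist <= contact_cutoff
  diag(contact) <- FALSE
  list(distance = dist, contact = contact, resid = rids,
       contact_cutoff = contact_cutoff)
}
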