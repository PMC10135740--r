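#' Construct a trajectory object
#'
#' A `trajectory` bundles per-frame coordinates, per-frame triclinic unit
#' cells, per-frame timestamps and a topology table. All coordinates are in
#' nanometres and all times in picoseconds (the GROMACS convention), so the
#' field's standard cutoffs (0.70 nm ion shell, 0.5 nm residue contact) apply
#' directly.
#'
#' @param xyz numeric array `[n_frames, n_atoms, 3]` of coordinates (nm).
#' @param topology data.frame with one row per atom and columns `name`,
#'   `element`, `resname`, `resid`, `chain`.
#' @param cell either a single 3x3 matrix (rows = cell vectors, nm), broadcast
#'   to all frames, an array `[n_frames, 3, 3]`, or `NULL` for a non-periodic
#'   system (downstream periodic analyses then refuse to run).
#' @param time numeric vector of per-frame times (ps), strictly increasing.
#'   Defaults to `0, 1, 2, ...` ps.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(xyz, topology, cell = NULL, time = NULL) {
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    format_error("`xyz` must be an [n_frames, n_atoms, 3] array")
  n_frames <- dim(xyz)[1]
  n_atoms <- dim(xyz)[2]
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  required <- c("name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(required, names(topology))
  if (length(missing_cols))
    topology_error(paste0("topology lacks column(s): ",
                          paste(missing_cols, collapse = ", ")))
  if (nrow(topology) != n_atoms)
    topology_error(sprintf(
      "topology has %d atoms but coordinates have %d", nrow(topology), n_atoms))
  if (is.null(time)) time <- as.numeric(seq_len(n_frames) - 1L)
  if (length(time) != n_frames)
    format_error("`time` length must equal the number of frames")
  if (n_frames > 1 && any(diff(time) <= 0))
    format_error("frame times must be strictly increasing")
  if (!is.null(cell)) {
    if (is.matrix(cell)) {
      validate_cell(cell)
      cells <- array(rep(t(cell), n_frames), dim = c(3, 3, n_frames))
      cell <- aperm(cells, c(3, 2, 1))
    } else if (length(dim(cell)) == 3L) {
      if (dim(cell)[1] != n_frames || any(dim(cell)[2:3] != 3L))
        cell_error("per-frame cell array must be [n_frames, 3, 3]")
      for (f in seq_len(n_frames)) validate_cell(cell[f, , ])
    } else cell_error("`cell` must be a 3x3 matrix or [n_frames, 3, 3] array")
  }
  structure(list(xyz = xyz, topology = topology, cell = cell, time = time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, %d atoms, %s\n",
              n_frames(x), n_atoms(x),
              if (is.null(x$cell)) "no periodic cell" else "periodic cell"))
  cat(sprintf("  time %.4g .. %.4g ps, %d residues\n",
              x$time[1], x$time[length(x$time)],
              length(unique(x$topology$resid))))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$xyz)[2]

#' Per-frame unit cell, with a clear error when absent
#' @param traj a `trajectory`.
#' @param frame 1-based frame index.
#' @return 3x3 cell matrix (rows = cell vectors, nm).
#' @export
frame_cell <- function(traj, frame) {
  if (is.null(traj$cell))
    cell_error("trajectory has no unit-cell information but a periodic analysis was requested")
  traj$cell[frame, , , drop = TRUE]
}

#' Keep every `stride`-th frame of a trajectory
#' @param traj a `trajectory`.
#' @param stride keep frames 1, 1+stride, 1+2*stride, ...
#' @return a `trajectory` with the subset of frames.
#' @export
stride_trajectory <- function(traj, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) domain_error("stride must be >= 1")
  keep <- seq(1L, n_frames(traj), by = stride)
  subset_frames(traj, keep)
}

subset_frames <- function(traj, frames) {
  trajectory(traj$xyz[frames, , , drop = FALSE], traj$topology,
             cell = if (is.null(traj$cell)) NULL else
               traj$cell[frames, , , drop = FALSE],
             time = traj$time[frames])
}

#' Load a trajectory from file
#'
#' Reads multi-frame GRO, multi-model PDB, DCD (coordinates only; a GRO or
#' PDB topology file is then required) or the package's lossless CSV
#' trajectory table. Coordinates are converted to nm and times to ps on load.
#' XTC and TRR are not supported.
#'
#' @param trajectory_path path to the trajectory file.
#' @param topology_path optional topology file (GRO or PDB); required for DCD,
#'   otherwise overrides the topology embedded in the trajectory file.
#' @param stride keep every `stride`-th frame (applied after reading).
#' @return a `trajectory`.
#' @export
load_trajectory <- function(trajectory_path, topology_path = NULL, stride = 1L) {
  if (!file.exists(trajectory_path))
    format_error(paste0("trajectory file not found: ", trajectory_path))
  ext <- tolower(tools::file_ext(trajectory_path))
  traj <- switch(ext,
    gro = read_gro(trajectory_path),
    pdb = read_pdb_trajectory(trajectory_path),
    dcd = read_dcd_trajectory(trajectory_path, topology_path),
    csv = read_trajectory_table(trajectory_path),
    format_error(paste0("unsupported trajectory format: .", ext,
                        " (supported: gro, pdb, dcd, csv)"))
  )
  if (!is.null(topology_path) && ext != "dcd") {
    top <- read_topology(topology_path)
    if (nrow(top) != n_atoms(traj))
      topology_error(sprintf(
        "topology file has %d atoms, trajectory has %d",
        nrow(top), n_atoms(traj)))
    traj$topology <- top
  }
  if (stride > 1L) traj <- stride_trajectory(traj, stride) else traj
}

read_topology <- function(path) {
  if (!file.exists(path)) format_error(paste0("topology file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gro = read_gro(path)$topology,
    pdb = read_pdb_trajectory(path)$topology,
    format_error(paste0("unsupported topology format: .", ext)))
}

read_dcd_trajectory <- function(path, topology_path) {
  if (is.null(topology_path))
    topology_error("DCD files carry no topology; supply `topology_path` (GRO or PDB)")
  top <- read_topology(topology_path)
  dcd <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(dcd)
  na <- ncol(dcd) / 3L
  if (na != nrow(top))
    topology_error(sprintf("DCD has %d atoms, topology has %d", na, nrow(top)))
  xyz <- array(NA_real_, dim = c(nf, na, 3))
  for (k in 1:3) xyz[, , k] <- dcd[, seq(k, 3L * na, by = 3L), drop = FALSE]
  xyz <- xyz / 10  # Angstrom -> nm
  cell <- NULL
  cp <- attr(dcd, "cell")
  if (!is.null(cp)) {
    cell <- array(NA_real_, dim = c(nf, 3, 3))
    for (f in seq_len(nf))
      cell[f, , ] <- cell_from_parameters(cp[f, 1] / 10, cp[f, 2] / 10,
                                          cp[f, 3] / 10,
                                          cp[f, 4], cp[f, 5], cp[f, 6])
  }
  trajectory(xyz, top, cell = cell)
}

#' Read a 0-based NDX-like atom index file
#'
#' Whitespace- or comma-separated integer atom indices, 0-based as in the
#' usual exchange convention; converted to R's 1-based indices on read.
#' Lines starting with `#` or `;` are comments.
#'
#' @param path file path.
#' @return sorted integer vector of 1-based atom indices.
#' @export
read_index_file <- function(path) {
  if (!file.exists(path)) format_error(paste0("index file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#;]", lines)]
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[[:space:],]+"))
  toks <- toks[nzchar(toks)]
  idx <- suppressWarnings(as.integer(toks))
  if (anyNA(idx)) selection_error("index file contains non-integer tokens")
  if (any(idx < 0L)) selection_error("index file entries must be >= 0 (0-based)")
  sort(unique(idx)) + 1L
}
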