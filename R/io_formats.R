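# File format readers and writers: multi-frame GRO (hand parser; fixed-width
# text), multi-model PDB (via bio3d), and a lossless CSV trajectory table for
# bit-exact fixture round-trips. GRO/PDB coordinates are 3-decimal, so those
# round-trips are exact only to format precision (1e-3 nm / 1e-4 nm).

MONATOMIC_IONS <- c(NA. = "Na", CL = "Cl", K = "K", MG = "Mg", ZN = "Zn",
                    CA = "Ca", BR = "Br", F = "F", I = "I", LI = "Li",
                    RB = "Rb", CS = "Cs")
names(MONATOMIC_IONS)[1] <- "NA"

#' Guess an element symbol from atom and residue names
#'
#' Monatomic-ion names (NA, CL, MG, ...) map to their ion element only when
#' the residue name matches the atom name (so CA inside an amino acid stays
#' carbon, the alpha-carbon convention); otherwise the first alphabetic
#' character of the atom name is used.
#'
#' @param name atom name(s).
#' @param resname residue name(s), recycled.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name, resname = "") {
  name <- toupper(trimws(name))
  resname <- rep_len(toupper(trimws(resname)), length(name))
  out <- character(length(name))
  ion <- name %in% names(MONATOMIC_IONS) & name == resname
  out[ion] <- MONATOMIC_IONS[name[ion]]
  rest <- !ion
  first <- sub("^[^A-Z]*([A-Z]).*$", "\\1", name[rest])
  out[rest] <- first
  out
}

parse_gro_box <- function(line) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(v)) format_error("unparseable GRO box line")
  if (length(v) == 3L) {
    diag(v)
  } else if (length(v) == 9L) {
    # order: v1x v2y v3z v1y v1z v2x v2z v3x v3y
    rbind(c(v[1], v[4], v[5]),
          c(v[6], v[2], v[7]),
          c(v[8], v[9], v[3]))
  } else format_error("GRO box line must have 3 or 9 fields")
}

format_gro_box <- function(cell) {
  if (max(abs(cell[upper.tri(cell) | lower.tri(cell)])) < 1e-12) {
    sprintf("%10.5f%10.5f%10.5f", cell[1, 1], cell[2, 2], cell[3, 3])
  } else {
    paste0(sprintf("%10.5f", c(cell[1, 1], cell[2, 2], cell[3, 3],
                               cell[1, 2], cell[1, 3], cell[2, 1],
                               cell[2, 3], cell[3, 1], cell[3, 2])),
           collapse = "")
  }
}

#' Read a (multi-frame) GRO file
#'
#' Fixed-width GROMACS coordinate format; repeated frames are concatenated
#' blocks. Frame times are taken from a `t=` tag in the title line when
#' present, else frame numbers are used. Velocities, if present, are ignored.
#' GRO carries no chain or element information: chain is set to `"A"` and
#' elements are inferred with [guess_element()].
#'
#' @param path file path.
#' @return a [trajectory].
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list(); cells <- list(); times <- numeric(0)
  topology <- NULL
  while (pos <= length(lines) && nzchar(trimws(paste(lines[pos:min(pos + 1, length(lines))], collapse = "")))) {
    title <- lines[pos]
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat)) format_error("malformed GRO: bad atom-count line")
    if (pos + 1L + nat + 1L > length(lines))
      format_error("malformed GRO: truncated frame")
    atom_lines <- lines[(pos + 2L):(pos + 1L + nat)]
    xyz <- matrix(NA_real_, nat, 3)
    for (i in seq_len(nat)) {
      ln <- atom_lines[i]
      xyz[i, ] <- as.numeric(c(substr(ln, 21, 28), substr(ln, 29, 36),
                               substr(ln, 37, 44)))
    }
    if (anyNA(xyz)) format_error("malformed GRO: unparseable coordinates")
    if (is.null(topology)) {
      resid <- as.integer(substr(atom_lines, 1, 5))
      resname <- trimws(substr(atom_lines, 6, 10))
      name <- trimws(substr(atom_lines, 11, 15))
      topology <- data.frame(
        name = name, element = guess_element(name, resname),
        resname = resname, resid = resid, chain = "A",
        stringsAsFactors = FALSE)
    }
    cells[[length(cells) + 1L]] <- parse_gro_box(lines[pos + 2L + nat])
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm))
               else length(frames))
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + nat + 3L
  }
  if (!length(frames)) format_error("empty GRO file")
  nf <- length(frames); na <- nrow(topology)
  xyz <- array(NA_real_, c(nf, na, 3))
  cell <- array(NA_real_, c(nf, 3, 3))
  for (f in seq_len(nf)) { xyz[f, , ] <- frames[[f]]; cell[f, , ] <- cells[[f]] }
  if (any(duplicated(times))) times <- seq_len(nf) - 1
  trajectory(xyz, topology, cell = cell, time = times)
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("trrdf frame %d t= %.6f", f - 1L, traj$time[f]), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    x <- traj$xyz[f, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       top$resid %% 100000L, substr(top$resname, 1, 5),
                       substr(top$name, 1, 5), seq_len(nrow(top)) %% 100000L,
                       x[, 1], x[, 2], x[, 3]), con)
    writeLines(format_gro_box(frame_cell(traj, f)), con)
  }
  invisible(path)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Uses bio3d for parsing; coordinates are converted from Angstrom to nm and
#' the CRYST1 record, when present, to a reduced triclinic cell.
#'
#' @param path file path.
#' @return a [trajectory].
#' @export
read_pdb_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    e <- trimws(at$elesy)
    ifelse(nzchar(e),
           paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 10))),
           guess_element(at$elety, at$resid))
  } else guess_element(at$elety, at$resid)
  top <- data.frame(name = at$elety, element = elem, resname = at$resid,
                    resid = at$resno,
                    chain = ifelse(is.na(at$chain), "A", at$chain),
                    stringsAsFactors = FALSE)
  xyz_flat <- pdb$xyz
  if (is.null(dim(xyz_flat))) xyz_flat <- matrix(xyz_flat, nrow = 1)
  nf <- nrow(xyz_flat); na <- nrow(top)
  xyz <- array(NA_real_, c(nf, na, 3))
  for (k in 1:3) xyz[, , k] <- xyz_flat[, seq(k, 3L * na, 3L), drop = FALSE] / 10
  cell <- NULL
  cr <- pdb$cryst1
  if (!is.null(cr) && !is.null(cr$abc) && all(is.finite(cr$abc)) &&
      all(cr$abc > 0)) {
    ang <- if (!is.null(cr$abg)) cr$abg else c(90, 90, 90)
    cell <- cell_from_parameters(cr$abc[1] / 10, cr$abc[2] / 10, cr$abc[3] / 10,
                                 ang[1], ang[2], ang[3])
  }
  trajectory(xyz, top, cell = cell)
}

#' Lossless CSV trajectory table
#'
#' One row per atom per frame with full-precision coordinates, the frame's
#' cell vectors repeated on each row, and the topology columns. Exists so
#' fixtures can round-trip bit-exactly through a plain-text file, which the
#' 3-decimal GRO/PDB formats cannot provide.
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  top <- traj$topology[rep(seq_len(na), nf), ]
  frame <- rep(seq_len(nf) - 1L, each = na)
  cellcols <- matrix(NA_real_, nf * na, 9)
  for (f in seq_len(nf))
    cellcols[frame == f - 1L, ] <- matrix(rep(as.numeric(t(frame_cell(traj, f))),
                                              each = na), ncol = 9)
  df <- data.frame(frame = frame, time = rep(traj$time, each = na),
                   atom = rep(seq_len(na) - 1L, nf), top,
                   x = as.numeric(t(traj$xyz[, , 1])),
                   y = as.numeric(t(traj$xyz[, , 2])),
                   z = as.numeric(t(traj$xyz[, , 3])))
  colnames(cellcols) <- paste0("cell_", c("ax", "ay", "az", "bx", "by", "bz",
                                          "cx", "cy", "cz"))
  df <- cbind(df, cellcols)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(resid = "integer", chain = "character",
                                       name = "character"))
  nf <- length(unique(df$frame)); na <- nrow(df) / nf
  ord <- order(df$frame, df$atom)
  df <- df[ord, ]
  top <- df[seq_len(na), c("name", "element", "resname", "resid", "chain")]
  xyz <- array(NA_real_, c(nf, na, 3))
  xyz[, , 1] <- t(matrix(df$x, na, nf))
  xyz[, , 2] <- t(matrix(df$y, na, nf))
  xyz[, , 3] <- t(matrix(df$z, na, nf))
  cell <- array(NA_real_, c(nf, 3, 3))
  first_rows <- which(!duplicated(df$frame))
  cc <- as.matrix(df[first_rows, paste0("cell_", c("ax", "ay", "az", "bx",
                                                   "by", "bz", "cx", "cy",
                                                   "cz"))])
  for (f in seq_len(nf)) cell[f, , ] <- matrix(cc[f, ], 3, 3, byrow = TRUE)
  trajectory(xyz, top, cell = cell, time = df$time[first_rows])
}
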