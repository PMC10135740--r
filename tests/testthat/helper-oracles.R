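# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Minimum-image distance by exhaustive search over the 5x5x5 block of
# periodic images.
oracle_min_image <- function(x1, x2, cell) {
  shifts <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  d <- x2 - x1
  best <- Inf
  for (s in seq_len(nrow(shifts))) {
    v <- d + as.numeric(shifts[s, ] %*% cell)
    best <- min(best, sum(v * v))
  }
  sqrt(best)
}

oracle_pair_matrix <- function(xa, xb, cell) {
  out <- matrix(NA_real_, nrow(xa), nrow(xb))
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb)))
    out[i, j] <- oracle_min_image(xa[i, ], xb[j, ], cell)
  out
}

# Explicit-loop histogram with half-open bins [lo, hi).
oracle_hist <- function(d, edges) {
  counts <- integer(length(edges) - 1L)
  for (x in d) for (k in seq_along(counts)) {
    if (x >= edges[k] && x < edges[k + 1L]) {
      counts[k] <- counts[k] + 1L
      break
    }
  }
  counts
}

# Random reduced triclinic cell within the GROMACS off-diagonal bounds.
random_reduced_cell <- function() {
  dg <- stats::runif(3, 2, 4)
  m <- diag(dg)
  m[2, 1] <- stats::runif(1, -dg[1] / 2, dg[1] / 2) * 0.95
  m[3, 1] <- stats::runif(1, -dg[1] / 2, dg[1] / 2) * 0.95
  m[3, 2] <- stats::runif(1, -dg[2] / 2, dg[2] / 2) * 0.95
  m
}

# Random topology table for selection-grammar property tests.
random_topology <- function(n) {
  data.frame(
    name = sample(c("CA", "CB", "CL", "NA.", "N", "O", "CD"), n, TRUE),
    element = NA_character_,
    resname = sample(c("LYS", "GLY", "GLU", "CL", "SOL"), n, TRUE),
    resid = sample(0:9, n, TRUE),
    chain = sample(c("A", "B"), n, TRUE),
    stringsAsFactors = FALSE) -> top
  top$name <- sub("\\.", "", top$name)
  top$element <- guess_element(top$name, top$resname)
  top
}

# Minimal tripeptide-like topology with standard atom names.
peptide_topology <- function() {
  mk <- function(resid, resname, names) {
    data.frame(name = names,
               element = substr(names, 1, 1),
               resname = resname, resid = resid, chain = "A",
               stringsAsFactors = FALSE)
  }
  rbind(mk(0L, "LYS", c("N", "CA", "CB", "CG", "CD", "CE", "NZ", "C", "O")),
        mk(1L, "GLY", c("N", "CA", "C", "O")),
        mk(2L, "GLU", c("N", "CA", "CB", "CG", "CD", "OE1", "OE2", "C", "O")))
}

peptide_trajectory <- function(n_frames = 1L, box_edge = 6) {
  top <- peptide_topology()
  xyz <- array(0, c(n_frames, nrow(top), 3))
  set.seed(7)
  base <- matrix(stats::runif(nrow(top) * 3, 2, 4), nrow(top), 3)
  for (f in seq_len(n_frames)) xyz[f, , ] <- base
  trajectory(xyz, top, cell = diag(rep(box_edge, 3)))
}
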