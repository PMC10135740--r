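# Seeded synthetic-trajectory generators with analytically known pair
# statistics. These are first-class, tested generators (not throwaway test
# scaffolding): an ideal gas has g(r) = 1 exactly in expectation, lattices
# have exact neighbour shells, the two-particle generator scripts the pair
# distance per frame, and the random-walk generator emulates ions moving in
# and out of a hydration shell around frozen sites. Each generator is fully
# determined by its seed.

fixture_topology <- function(n, name, element, resname, resid = NULL) {
  data.frame(name = rep_len(name, n), element = rep_len(element, n),
             resname = rep_len(resname, n),
             resid = if (is.null(resid)) seq_len(n) - 1L else
               rep_len(resid, n),
             chain = "A", stringsAsFactors = FALSE)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

#' Ideal-gas trajectory: i.i.d. uniform positions each frame
#'
#' Expectation g(r) = 1 at every r; with `frozen = TRUE` the first frame is
#' repeated, giving static "dynamics" (useful for lag-invariance checks).
#'
#' @param n_particles number of particles (>= 2).
#' @param n_frames number of frames.
#' @param box_edge cubic cell edge (nm); or supply `cell` (3x3 matrix).
#' @param cell optional triclinic cell, overrides `box_edge`.
#' @param seed RNG seed; fully determines the output.
#' @param frozen repeat frame 1 instead of redrawing.
#' @return a [trajectory] (atoms named AR, one residue per atom).
#' @export
generate_ideal_gas <- function(n_particles, n_frames, box_edge = 2,
                               cell = NULL, seed = 1L, frozen = FALSE) {
  if (n_particles < 2L) domain_error("need at least 2 particles")
  if (is.null(cell)) cell <- diag(rep(box_edge, 3))
  validate_cell(cell)
  xyz <- with_seed(seed, {
    a <- array(NA_real_, c(n_frames, n_particles, 3))
    for (f in seq_len(n_frames)) {
      frac <- matrix(stats::runif(n_particles * 3), n_particles, 3)
      a[f, , ] <- if (frozen && f > 1L) a[1, , ] else frac %*% cell
    }
    a
  })
  trajectory(xyz, fixture_topology(n_particles, "AR", "Ar", "GAS"),
             cell = cell)
}

#' Static lattice trajectory with exact neighbour shells
#'
#' Simple cubic: 6 neighbours at a, 12 at a*sqrt(2), 8 at a*sqrt(3) (running
#' coordination 6/18/26). Face-centred cubic: 12 at a/sqrt(2). The cell is
#' `n_cells * lattice_constant` cubed, commensurate by construction.
#'
#' @param kind `"sc"` or `"fcc"`.
#' @param n_cells unit cells per edge (>= 2 so shells fit the half-cell rule).
#' @param lattice_constant conventional-cell edge a (nm).
#' @param n_frames identical frames to emit (frozen dynamics).
#' @return a [trajectory].
#' @export
generate_lattice <- function(kind = c("sc", "fcc"), n_cells = 4L,
                             lattice_constant = 1.0, n_frames = 1L) {
  kind <- match.arg(kind)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) domain_error("n_cells must be >= 1")
  a <- lattice_constant
  basis <- if (kind == "sc") matrix(0, 1, 3) else
    rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  g <- as.matrix(expand.grid(0:(n_cells - 1L), 0:(n_cells - 1L),
                             0:(n_cells - 1L)))
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b)
    (g + matrix(basis[b, ], nrow(g), 3, byrow = TRUE)) * a))
  cell <- diag(rep(n_cells * a, 3))
  xyz <- array(NA_real_, c(n_frames, nrow(pos), 3))
  for (f in seq_len(n_frames)) xyz[f, , ] <- pos
  trajectory(xyz, fixture_topology(nrow(pos), "AR", "Ar", "LAT"), cell = cell)
}

#' Two-particle trajectory with scripted per-frame separations
#'
#' One reference particle (default at the cell centre) and one target placed
#' at the scripted minimum-image separation along a scripted direction;
#' placing the reference near a face exercises separations across the
#' periodic boundary.
#'
#' @param separations numeric vector: pair distance (nm) per frame.
#' @param box_edge cubic cell edge (nm).
#' @param direction length-3 displacement direction (normalised internally).
#' @param ref_position optional reference position (nm); defaults to the cell
#'   centre.
#' @return a [trajectory] (atoms REF/carbon and CL/chloride).
#' @export
generate_two_particle <- function(separations, box_edge = 2,
                                  direction = c(1, 0, 0),
                                  ref_position = NULL) {
  if (any(separations < 0) || any(separations > box_edge / 2))
    domain_error("scripted separations must lie in [0, box_edge/2]")
  u <- direction / sqrt(sum(direction^2))
  if (is.null(ref_position)) ref_position <- rep(box_edge / 2, 3)
  nf <- length(separations)
  xyz <- array(NA_real_, c(nf, 2, 3))
  for (f in seq_len(nf)) {
    xyz[f, 1, ] <- ref_position
    xyz[f, 2, ] <- (ref_position + separations[f] * u) %% box_edge
  }
  top <- data.frame(name = c("REF", "CL"), element = c("C", "Cl"),
                    resname = c("REF", "CL"), resid = c(0L, 1L), chain = "A",
                    stringsAsFactors = FALSE)
  trajectory(xyz, top, cell = diag(rep(box_edge, 3)))
}

#' Random-walk ions around frozen sites
#'
#' Frozen "protein" site atoms plus ions performing seeded Gaussian-step
#' random walks wrapped into the cell — a minimal emulation of ions moving in
#' and out of hydration shells, whose per-frame shell occupancy is countable
#' by brute force. Step size 0 freezes the ions.
#'
#' @param n_ions number of walking ions.
#' @param n_frames number of frames.
#' @param box_edge cubic cell edge (nm).
#' @param step_sd per-axis Gaussian step standard deviation (nm/frame).
#' @param site_positions matrix (n_sites x 3) of frozen site coordinates (nm);
#'   default one site at the cell centre.
#' @param seed RNG seed.
#' @return a [trajectory]: sites first (name CA, carbon, resname GLY, one
#'   residue each), then ions (name CL, chloride).
#' @export
generate_random_walk_ions <- function(n_ions, n_frames, box_edge = 4,
                                      step_sd = 0.1, site_positions = NULL,
                                      seed = 1L) {
  if (is.null(site_positions))
    site_positions <- matrix(box_edge / 2, 1, 3)
  site_positions <- matrix(site_positions, ncol = 3)
  ns <- nrow(site_positions)
  xyz <- with_seed(seed, {
    a <- array(NA_real_, c(n_frames, ns + n_ions, 3))
    ion <- matrix(stats::runif(n_ions * 3, 0, box_edge), n_ions, 3)
    for (f in seq_len(n_frames)) {
      if (f > 1L)
        ion <- (ion + matrix(stats::rnorm(n_ions * 3, sd = step_sd),
                             n_ions, 3)) %% box_edge
      a[f, seq_len(ns), ] <- site_positions
      a[f, ns + seq_len(n_ions), ] <- ion
    }
    a
  })
  top <- rbind(fixture_topology(ns, "CA", "C", "GLY", resid = seq_len(ns) - 1L),
               fixture_topology(n_ions, "CL", "Cl", "CL",
                                resid = ns + seq_len(n_ions) - 1L))
  trajectory(xyz, top, cell = diag(rep(box_edge, 3)))
}
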