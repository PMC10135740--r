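# Minimum-image geometry under periodic boundary conditions.
#
# Cells are 3x3 matrices with rows = cell vectors in the reduced triclinic
# form (first vector along x, second in the xy-plane), the GROMACS
# convention; rhombic-dodecahedral boxes are handled in this representation.
# For orthorhombic cells the nearest image follows directly from rounding
# fractional coordinates. For skewed cells rounding alone can miss the true
# nearest image, so the rounded shift is refined by searching its 3x3x3
# neighbour-image block, which is sufficient for reduced cells.

#' Validate a triclinic unit cell
#'
#' @param cell 3x3 matrix, rows = cell vectors (nm).
#' @return the cell, invisibly, or a cell error.
#' @export
validate_cell <- function(cell) {
  if (!is.matrix(cell) || any(dim(cell) != 3L) || anyNA(cell))
    cell_error("cell must be a numeric 3x3 matrix")
  if (abs(cell[1, 2]) > 1e-9 || abs(cell[1, 3]) > 1e-9 ||
      abs(cell[2, 3]) > 1e-9)
    cell_error("cell is not in reduced triclinic form (a along x, b in xy-plane)")
  if (any(diag(cell) <= 0))
    cell_error("cell diagonal must be strictly positive")
  if (det(cell) <= 1e-12) cell_error("cell volume must be positive")
  if (abs(cell[2, 1]) > cell[1, 1] / 2 + 1e-9 ||
      abs(cell[3, 1]) > cell[1, 1] / 2 + 1e-9 ||
      abs(cell[3, 2]) > cell[2, 2] / 2 + 1e-9)
    cell_error("cell off-diagonal elements exceed half the corresponding diagonal")
  invisible(cell)
}

#' Triclinic cell from box-vector lengths and angles
#'
#' @param a,b,c cell-vector lengths (nm).
#' @param alpha,beta,gamma cell angles in degrees (alpha between b and c, etc.).
#' @return 3x3 reduced-form cell matrix.
#' @export
cell_from_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  d2r <- pi / 180
  ca <- cos(alpha * d2r); cb <- cos(beta * d2r); cg <- cos(gamma * d2r)
  sg <- sin(gamma * d2r)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) cell_error("inconsistent cell parameters (negative c_z^2)")
  m <- rbind(c(a, 0, 0), c(b * cg, b * sg, 0), c(cx, cy, sqrt(cz2)))
  m[abs(m) < 1e-12] <- 0
  validate_cell(m)
  m
}

is_orthorhombic <- function(cell) {
  max(abs(cell[row(cell) != col(cell)])) < 1e-12
}

#' Smallest distance between opposite faces of a cell
#'
#' Minimum-image histograms are unambiguous only up to half this width; the
#' RDF engines refuse larger `r_max`.
#'
#' @param cell 3x3 cell matrix.
#' @return width in nm.
#' @export
min_cell_width <- function(cell) {
  v <- abs(det(cell))
  areas <- c(sqrt(sum(crossprod3(cell[2, ], cell[3, ])^2)),
             sqrt(sum(crossprod3(cell[3, ], cell[1, ])^2)),
             sqrt(sum(crossprod3(cell[1, ], cell[2, ])^2)))
  min(v / areas)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

neighbour_shifts <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dimnames(g) <- NULL
  g
})

# Minimum-image displacement norms for a matrix of raw displacements (n x 3).
# Fast path: orthorhombic rounding; general path: rounded fractional shift
# refined over the 27 neighbouring images.
min_image_norms <- function(disp, cell) {
  if (is_orthorhombic(cell)) {
    L <- diag(cell)
    d <- disp - round(disp / rep(L, each = nrow(disp))) *
      rep(L, each = nrow(disp))
    return(sqrt(rowSums(d * d)))
  }
  hinv <- solve(cell)
  f <- disp %*% hinv
  f <- f - round(f)
  best <- rep(Inf, nrow(disp))
  for (s in seq_len(nrow(neighbour_shifts))) {
    cand <- (f + matrix(neighbour_shifts[s, ], nrow(f), 3, byrow = TRUE)) %*% cell
    best <- pmin(best, rowSums(cand * cand))
  }
  sqrt(best)
}

#' Minimum-image distance between two points
#'
#' @param x1,x2 length-3 coordinate vectors (nm).
#' @param cell 3x3 cell matrix, or `NULL` for a non-periodic distance.
#' @return distance in nm.
#' @export
minimum_image_distance <- function(x1, x2, cell) {
  disp <- matrix(as.numeric(x2) - as.numeric(x1), 1, 3)
  if (is.null(cell)) return(sqrt(sum(disp^2)))
  validate_cell(cell)
  min_image_norms(disp, cell)
}

#' Minimum-image distance matrix between two coordinate sets
#'
#' @param xa `n_a x 3` reference coordinates (nm).
#' @param xb `n_b x 3` target coordinates (nm).
#' @param cell 3x3 cell matrix or `NULL` (no periodicity).
#' @return `n_a x n_b` matrix of distances (nm).
#' @export
pair_distances <- function(xa, xb, cell = NULL) {
  xa <- matrix(as.numeric(xa), ncol = 3)
  xb <- matrix(as.numeric(xb), ncol = 3)
  na_ <- nrow(xa); nb_ <- nrow(xb)
  disp <- matrix(NA_real_, na_ * nb_, 3)
  for (k in 1:3) disp[, k] <- rep(xb[, k], each = na_) - rep(xa[, k], nb_)
  d <- if (is.null(cell)) sqrt(rowSums(disp * disp)) else
    min_image_norms(disp, cell)
  matrix(d, na_, nb_)
}

#' Per-frame reference x target distance matrix
#'
#' @param traj a [trajectory].
#' @param frame 1-based frame index.
#' @param ref_idx,target_idx atom index vectors (1-based).
#' @param pbc apply the minimum-image convention (requires cell information).
#' @return list with `values` (distance matrix, nm), `frame_index`, and
#'   `self_pairs` (logical matrix marking identical-atom pairs).
#' @export
distance_block <- function(traj, frame, ref_idx, target_idx, pbc = TRUE) {
  cell <- if (pbc) frame_cell(traj, frame) else NULL
  xa <- traj$xyz[frame, ref_idx, , drop = FALSE]
  xb <- traj$xyz[frame, target_idx, , drop = FALSE]
  dim(xa) <- c(length(ref_idx), 3); dim(xb) <- c(length(target_idx), 3)
  list(values = pair_distances(xa, xb, cell),
       frame_index = frame,
       self_pairs = outer(ref_idx, target_idx, "=="))
}

#' Volume of a spherical shell
#'
#' @param r_inner,r_outer shell radii (nm), `0 <= r_inner <= r_outer`.
#' @return volume in nm^3: `(4*pi/3) * (r_outer^3 - r_inner^3)`.
#' @export
shell_volume <- function(r_inner, r_outer) {
  if (any(r_inner < 0)) domain_error("r_inner must be >= 0")
  if (any(r_inner > r_outer)) domain_error("r_inner must not exceed r_outer")
  (4 * pi / 3) * (r_outer^3 - r_inner^3)
}
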