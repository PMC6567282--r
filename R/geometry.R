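## Ideal-geometry helpers: polyhedra, the cubic-diamond (CD) lattice and
## small rotation utilities. All coordinates are in reduced length sigma.

#' Unit vectors to the four vertices of a regular tetrahedron
#'
#' Rows are unit vectors along (1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1).
#' The opposite orientation (as used by the interpenetrating sublattice)
#' is obtained by negation.
#'
#' @param orientation `+1` (default) or `-1` for the inverted tetrahedron.
#' @return A 4 x 3 matrix of unit row vectors.
#' @export
tetrahedron_directions <- function(orientation = 1L) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  orientation * v
}

#' Vertices of a regular dodecahedron
#'
#' Standard coordinates (+-1,+-1,+-1), (0,+-1/phi,+-phi) and cyclic
#' permutations, scaled so the circumscribed sphere has diameter `d`.
#' The edge length of the returned polyhedron is d / (sqrt(3) * phi).
#'
#' @param d Circumscribed-sphere diameter in sigma.
#' @return A 20 x 3 matrix of vertex coordinates.
#' @export
dodecahedron_vertices <- function(d = 2 * sqrt(3)) {
  phi <- (1 + sqrt(5)) / 2
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  recs <- rbind(
    cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi)
  )
  v <- rbind(cube, recs)
  dimnames(v) <- NULL
  v * d / (2 * sqrt(3))
}

## Inradius / circumradius ratio of the regular dodecahedron (~0.7947);
## sets the excluded-volume range of the NP central site (inscribed
## sphere) relative to its nominal circumscribed diameter.
dodecahedron_inradius_ratio <- function() {
  r_in <- 0.5 * sqrt(5 / 2 + 11 / (2 * sqrt(5)))  # unit edge
  r_circ <- sqrt(3) / 4 * (1 + sqrt(5))           # unit edge
  r_in / r_circ
}

#' Primitive FCC lattice vectors of the cubic-diamond cell
#'
#' The CD lattice is two interpenetrating FCC lattices offset by a quarter
#' body diagonal. Rows are the primitive vectors (b/2)(0,1,1), (b/2)(1,0,1),
#' (b/2)(1,1,0); they have equal lengths and 60-degree mutual angles, giving
#' the regular triclinic simulation box.
#'
#' @param b Conventional (cubic) lattice constant in sigma.
#' @return A 3 x 3 matrix whose rows are the primitive vectors.
#' @export
fcc_primitive_vectors <- function(b) {
  b / 2 * rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
}

#' Ideal cubic-diamond body centers
#'
#' Generates the NP sublattice at the FCC points and the cage sublattice
#' offset by (b/4, b/4, b/4), replicated `n` times along each primitive
#' vector.
#'
#' @param n Replications per primitive vector (n^3 primitive cells).
#' @param b Conventional lattice constant in sigma.
#' @return A list with `centers` (2n^3 x 3), `species` ("np"/"cage"),
#'   `cell` (n^3-row integer matrix of cell indices for each body),
#'   `basis` (1 or 2), `box` (3 x 3 row-vector matrix), `b`, and `n`.
#' @export
cd_lattice_sites <- function(n, b) {
  stopifnot(n >= 1)
  a <- fcc_primitive_vectors(b)
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  colnames(idx) <- NULL
  fcc <- idx %*% a
  off <- matrix(rep(b / 4, 3), nrow(fcc), 3, byrow = TRUE)
  centers <- rbind(fcc, fcc + off)
  species <- rep(c("np", "cage"), each = nrow(fcc))
  list(
    centers = centers,
    species = species,
    cell = rbind(idx, idx),
    basis = rep(c(1L, 2L), each = nrow(fcc)),
    box = n * a,
    b = b,
    n = as.integer(n)
  )
}

## The four nearest-neighbour bond vectors of the cage sublattice
## (sublattice at (b/4,b/4,b/4) bonds to NPs along these); NP bonds are the
## negatives. Units of b.
cd_bond_vectors <- function(b) {
  b / 4 * rbind(c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
}

#' Rotation matrix from a rotation vector
#'
#' Rodrigues formula; `phi` is an axis-angle vector whose norm is the
#' rotation angle in radians.
#'
#' @param phi Length-3 rotation vector.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_from_vector <- function(phi) {
  th <- sqrt(sum(phi^2))
  if (th < 1e-14) return(diag(3))
  k <- phi / th
  K <- rbind(
    c(0, -k[3], k[2]),
    c(k[3], 0, -k[1]),
    c(-k[2], k[1], 0)
  )
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Rotation taking unit vector `a` onto unit vector `b`.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    ## antiparallel: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_from_vector(pi * ax))
  }
  rotation_from_vector(atan2(s, cth) * v / s)
}

## Wrap fractional coordinates to the half-open cell [0, 1).
wrap_fractional <- function(frac) {
  frac - floor(frac)
}

## Minimum-image displacement r_j - r_i under a (possibly triclinic)
## row-vector box matrix `box`; rows of ri, rj are positions.
minimum_image <- function(dr, box, periodic = c(TRUE, TRUE, TRUE)) {
  inv <- solve(box)
  f <- dr %*% inv
  for (k in 1:3) if (periodic[k]) f[, k] <- f[, k] - round(f[, k])
  f %*% box
}
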