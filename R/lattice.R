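## Bulk cubic-diamond lattices and crystal slabs at full bead resolution.

#' Default lattice constant from the rest geometry
#'
#' The nearest-neighbour cage-NP separation is taken as the sum of the two
#' arm lengths (cage center to strand tip; NP center to strand tip) minus
#' the 8-base-pair duplex overlap, times `scale`; the conventional lattice
#' constant follows as b = 4 r_nn / sqrt(3). With `scale = 1` the two
#' sticky regions of a pre-hybridized pair of straight strands overlap in
#' register at build time; the zero-pressure barostat relaxes b afterwards.
#'
#' @param d NP diameter in sigma.
#' @param scale Multiplier on the rest separation (default 1).
#' @return Lattice constant b in sigma.
#' @export
default_lattice_constant <- function(d = 40, scale = 1) {
  g <- cage_geometry()
  arm_cage <- g$r_anchor + 14 * .fene_r0      # anchor is nucleotide 1
  arm_np <- d / 2 + 15 * .fene_r0
  overlap <- 7 * .fene_r0                     # 8 paired bases = 7 gaps
  r_nn <- scale * (arm_cage + arm_np - overlap)
  4 * r_nn / sqrt(3)
}

## Dodecahedron vertex indices aligned with the four cage-bond directions
## (+1,+1,+1)-type; these are the strands used for lattice links.
np_bonded_vertices <- function(d = 40) {
  verts <- dodecahedron_vertices(d)
  dirs <- tetrahedron_directions(1L)
  apply(dirs, 1, function(u) which.max(verts %*% u))
}

## Shift the bonded NP strands sideways so that, at build time, the two
## pre-hybridized strands of a link run side by side with their bases
## facing, instead of colliding head-on.
offset_bonded_np_strands <- function(top, np_bodies, vertex_ids,
                                     lateral = 2.9, cage_dirs = NULL) {
  s <- top$sites
  if (is.null(cage_dirs)) cage_dirs <- tetrahedron_directions(-1L)
  for (b in np_bodies) {
    for (v in vertex_ids) {
      sel <- which(s$body == b & !is.na(s$strand) & s$strand == v &
                     s$species %in% c("dna_backbone", "dna_base"))
      if (!length(sel)) next
      ## strand direction from the body center
      ctr <- as.numeric(top$bodies[top$bodies$body == b, c("cx", "cy", "cz")])
      first <- sel[1]
      u <- c(s$x[first], s$y[first], s$z[first]) - ctr
      u <- u / sqrt(sum(u^2))
      ## lane shared with the partner cage strand: the cage sees this
      ## bond along -u
      p <- bond_perp(-u, cage_dirs)
      ## sites come in backbone/base pairs ordered along the strand; the
      ## lateral displacement ramps up over the first nucleotides so the
      ## graft bond stays within its FENE range, and the bases flip to
      ## face the partner strand
      nt <- ceiling(seq_along(sel) / 2)
      ramp <- lateral * pmin(1, (nt - 1) / 4)
      isbase <- s$species[sel] == "dna_base"
      vert <- as.numeric(s[first, c("x", "y", "z")]) - .fene_r0 * u
      bk <- matrix(vert, length(sel), 3, byrow = TRUE) +
        outer(nt * .fene_r0, u) + outer(ramp, p)
      bk[isbase, ] <- bk[isbase, , drop = FALSE] -
        matrix(.fene_r0 * p, sum(isbase), 3, byrow = TRUE)
      s[sel, c("x", "y", "z")] <- bk
    }
  }
  top$sites <- s
  top
}

#' Build a fully bonded bulk cubic-diamond lattice
#'
#' `n^3` primitive cells, each holding one NP (at the FCC points) and one
#' cage (offset by a quarter body diagonal), in a regular triclinic box
#' with 60-degree angles. All cages share one orientation and the NPs the
#' opposite, so only nearest cage-NP strand pairs can hybridize.
#'
#' @param n Replications per primitive vector.
#' @param d NP diameter in sigma.
#' @param ka DNA stiffness.
#' @param b Lattice constant; defaults to [default_lattice_constant()].
#' @param bodies_only If `TRUE`, build only body centers (no bead sites);
#'   used by the center-of-body analysis stages.
#' @return A `cd_topology` system with `meta$lattice` describing the cell
#'   map.
#' @export
build_bulk_lattice <- function(n = 4, d = 40, ka = 1, b = NULL,
                               bodies_only = FALSE) {
  stopifnot(n >= 1)
  if (is.null(b)) b <- default_lattice_constant(d)
  g <- cage_geometry()
  r_nn <- sqrt(3) * b / 4
  max_reach <- (g$r_anchor + 14 * .fene_r0) + (d / 2 + 15 * .fene_r0)
  if (r_nn > max_reach)
    stop("lattice constant too large for strand reach: r_nn = ",
         round(r_nn, 2), " > ", round(max_reach, 2))
  if (r_nn < 0.5 * max_reach)
    stop("lattice constant too small: strands cannot avoid second ",
         "neighbours (r_nn = ", round(r_nn, 2), ")")
  lat <- cd_lattice_sites(n, b)

  if (bodies_only) {
    sys <- body_level_system(lat, d = d, ka = ka)
    return(sys)
  }

  np_proto <- build_np(d, ka)
  cage_proto <- build_cage(ka, orientation = -1L)
  tops <- vector("list", nrow(lat$centers))
  for (i in seq_len(nrow(lat$centers))) {
    proto <- if (lat$species[i] == "np") np_proto else cage_proto
    tops[[i]] <- transform_topology(proto, shift = lat$centers[i, ])
  }
  sys <- merge_topologies(tops, box = lat$box,
                          periodic = c(TRUE, TRUE, TRUE),
                          meta = list(d = d, ka = ka, b = b, n = n,
                                      lattice = lat))
  sys$bodies$cell1 <- lat$cell[, 1]; sys$bodies$cell2 <- lat$cell[, 2]
  sys$bodies$cell3 <- lat$cell[, 3]; sys$bodies$basis <- lat$basis
  np_bodies <- sys$bodies$body[sys$bodies$kind == "np"]
  sys <- offset_bonded_np_strands(sys, np_bodies, np_bonded_vertices(d))
  sys
}

## Body-center-only system (no bead sites): same container, one "site"
## per body carrying the total body mass.
body_level_system <- function(lat, d = 40, ka = 1,
                              masses = body_masses()) {
  m <- ifelse(lat$species == "np", masses[["np"]], masses[["cage"]])
  sites <- data.frame(
    id = seq_along(lat$species), body = seq_along(lat$species),
    species = ifelse(lat$species == "np", "np_center", "cage_center"),
    base = NA_character_, strand = NA_integer_,
    diameter = ifelse(lat$species == "np", d, 40),
    pair_diameter = ifelse(lat$species == "np",
                           d * dodecahedron_inradius_ratio(), 40),
    mass = m,
    x = lat$centers[, 1], y = lat$centers[, 2], z = lat$centers[, 3])
  bodies <- data.frame(body = seq_along(lat$species), kind = lat$species,
                       cx = lat$centers[, 1], cy = lat$centers[, 2],
                       cz = lat$centers[, 3],
                       cell1 = lat$cell[, 1], cell2 = lat$cell[, 2],
                       cell3 = lat$cell[, 3], basis = lat$basis)
  new_topology(sites, empty_bonds(), empty_angles(), bodies,
               box = lat$box, periodic = c(TRUE, TRUE, TRUE),
               meta = list(d = d, ka = ka, b = lat$b, n = lat$n,
                           lattice = lat, bodies_only = TRUE))
}

#' Total body masses (site counts, all site masses being 1)
#'
#' @return Named vector with elements `np` and `cage`.
#' @export
body_masses <- function() {
  c(np = 21 + 20 * 30, cage = 6 * 7 + 4 * 3 + 1 + 4 * 30)
}

#' Ideal nearest-neighbour map of a lattice system
#'
#' For each cage body, the four NP bodies at the ideal bonded separation
#' sqrt(3) b / 4 under minimum image.
#'
#' @param sys A lattice system built by [build_bulk_lattice()] or
#'   [build_slab()].
#' @param tol Relative distance tolerance.
#' @return Integer matrix, one row per cage body, body ids of neighbours
#'   (NA where a bond dangles at a surface).
#' @export
ideal_neighbor_map <- function(sys, tol = 0.05) {
  b <- sys$meta$b
  r_nn <- sqrt(3) * b / 4
  ctr <- as.matrix(sys$bodies[, c("cx", "cy", "cz")])
  cages <- which(sys$bodies$kind == "cage")
  nps <- which(sys$bodies$kind == "np")
  out <- matrix(NA_integer_, length(cages), 4)
  for (ci in seq_along(cages)) {
    dr <- sweep(ctr[nps, , drop = FALSE], 2, ctr[cages[ci], ], "-")
    if (!is.null(sys$box)) dr <- minimum_image(dr, sys$box, sys$periodic)
    dd <- sqrt(rowSums(dr^2))
    hit <- which(abs(dd - r_nn) < tol * r_nn)
    out[ci, seq_along(hit)] <- sys$bodies$body[nps[hit]]
  }
  rownames(out) <- sys$bodies$body[cages]
  out
}

#' Build an isolated cage-NP pair
#'
#' Places one nanoparticle at the nearest-neighbour lattice separation
#' from one cage, either along a cage vertex (bonding) direction with
#' the strands pre-paired as in the lattice build, or along a face
#' direction (`aligned = FALSE`), where no cage strand points at the NP
#' and hybridization requires the strands to reorient. The misaligned
#' pair is the desk-scale probe of surface reorientation bonding: how
#' easily a bond forms off-axis is controlled by the DNA stiffness.
#'
#' @param ka DNA stiffness.
#' @param d NP diameter.
#' @param aligned Logical; see above.
#' @param b Lattice constant setting the separation sqrt(3) b / 4.
#' @return A `cd_topology` with two bodies in a large open box.
#' @export
build_cage_np_pair <- function(ka = 1, d = 40, aligned = TRUE,
                               b = default_lattice_constant(d)) {
  r_nn <- sqrt(3) * b / 4
  cage <- build_cage(ka, orientation = -1L)
  np <- build_np(d, ka)
  dirs <- tetrahedron_directions(-1L)
  u <- if (aligned) dirs[1, ] else -dirs[1, ]
  if (!aligned) {
    ## point one NP strand back toward the cage
    R <- rotation_between(tetrahedron_directions(1L)[1, ], -u)
    np <- transform_topology(np, R = R)
  }
  np <- transform_topology(np, shift = r_nn * u)
  sys <- merge_topologies(list(cage, np),
                          meta = list(d = d, ka = ka, b = b,
                                      aligned = aligned))
  if (aligned) {
    vid <- np_bonded_vertices(d)[1]
    sys <- offset_bonded_np_strands(sys, 2L, vid)
  }
  sys
}
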