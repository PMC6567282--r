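## Coarse-grained topology builders: tetrahedral DNA-origami cages,
## dodecahedral nanoparticles, grafted single strands, and the containers
## shared by the simulation and analysis code.
##
## A topology is a list of class "cd_topology":
##   sites  - data.frame(id, body, species, base, strand, diameter,
##            pair_diameter, mass, x, y, z)
##   bonds  - data.frame(i, j, kb, R0, eps, Delta, role)   (shifted FENE)
##   angles - data.frame(i, j, k, ka, role)  V = ka (1 + cos theta), angle
##            at the middle site j
##   box    - 3 x 3 matrix of row vectors, or NULL for isolated bodies
##   periodic - logical(3)
##   bodies - data.frame(body, kind, cx, cy, cz [, cell1..3, basis])
##   meta   - named list of build parameters

## FENE rest length of the unshifted (Delta = 0) bond with kb=30, R0=1.5,
## eps=1: the printed minimum used throughout the parameter tables.
.fene_r0 <- 0.96

## Bond parameter rows for the tetrahedral cage (kb, R0, eps, Delta).
.cage_bonds <- list(
  edge_first  = c(kb = 240, R0 = 1.5, eps = 8, Delta = 6.36),
  edge_second = c(kb = 240, R0 = 1.5, eps = 8, Delta = 13.67),
  anchor_center = c(kb = 240, R0 = 1.5, eps = 8, Delta = 36.52),
  vertex_edge = c(kb = 30, R0 = 1.5, eps = 1, Delta = 15.08),
  edge_edge   = c(kb = 30, R0 = 1.5, eps = 1, Delta = 9.15)
)

## Excluded-volume diameters by species (Table of pair diameters); the NP
## center is special-cased in build_np (inscribed-sphere pair diameter).
.species_diameter <- c(
  cage_edge = 9.9, cage_center = 40, cage_vertex_dna_anchor = 1,
  np_vertex = 1, np_center = NA, dna_backbone = 1, dna_base = 1
)

#' Reverse complement of a DNA sequence
#'
#' The inert spacer letter "N" is its own complement.
#'
#' @param seq Character scalar over A, C, G, T, N.
#' @return Character scalar.
#' @export
revcomp_dna <- function(seq) {
  map <- c(A = "T", T = "A", C = "G", G = "C", N = "N")
  paste(rev(unname(map[strsplit(seq, "")[[1]]])), collapse = "")
}

#' Default sticky-end sequences
#'
#' The cage 8-mer is non-self-complementary; the NP carries its reverse
#' complement so cage-NP hybridization is the only fully matched pairing.
#'
#' @return Character scalar (8 bases).
#' @export
cage_sticky_sequence <- function() "GCGCAGTC"

#' @rdname cage_sticky_sequence
#' @export
np_sticky_sequence <- function() revcomp_dna(cage_sticky_sequence())

#' Specification of a grafted DNA strand
#'
#' Each strand has 15 nucleotides: `n_spacer` inert spacers (base letter
#' "N", no complement anywhere) proximal to the graft, then `n_sticky`
#' sticky bases written 5' to 3' outward from the body.
#'
#' @param sticky Sticky-end sequence (length `n_sticky`).
#' @param n_spacer Number of spacer nucleotides (default 7).
#' @param n_sticky Number of sticky nucleotides (default 8).
#' @return A list of class "strand_spec".
#' @export
strand_spec <- function(sticky = cage_sticky_sequence(), n_spacer = 7L,
                        n_sticky = 8L) {
  sticky <- toupper(sticky)
  stopifnot(nchar(sticky) == n_sticky,
            grepl("^[ACGTN]+$", sticky))
  structure(list(n_spacer = as.integer(n_spacer),
                 n_sticky = as.integer(n_sticky),
                 sticky = sticky),
            class = "strand_spec")
}

strand_bases <- function(spec) {
  c(rep("N", spec$n_spacer), strsplit(spec$sticky, "")[[1]])
}

## Deterministic unit vector orthogonal to u.
orthonormal_perp <- function(u) {
  u <- u / sqrt(sum(u^2))
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- p - sum(p * u) * u
  p / sqrt(sum(p^2))
}

## Perpendicular lane of a cage-NP link: the azimuth bisecting the gap
## between two truncation beads of the cage vertex, so the laterally
## offset partner strand passes between the beads rather than into one.
## `u_cage` is the cage's vertex (bond) direction; `cage_dirs` the
## cage's four vertex directions (rows).
bond_perp <- function(u_cage, cage_dirs) {
  u <- u_cage / sqrt(sum(u_cage^2))
  for (r in seq_len(nrow(cage_dirs))) {
    w <- cage_dirs[r, ]
    if (abs(sum(w * u)) < 0.9) {
      p <- w - sum(w * u) * u
      return(-p / sqrt(sum(p^2)))
    }
  }
  orthonormal_perp(u)
}

new_topology <- function(sites, bonds, angles, bodies, box = NULL,
                         periodic = c(FALSE, FALSE, FALSE), meta = list()) {
  structure(list(sites = sites, bonds = bonds, angles = angles,
                 bodies = bodies, box = box, periodic = periodic,
                 meta = meta),
            class = "cd_topology")
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), kb = numeric(), R0 = numeric(),
             eps = numeric(), Delta = numeric(), role = character())
}

empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(), ka = numeric(),
             role = character())
}

make_sites <- function(species, pos, base = NA_character_,
                       strand = NA_integer_, diameter = NULL,
                       pair_diameter = NULL, mass = 1) {
  n <- nrow(pos)
  if (is.null(diameter)) diameter <- unname(.species_diameter[species])
  if (is.null(pair_diameter)) pair_diameter <- diameter
  data.frame(id = seq_len(n), body = 1L, species = species,
             base = rep_len(base, n), strand = rep_len(strand, n),
             diameter = diameter, pair_diameter = pair_diameter,
             mass = rep_len(mass, n),
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

## Build one grafted strand: 15 nucleotides of backbone + base sites along
## unit direction u starting at `start` (= position of nucleotide 1's
## backbone); base sites are offset by the rest length along `p`.
## Returns sites plus bonds/angles in strand-local indexing (1..30, with
## backbone k at 2k-1 and base k at 2k).
graft_strand_sites <- function(spec, start, u, p = orthonormal_perp(u),
                               first_species = "dna_backbone") {
  n_nt <- spec$n_spacer + spec$n_sticky
  bases <- strand_bases(spec)
  bk <- matrix(start, n_nt, 3, byrow = TRUE) +
    outer(.fene_r0 * (seq_len(n_nt) - 1), u)
  bs <- bk + matrix(p * .fene_r0, n_nt, 3, byrow = TRUE)
  pos <- matrix(0, 2 * n_nt, 3)
  pos[2 * seq_len(n_nt) - 1, ] <- bk
  pos[2 * seq_len(n_nt), ] <- bs
  species <- rep(c("dna_backbone", "dna_base"), n_nt)
  species[1] <- first_species
  base <- rep(NA_character_, 2 * n_nt)
  base[2 * seq_len(n_nt)] <- bases
  sites <- make_sites(species, pos, base = base)
  ## backbone-backbone and base-backbone FENE (standard, Delta = 0)
  bb <- data.frame(i = 2 * seq_len(n_nt - 1) - 1, j = 2 * seq_len(n_nt - 1) + 1,
                   kb = 30, R0 = 1.5, eps = 1, Delta = 0,
                   role = "dna_backbone")
  sb <- data.frame(i = 2 * seq_len(n_nt) - 1, j = 2 * seq_len(n_nt),
                   kb = 30, R0 = 1.5, eps = 1, Delta = 0, role = "dna_base")
  ## backbone bending angles carry the DNA stiffness ka (set by caller)
  ang <- data.frame(i = 2 * (1:(n_nt - 2)) - 1, j = 2 * (2:(n_nt - 1)) - 1,
                    k = 2 * (3:n_nt) - 1, ka = NA_real_,
                    role = "dna_backbone")
  list(sites = sites, bonds = rbind(bb, sb), angles = ang, n_nt = n_nt)
}

## Internal cage geometry scale: truncation-bead / edge-bead distances are
## fixed by the printed rest lengths, which in turn fix the circumradius.
cage_geometry <- function() {
  s1 <- .cage_bonds$edge_first[["Delta"]] + .fene_r0        # 7.32
  u_t <- .cage_bonds$edge_edge[["Delta"]] + .fene_r0        # 10.11
  gap <- .cage_bonds$vertex_edge[["Delta"]] + .fene_r0      # 16.04
  L <- 2 * (3 * s1 + gap + u_t)                             # full edge
  list(s1 = s1, u_t = u_t, gap = gap, L = L,
       R_v = L * sqrt(3 / 8),
       r_anchor = .cage_bonds$anchor_center[["Delta"]] + .fene_r0)
}

#' Build a tetrahedral DNA-origami cage topology
#'
#' Six edges of seven beads each, four truncated vertices of three beads
#' (the terminal beads of the edges meeting there), a 40-sigma central
#' site, and four grafted DNA strands whose first nucleotide (the anchor)
#' is tethered to the center. All parameterised bonds are built at their
#' rest lengths; the anchor-to-truncation-bead tethers take their rest
#' length from the constructed geometry.
#'
#' @param ka Angle (DNA) stiffness in reduced units, in `[0.5, 2]`.
#' @param strand A [strand_spec()]; default carries the cage sticky end.
#' @param orientation `+1` or `-1`; `-1` matches the cage sublattice of
#'   the standard bulk lattice.
#' @return A `cd_topology` with one body centred at the origin.
#' @export
build_cage <- function(ka = 1, strand = strand_spec(cage_sticky_sequence()),
                       orientation = 1L) {
  stopifnot(ka >= 0.5 - 1e-9, ka <= 2 + 1e-9)
  g <- cage_geometry()
  dirs <- tetrahedron_directions(orientation)
  P <- g$R_v * dirs
  edges <- utils::combn(4, 2)

  sites <- list(); bonds <- list(); angles <- list()
  nid <- 0L
  edge_bead_id <- vector("list", 6)   # per edge, ids of the 7 beads (i->j)
  trunc_id <- matrix(NA_integer_, 4, 4)  # [vertex, other-vertex]
  trunc_pos <- array(NA_real_, c(4, 4, 3))

  for (e in seq_len(ncol(edges))) {
    i <- edges[1, e]; j <- edges[2, e]
    ehat <- (P[j, ] - P[i, ]) / g$L
    M <- (P[i, ] + P[j, ]) / 2
    beadpos <- matrix(M, 7, 3, byrow = TRUE) + outer((-3:3) * g$s1, ehat)
    s <- make_sites(rep("cage_edge", 7), beadpos)
    s$id <- nid + seq_len(7)
    edge_bead_id[[e]] <- s$id
    sites[[length(sites) + 1]] <- s
    nid <- nid + 7L
    ## first and second neighbour FENE along the edge
    p1 <- .cage_bonds$edge_first; p2 <- .cage_bonds$edge_second
    ids <- s$id
    bonds[[length(bonds) + 1]] <- data.frame(
      i = ids[1:6], j = ids[2:7], kb = p1[["kb"]], R0 = p1[["R0"]],
      eps = p1[["eps"]], Delta = p1[["Delta"]], role = "edge_first")
    bonds[[length(bonds) + 1]] <- data.frame(
      i = ids[1:5], j = ids[3:7], kb = p2[["kb"]], R0 = p2[["R0"]],
      eps = p2[["eps"]], Delta = p2[["Delta"]], role = "edge_second")
    ## truncation beads: terminal beads of this edge, one at each end
    for (end in c(i, j)) {
      other <- if (end == i) j else i
      tpos <- P[end, ] + g$u_t * (P[other, ] - P[end, ]) / g$L
      s2 <- make_sites("cage_edge", matrix(tpos, 1, 3))
      s2$id <- nid + 1L
      trunc_id[end, other] <- s2$id
      trunc_pos[end, other, ] <- tpos
      sites[[length(sites) + 1]] <- s2
      nid <- nid + 1L
      ## tether to the nearest of the 7 edge beads
      near <- if (end == i) ids[1] else ids[7]
      pv <- .cage_bonds$vertex_edge
      bonds[[length(bonds) + 1]] <- data.frame(
        i = s2$id, j = near, kb = pv[["kb"]], R0 = pv[["R0"]],
        eps = pv[["eps"]], Delta = pv[["Delta"]], role = "vertex_edge")
    }
  }

  ## triangle bonds across each truncation face
  pe <- .cage_bonds$edge_edge
  for (v in 1:4) {
    tri <- stats::na.omit(trunc_id[v, ])
    cmb <- utils::combn(tri, 2)
    bonds[[length(bonds) + 1]] <- data.frame(
      i = cmb[1, ], j = cmb[2, ], kb = pe[["kb"]], R0 = pe[["R0"]],
      eps = pe[["eps"]], Delta = pe[["Delta"]], role = "edge_edge")
  }

  ## central site
  cs <- make_sites("cage_center", matrix(0, 1, 3))
  cs$id <- nid + 1L
  center_id <- cs$id
  sites[[length(sites) + 1]] <- cs
  nid <- nid + 1L

  ## strands: anchor (first nucleotide) on the vertex axis, tethered to
  ## the center and to the three truncation beads of its vertex
  pa <- .cage_bonds$anchor_center
  for (v in 1:4) {
    u <- dirs[v, ]
    st <- graft_strand_sites(strand, g$r_anchor * u, u,
                             p = bond_perp(u, dirs),
                             first_species = "cage_vertex_dna_anchor")
    st$sites$id <- nid + st$sites$id
    st$sites$strand <- v
    st$bonds$i <- nid + st$bonds$i; st$bonds$j <- nid + st$bonds$j
    st$angles$i <- nid + st$angles$i; st$angles$j <- nid + st$angles$j
    st$angles$k <- nid + st$angles$k
    st$angles$ka <- ka
    anchor <- nid + 1L
    bonds[[length(bonds) + 1]] <- data.frame(
      i = anchor, j = center_id, kb = pa[["kb"]], R0 = pa[["R0"]],
      eps = pa[["eps"]], Delta = pa[["Delta"]], role = "anchor_center")
    for (other in which(!is.na(trunc_id[v, ]))) {
      tid <- trunc_id[v, other]
      tp <- trunc_pos[v, other, ]
      dist <- sqrt(sum((tp - g$r_anchor * u)^2))
      bonds[[length(bonds) + 1]] <- data.frame(
        i = anchor, j = tid, kb = 30, R0 = 1.5, eps = 1,
        Delta = dist - .fene_r0, role = "anchor_vertex")
    }
    ## graft angle keeps the strand outward along the center->vertex axis
    angles[[length(angles) + 1]] <- data.frame(
      i = center_id, j = anchor, k = anchor + 2L, ka = ka, role = "graft")
    sites[[length(sites) + 1]] <- st$sites
    bonds[[length(bonds) + 1]] <- st$bonds
    angles[[length(angles) + 1]] <- st$angles
    nid <- nid + nrow(st$sites)
  }

  sites <- do.call(rbind, sites)
  bodies <- data.frame(body = 1L, kind = "cage", cx = 0, cy = 0, cz = 0)
  new_topology(sites, do.call(rbind, bonds), do.call(rbind, angles),
               bodies, meta = list(ka = ka, kind = "cage",
                                   orientation = orientation,
                                   geometry = cage_geometry()))
}

#' Build a DNA-functionalized nanoparticle topology
#'
#' Twenty vertex sites (diameter 1 sigma) at the vertices of a regular
#' dodecahedron with circumscribed diameter `d`, one central site, FENE
#' bonds vertex-vertex and center-vertex, and twenty grafted DNA strands
#' pointing radially outward. The central site repels other particles
#' over the inscribed sphere of the dodecahedron.
#'
#' @param d Nanoparticle (circumscribed) diameter in sigma; the supported
#'   range is 40-120 (values outside it warn but still build).
#' @param ka Angle (DNA) stiffness.
#' @param strand A [strand_spec()]; default carries the NP sticky end
#'   (reverse complement of the cage's).
#' @return A `cd_topology` with one body centred at the origin.
#' @export
build_np <- function(d = 40, ka = 1,
                     strand = strand_spec(np_sticky_sequence())) {
  if (d < 40 || d > 120)
    warning("NP diameter ", d, " outside the supported range [40, 120]")
  verts <- dodecahedron_vertices(d)
  l_rest <- d / 2.8                       # printed vertex spacing
  l_geo <- d / (sqrt(3) * (1 + sqrt(5)) / 2)  # exact edge length

  sites <- list(); bonds <- list(); angles <- list()
  vs <- make_sites(rep("np_vertex", 20), verts)
  sites[[1]] <- vs
  cs <- make_sites("np_center", matrix(0, 1, 3),
                   diameter = d, pair_diameter = d * dodecahedron_inradius_ratio())
  cs$id <- 21L
  center_id <- 21L
  sites[[2]] <- cs
  nid <- 21L

  ## center-vertex and nearest-neighbour vertex-vertex FENE
  bonds[[1]] <- data.frame(i = 1:20, j = center_id, kb = 30, R0 = 1.5,
                           eps = 1, Delta = d / 2 - .fene_r0,
                           role = "np_center_vertex")
  dm <- as.matrix(stats::dist(verts))
  nn <- which(dm > 1e-9 & dm < 1.2 * l_geo, arr.ind = TRUE)
  nn <- nn[nn[, 1] < nn[, 2], , drop = FALSE]
  bonds[[2]] <- data.frame(i = nn[, 1], j = nn[, 2], kb = 30, R0 = 1.5,
                           eps = 1, Delta = l_rest - .fene_r0,
                           role = "np_vertex_vertex")

  for (v in 1:20) {
    u <- verts[v, ] / sqrt(sum(verts[v, ]^2))
    st <- graft_strand_sites(strand, verts[v, ] + .fene_r0 * u, u)
    st$sites$id <- nid + st$sites$id
    st$sites$strand <- v
    st$bonds$i <- nid + st$bonds$i; st$bonds$j <- nid + st$bonds$j
    st$angles$i <- nid + st$angles$i; st$angles$j <- nid + st$angles$j
    st$angles$k <- nid + st$angles$k
    st$angles$ka <- ka
    ## graft bond and orientation angle at the first nucleotide
    bonds[[length(bonds) + 1]] <- data.frame(
      i = v, j = nid + 1L, kb = 30, R0 = 1.5, eps = 1, Delta = 0,
      role = "np_graft")
    angles[[length(angles) + 1]] <- data.frame(
      i = center_id, j = nid + 1L, k = nid + 3L, ka = ka, role = "graft")
    sites[[length(sites) + 1]] <- st$sites
    bonds[[length(bonds) + 1]] <- st$bonds
    angles[[length(angles) + 1]] <- st$angles
    nid <- nid + nrow(st$sites)
  }

  sites <- do.call(rbind, sites)
  bodies <- data.frame(body = 1L, kind = "np", cx = 0, cy = 0, cz = 0)
  new_topology(sites, do.call(rbind, bonds), do.call(rbind, angles),
               bodies, meta = list(d = d, ka = ka, kind = "np"))
}

#' @export
print.cd_topology <- function(x, ...) {
  cat("cd_topology:", nrow(x$sites), "sites,", nrow(x$bonds), "bonds,",
      nrow(x$angles), "angles,", nrow(x$bodies), "bodies\n")
  if (!is.null(x$box)) {
    cat("box row vectors (sigma):\n")
    print(round(x$box, 3))
    cat("periodic:", x$periodic, "\n")
  }
  invisible(x)
}

site_positions <- function(top) {
  as.matrix(top$sites[, c("x", "y", "z")])
}

set_site_positions <- function(top, pos) {
  top$sites$x <- pos[, 1]; top$sites$y <- pos[, 2]; top$sites$z <- pos[, 3]
  top
}

## Rigid transform of a single-body topology: rotate about the body
## origin, then translate.
transform_topology <- function(top, R = diag(3), shift = c(0, 0, 0)) {
  pos <- site_positions(top) %*% t(R)
  pos <- sweep(pos, 2, shift, "+")
  top <- set_site_positions(top, pos)
  top$bodies[, c("cx", "cy", "cz")] <-
    matrix(as.numeric(top$bodies[1, c("cx", "cy", "cz")]) %*% t(R) + shift,
           nrow(top$bodies), 3, byrow = TRUE)
  top
}

## Concatenate topologies, re-numbering site ids and body ids.
merge_topologies <- function(tops, box = NULL,
                             periodic = c(FALSE, FALSE, FALSE),
                             meta = list()) {
  off_id <- 0L; off_body <- 0L
  sites <- vector("list", length(tops)); bonds <- sites; angles <- sites
  bodies <- sites
  for (k in seq_along(tops)) {
    t0 <- tops[[k]]
    s <- t0$sites
    s$id <- s$id + off_id
    s$body <- s$body + off_body
    b <- t0$bonds; b$i <- b$i + off_id; b$j <- b$j + off_id
    a <- t0$angles
    a$i <- a$i + off_id; a$j <- a$j + off_id; a$k <- a$k + off_id
    bd <- t0$bodies; bd$body <- bd$body + off_body
    sites[[k]] <- s; bonds[[k]] <- b; angles[[k]] <- a; bodies[[k]] <- bd
    off_id <- off_id + nrow(s)
    off_body <- off_body + nrow(bd)
  }
  new_topology(do.call(rbind, sites), do.call(rbind, bonds),
               do.call(rbind, angles), do.call(rbind, bodies),
               box = box, periodic = periodic, meta = meta)
}

#' Geometric body centers of a topology
#'
#' Returns the position of each body's central site (cage or NP center).
#'
#' @param top A `cd_topology`.
#' @return A matrix with one row per body.
#' @export
body_centers <- function(top) {
  ctr <- top$sites[top$sites$species %in% c("cage_center", "np_center"), ]
  ctr <- ctr[order(ctr$body), ]
  as.matrix(ctr[, c("x", "y", "z")])
}

#' Build a pair of free complementary DNA strands
#'
#' Two 15-nucleotide strands (cage-type and NP-type sticky ends) placed
#' side by side with their sticky regions in register, in a periodic
#' cubic box. Used by the melting-scan calibration of the base-pair
#' attraction and the hybridization diagnostics.
#'
#' @param ka DNA stiffness.
#' @param box_side Cubic box side in sigma.
#' @return A `cd_topology` with two single-strand "bodies".
#' @export
build_strand_pair <- function(ka = 1, box_side = 20) {
  mk <- function(spec, start, u, p) {
    st <- graft_strand_sites(spec, start, u, p)
    st$sites$strand <- 1L
    st$angles$ka <- ka
    new_topology(st$sites, st$bonds, st$angles,
                 data.frame(body = 1L, kind = "cage", cx = start[1],
                            cy = start[2], cz = start[3]))
  }
  len <- 14 * .fene_r0
  sA <- mk(strand_spec(cage_sticky_sequence()), c(2, 8, 10),
           c(1, 0, 0), c(0, 1, 0))
  ## antiparallel partner: sticky regions (nucleotides 8-15) in register
  sB <- mk(strand_spec(np_sticky_sequence()), c(2 + 2 * len - 7 * .fene_r0,
                                                8 + 2.9, 10),
           c(-1, 0, 0), c(0, -1, 0))
  sB$bodies$kind <- "np"
  sys <- merge_topologies(list(sA, sB), box = diag(3) * box_side,
                          periodic = c(TRUE, TRUE, TRUE),
                          meta = list(ka = ka))
  sys
}

#' Count close complementary base pairs between two strands
#'
#' @param top A system containing DNA strands.
#' @param rhyb Distance criterion in sigma.
#' @return Number of complementary inter-strand base pairs within
#'   `rhyb`.
#' @export
count_base_pairs <- function(top, rhyb = 1.5) {
  s <- top$sites
  bs <- s[s$species == "dna_base" & !is.na(s$base) & s$base != "N", ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  gid <- bs$body * 100L + bs$strand
  pos <- as.matrix(bs[, c("x", "y", "z")])
  n <- 0L
  for (i in seq_len(nrow(bs))) {
    dr <- sweep(pos, 2, pos[i, ], "-")
    if (!is.null(top$box)) dr <- minimum_image(dr, top$box, top$periodic)
    ok <- rowSums(dr^2) < rhyb^2 & gid != gid[i] &
      bs$base == comp[[bs$base[i]]]
    n <- n + sum(ok)
  }
  as.integer(n / 2)
}
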