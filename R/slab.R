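## Plane-cut machinery shared by the broken-bond surface-energy oracle and
## the crystal-slab builder. All lengths inside this file are in units of
## the conventional lattice constant b unless noted.

## Conventional-cell basis of the CD structure: NP sublattice on the FCC
## points, cages offset by a quarter body diagonal.
.cd_basis <- function() {
  A <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  list(np = A, cage = A + 0.25)
}

## Bond vectors from each cage to its 4 NP neighbours (units of b).
.cage_bond_vecs <- function() {
  rbind(c(-1, -1, -1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1)) / 4
}

## Two short in-plane FCC translations for an integer Miller normal.
facet_inplane_vectors <- function(hkl) {
  n <- as.numeric(hkl)
  rng <- -3:3
  cand <- as.matrix(expand.grid(rng, rng, rng))
  cand <- cand[(rowSums(cand) %% 2) == 0 & rowSums(abs(cand)) > 0, ] / 2
  cand <- cand[abs(cand %*% n) < 1e-9, , drop = FALSE]
  if (nrow(cand) < 2) stop("not a lattice plane: (", paste(hkl, collapse = ""), ")")
  len <- sqrt(rowSums(cand^2))
  cand <- cand[order(len), , drop = FALSE]
  u1 <- cand[1, ]
  cr <- t(apply(cand, 1, function(v) c(u1[2] * v[3] - u1[3] * v[2],
                                       u1[3] * v[1] - u1[1] * v[3],
                                       u1[1] * v[2] - u1[2] * v[1])))
  ok <- sqrt(rowSums(cr^2)) > 1e-9
  u2 <- cand[which(ok)[1], ]
  u2 <- u2 - round(sum(u1 * u2) / sum(u1 * u1)) * u1
  list(u1 = u1, u2 = u2, n = n)
}

## Layer structure along an integer Miller normal: distinct fractional
## projections (mod 1) of the two sublattices, with species labels.
cd_layer_structure <- function(hkl) {
  n <- as.numeric(hkl)
  basis <- .cd_basis()
  s_np <- sort(unique(round((basis$np %*% n) %% 1, 9)))
  s_cage <- sort(unique(round((basis$cage %*% n) %% 1, 9)))
  lay <- rbind(data.frame(s = s_np, kind = "np"),
               data.frame(s = s_cage, kind = "cage"))
  lay <- lay[!duplicated(lay$s), ]
  lay[order(lay$s), ]
}

#' Broken-bond density of a cubic-diamond facet
#'
#' Counts severed nearest-neighbour cage-NP links per unit area for a cut
#' plane normal to `hkl`, exactly, on a periodic supercell. Candidate cut
#' positions are the midpoints between consecutive atomic layers; the
#' `"min"` termination selects the one severing fewest bonds.
#'
#' @param hkl Integer Miller triple, e.g. `c(1, 1, 1)`.
#' @param termination `"min"` (default), `"max"`, or a numeric offset
#'   (fractional, in units of the layer period) to cut at.
#' @param supercell Cells per axis of the counting supercell (the counts
#'   are exact for any size >= 2).
#' @param b Lattice constant (sets the area unit; default 1).
#' @return A list with `per_area` (broken bonds per unit area),
#'   `per_surface_body`, the surface-layer species `surface_kind`,
#'   `cut` (fractional offset), and `scan`, the full table over candidate
#'   cuts.
#' @export
broken_bond_density <- function(hkl, termination = "min", supercell = 4L,
                                b = 1) {
  n <- as.numeric(hkl)
  if (length(n) != 3 || any(n != round(n)) || all(n == 0))
    stop("hkl must be a nonzero integer Miller triple")
  M <- as.integer(supercell)
  nlen <- sqrt(sum(n^2))
  area_total <- M^3 * nlen                 # total plane-set area on the torus
  basis <- .cd_basis()
  cells <- as.matrix(expand.grid(0:(M - 1), 0:(M - 1), 0:(M - 1)))
  cage_pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    sweep(basis$cage, 2, as.numeric(cells[i, ]), "+")))
  bvec <- .cage_bond_vecs()
  s_i <- as.numeric(cage_pos %*% n)
  ds <- as.numeric(bvec %*% n)

  lay <- cd_layer_structure(hkl)
  svals <- lay$s
  gaps <- data.frame(
    lo = svals,
    hi = c(svals[-1], svals[1] + 1),
    below = lay$kind
  )
  gaps$cut <- (gaps$lo + gaps$hi) / 2

  count_cut <- function(cc) {
    tot <- 0L
    for (k in seq_len(nrow(bvec))) {
      a <- s_i; bb <- s_i + ds[k]
      lo <- pmin(a, bb); hi <- pmax(a, bb)
      tot <- tot + sum(floor(hi - cc) - floor(lo - cc))
    }
    tot
  }
  gaps$crossings <- vapply(gaps$cut, count_cut, numeric(1))
  gaps$per_area <- gaps$crossings / area_total / b^2

  ## surface bodies: all atoms in the layer just below each cut
  all_pos <- rbind(
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
      sweep(basis$np, 2, as.numeric(cells[i, ]), "+"))),
    cage_pos)
  s_all <- round(as.numeric(all_pos %*% n) %% 1, 9)
  gaps$surface_atoms <- vapply(gaps$lo, function(s0)
    sum(abs(s_all - round(s0 %% 1, 9)) < 1e-7), numeric(1))
  gaps$per_surface_body <- gaps$crossings / gaps$surface_atoms

  pick <- if (identical(termination, "min")) {
    which.min(gaps$crossings)
  } else if (identical(termination, "max")) {
    which.max(gaps$crossings)
  } else if (is.numeric(termination)) {
    which.min(abs(gaps$cut - termination))
  } else stop("unknown termination: ", termination)

  list(hkl = as.integer(hkl),
       per_area = gaps$per_area[pick],
       per_surface_body = gaps$per_surface_body[pick],
       surface_kind = gaps$below[pick],
       cut = gaps$cut[pick],
       scan = gaps)
}

#' Broken-bond surface-energy ratios of the low-index facets
#'
#' Severed-link densities per area for (100), (110) and (111) at their
#' minimal terminations, relative to (111).
#'
#' @param supercell Counting supercell size.
#' @return A data.frame with columns `facet`, `per_area`, `gamma_rel`.
#' @export
broken_bond_gamma_table <- function(supercell = 4L) {
  fac <- list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  pa <- vapply(fac, function(h)
    broken_bond_density(h, supercell = supercell)$per_area, numeric(1))
  data.frame(facet = c("100", "110", "111"), per_area = pa,
             gamma_rel = pa / pa[3])
}

#' Build a crystal slab exposing a low-index facet
#'
#' Periodic in the plane of the facet, non-periodic along z. Layers are
#' selected downward from a cut plane chosen by `termination`:
#' `"min_broken"` (default) starts below the minimal-broken-bond cut, so
#' each ideal (111)/(110) surface body dangles the fewest bonds;
#' `"cage_both_sides"` (the (100) choice) starts below a cage layer and
#' extends the stack so both exposed faces are cage layers.
#'
#' @param facet Integer Miller triple among (100), (110), (111).
#' @param surface_cells In-plane replications of the 2D surface mesh.
#' @param n_layers Number of atomic (body) layers.
#' @param d,ka NP diameter and DNA stiffness.
#' @param b Lattice constant; defaults to [default_lattice_constant()].
#' @param vacuum Free space added along z, in sigma.
#' @param termination See above.
#' @param bodies_only If `TRUE`, body centers only.
#' @return A `cd_topology` system, periodic in x and y only.
#' @export
build_slab <- function(facet = c(1, 1, 1), surface_cells = 4L,
                       n_layers = 8L, d = 40, ka = 1, b = NULL,
                       vacuum = NULL, termination = NULL,
                       bodies_only = FALSE) {
  key <- paste(sort(abs(as.integer(facet)), decreasing = TRUE), collapse = "")
  if (!key %in% c("100", "110", "111"))
    stop("unsupported facet: (", paste(facet, collapse = ""), ")")
  if (is.null(termination))
    termination <- if (key == "100") "cage_both_sides" else "min_broken"
  if (is.null(b)) b <- default_lattice_constant(d)
  if (is.null(vacuum)) vacuum <- 1.5 * b
  n <- as.numeric(facet)
  nlen <- sqrt(sum(n^2))
  ip <- facet_inplane_vectors(facet)
  bb <- broken_bond_density(facet, termination = "min")
  lay <- cd_layer_structure(facet)

  ## top cut: minimal-broken gap, or the gap sitting above a cage layer
  if (termination == "min_broken") {
    c_top <- bb$cut
  } else if (termination == "cage_both_sides") {
    gs <- bb$scan
    c_top <- gs$cut[gs$below == "cage"][1]
  } else stop("unknown termination: ", termination)

  ## descending sequence of layer s-values below the cut
  base_s <- lay$s
  cand <- sort(unique(c(outer(base_s, -(0:(ceiling(n_layers /
    nrow(lay)) + 2)), "+"))), decreasing = TRUE)
  cand <- cand[cand < c_top - 1e-9]
  sel_layers <- cand[seq_len(n_layers)]
  kind_of <- function(s) lay$kind[match(round(s %% 1, 9), round(lay$s, 9))]
  if (termination == "cage_both_sides") {
    while (kind_of(sel_layers[length(sel_layers)]) != "cage") {
      sel_layers <- c(sel_layers, cand[length(sel_layers) + 1])
    }
  }
  c_bot <- min(sel_layers) - (c_top - max(sel_layers))

  ## enumerate atoms of the slab within one in-plane cell
  nu <- n / sum(n^2)
  B3 <- rbind(ip$u1, ip$u2, nu)
  B3inv <- solve(B3)
  basis <- .cd_basis()
  span <- ceiling(max(abs(c(ip$u1, ip$u2))) + abs(c_bot) + 3)
  rng <- -span:span
  cells <- as.matrix(expand.grid(rng, rng, rng))
  atoms <- list()
  for (kind in c("np", "cage")) {
    for (ib in seq_len(nrow(basis[[kind]]))) {
      pos <- sweep(cells, 2, basis[[kind]][ib, ], "+")
      f <- pos %*% B3inv
      keep <- f[, 1] > -1e-7 & f[, 1] < 1 - 1e-7 &
        f[, 2] > -1e-7 & f[, 2] < 1 - 1e-7 &
        f[, 3] > c_bot & f[, 3] < c_top
      if (any(keep))
        atoms[[length(atoms) + 1]] <-
          data.frame(x = pos[keep, 1], y = pos[keep, 2], z = pos[keep, 3],
                     kind = kind, s = f[keep, 3])
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms <- atoms[!duplicated(round(as.matrix(atoms[, 1:3]), 7)), ]

  ## replicate in plane
  reps <- as.matrix(expand.grid(0:(surface_cells - 1),
                                0:(surface_cells - 1)))
  shift <- reps[, 1, drop = FALSE] %*% ip$u1 + reps[, 2, drop = FALSE] %*% ip$u2
  centers <- do.call(rbind, lapply(seq_len(nrow(shift)), function(i)
    sweep(as.matrix(atoms[, 1:3]), 2, shift[i, ], "+")))
  kinds <- rep(atoms$kind, nrow(shift))
  slayer <- rep(atoms$s, nrow(shift))

  ## rotate so the facet normal is +z and u1 lies along +x
  R1 <- rotation_between(n / nlen, c(0, 0, 1))
  u1r <- as.numeric(R1 %*% ip$u1)
  ang <- atan2(u1r[2], u1r[1])
  R2 <- rotation_from_vector(c(0, 0, -ang))
  Rt <- R2 %*% R1
  centers <- centers %*% t(Rt) * b
  A1 <- as.numeric(Rt %*% ip$u1) * surface_cells * b
  A2 <- as.numeric(Rt %*% ip$u2) * surface_cells * b
  thick <- (c_top - c_bot) / nlen * b
  A3 <- c(0, 0, thick + vacuum)
  ## put the slab mid-box along z
  z0 <- min(centers[, 3])
  centers[, 3] <- centers[, 3] - z0 + vacuum / 2 +
    (c_top - max(slayer)) / nlen * b
  box <- rbind(A1, A2, A3)
  dimnames(box) <- NULL

  lat <- list(centers = centers, species = kinds,
              cell = matrix(0L, nrow(centers), 3),
              basis = ifelse(kinds == "np", 1L, 2L), box = box, b = b,
              n = NA_integer_)
  meta <- list(d = d, ka = ka, b = b, facet = as.integer(facet),
               n_layers = length(sel_layers), layers = sel_layers,
               termination = termination, lattice = lat)
  if (bodies_only) {
    sys <- body_level_system(lat, d = d, ka = ka)
    sys$periodic <- c(TRUE, TRUE, FALSE)
    sys$meta <- utils::modifyList(sys$meta, meta)
    sys$bodies$layer <- round(slayer, 6)
    return(sys)
  }

  np_proto <- build_np(d, ka)
  cage_proto <- build_cage(ka, orientation = -1L)
  tops <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    proto <- if (kinds[i] == "np") np_proto else cage_proto
    tops[[i]] <- transform_topology(proto, R = Rt, shift = centers[i, ])
  }
  sys <- merge_topologies(tops, box = box,
                          periodic = c(TRUE, TRUE, FALSE), meta = meta)
  sys$bodies$basis <- ifelse(kinds == "np", 1L, 2L)
  sys$bodies$layer <- round(slayer, 6)

  ## sideways offsets for NP strands whose cage partner is present
  nb <- ideal_neighbor_map(sys)
  bonded_dirs <- tetrahedron_directions(1L) %*% t(Rt)
  verts <- dodecahedron_vertices(d) %*% t(Rt)
  vids <- apply(bonded_dirs, 1, function(u) which.max(verts %*% u))
  ctr <- as.matrix(sys$bodies[, c("cx", "cy", "cz")])
  r_nn <- sqrt(3) * b / 4
  nps <- which(sys$bodies$kind == "np")
  for (bi in nps) {
    for (m in 1:4) {
      tgt <- ctr[bi, ] + r_nn * bonded_dirs[m, ]
      dr <- sweep(ctr[sys$bodies$kind == "cage", , drop = FALSE], 2, tgt, "-")
      dr <- minimum_image(dr, sys$box, sys$periodic)
      if (min(sqrt(rowSums(dr^2))) < 0.05 * r_nn)
        sys <- offset_bonded_np_strands(sys, sys$bodies$body[bi], vids[m],
                                        cage_dirs = tetrahedron_directions(-1L) %*% t(Rt))
    }
  }
  sys
}
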