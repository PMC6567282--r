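test_that("cage topology has the printed composition and rest geometry", {
  cg <- build_cage(ka = 1)
  s <- cg$sites
  ## 6 edges x 7 beads + 4 vertices x 3 truncation beads, all edge type
  expect_equal(sum(s$species == "cage_edge"), 6 * 7 + 4 * 3)
  expect_equal(sum(s$species == "cage_center"), 1)
  expect_equal(sum(s$species == "cage_vertex_dna_anchor"), 4)
  ## 4 strands x 15 nucleotides x 2 sites (anchor is nucleotide 1)
  expect_equal(nrow(s), 54 + 1 + 4 * 30)
  expect_equal(unname(s$diameter[s$species == "cage_edge"][1]), 9.9)
  expect_equal(unname(s$diameter[s$species == "cage_center"]), 40)

  ## every FENE bond is built strictly inside (Delta, Delta + R0)
  pos <- as.matrix(s[, c("x", "y", "z")])
  b <- cg$bonds
  r <- sqrt(rowSums((pos[b$i, ] - pos[b$j, ])^2))
  expect_true(all(r > b$Delta & r < b$Delta + b$R0))
  ## parameterised bonds are at their printed rest lengths
  for (role in c("edge_first", "edge_edge", "vertex_edge", "anchor_center")) {
    sel <- b$role == role
    expect_equal(r[sel], b$Delta[sel] + 0.96, tolerance = 1e-8)
  }
  ## nearest-neighbour edge rest (7.32) is below the bead diameter (9.9):
  ## overlap is permitted because bonded pairs carry no pair term
  expect_lt(7.32, 9.9)

  ## Table row check: edge first neighbour
  p1 <- cdlattice:::.cage_bonds$edge_first
  expect_equal(unname(p1), c(240, 1.5, 8, 6.36))
})

test_that("strand grafts point outward with the angle at its minimum", {
  cg <- build_cage(ka = 1)
  pos <- as.matrix(cg$sites[, c("x", "y", "z")])
  graft <- cg$angles[cg$angles$role == "graft", ]
  for (g in seq_len(nrow(graft))) {
    v1 <- pos[graft$i[g], ] - pos[graft$j[g], ]   # anchor -> center
    v2 <- pos[graft$k[g], ] - pos[graft$j[g], ]   # anchor -> next bead
    cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(cth, -1, tolerance = 1e-9)       # angle is pi
  }
})

test_that("nanoparticle matches the dodecahedron oracle", {
  np <- build_np(d = 40)
  s <- np$sites
  expect_equal(sum(!s$species %in% c("dna_backbone", "dna_base")), 21)
  expect_equal(sum(!is.na(s$strand) & s$species == "dna_backbone"), 300)
  expect_equal(length(unique(s$strand[!is.na(s$strand)])), 20)
  ## exact regular-dodecahedron edge: circumdiameter / (sqrt(3) phi)
  verts <- as.matrix(s[s$species == "np_vertex", c("x", "y", "z")])
  dm <- as.matrix(dist(verts)); diag(dm) <- Inf
  phi <- (1 + sqrt(5)) / 2
  expect_equal(min(dm), 40 / (sqrt(3) * phi), tolerance = 1e-6)
  ## circumscribed diameter d
  expect_equal(max(sqrt(rowSums(verts^2))) * 2, 40, tolerance = 1e-9)
  ## bond shifts as printed: center-vertex d/2 - 0.96, vertex l - 0.96
  cv <- np$bonds[np$bonds$role == "np_center_vertex", ]
  expect_equal(unique(cv$Delta), 40 / 2 - 0.96)
  vv <- np$bonds[np$bonds$role == "np_vertex_vertex", ]
  expect_equal(unique(vv$Delta), 40 / 2.8 - 0.96)
  ## inscribed-sphere excluded volume for the central site
  ctr <- s[s$species == "np_center", ]
  expect_lt(ctr$pair_diameter, 40)
  expect_equal(unname(ctr$pair_diameter / 40), 0.7946545, tolerance = 1e-6)
  ## out-of-range diameters warn but build
  expect_warning(build_np(d = 130), "outside the supported range")
})

test_that("bulk lattice counts, box geometry and neighbour shells", {
  sys <- build_bulk_lattice(4, bodies_only = TRUE)
  expect_equal(sum(sys$bodies$kind == "np"), 64)
  expect_equal(sum(sys$bodies$kind == "cage"), 64)

  one <- build_bulk_lattice(1)
  expect_equal(nrow(one$bodies), 2)
  ## regular triclinic box: equal lengths, 60 degree angles
  L <- sqrt(rowSums(one$box^2))
  expect_equal(L, rep(L[1], 3))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    cth <- sum(one$box[pair[1], ] * one$box[pair[2], ]) / (L[pair[1]] * L[pair[2]])
    expect_equal(cth, 0.5, tolerance = 1e-12)
  }

  ## every cage has exactly 4 NP neighbours at sqrt(3) b / 4 (brute force)
  two <- build_bulk_lattice(2, bodies_only = TRUE)
  nb <- ideal_neighbor_map(two)
  expect_true(all(rowSums(!is.na(nb)) == 4))
  ## and each sublattice has the 12-neighbour FCC shell (3x supercell so
  ## the shell is not aliased by periodic images)
  three <- build_bulk_lattice(3, bodies_only = TRUE)
  ctr <- as.matrix(three$bodies[three$bodies$kind == "np",
                                c("cx", "cy", "cz")])
  b <- three$meta$b
  d12 <- apply(ctr, 1, function(p) {
    dr <- sweep(ctr, 2, p, "-")
    dr <- cdlattice:::minimum_image(dr, three$box, three$periodic)
    dd <- sort(sqrt(rowSums(dr^2)))
    sum(abs(dd - b / sqrt(2)) < 1e-6 * b)
  })
  expect_true(all(d12 == 12))

  ## infeasible lattice constants are rejected
  expect_error(build_bulk_lattice(1, b = 500), "strand reach")

  ## rebuilding is bit-identical
  a1 <- build_bulk_lattice(1); a2 <- build_bulk_lattice(1)
  expect_identical(a1$sites, a2$sites)
})

test_that("sticky sequences are complementary and not self-complementary", {
  cs <- cage_sticky_sequence(); ns <- np_sticky_sequence()
  expect_equal(ns, revcomp_dna(cs))
  expect_false(cs == revcomp_dna(cs))
  expect_error(strand_spec("ABC"), "")
})

test_that("slabs expose the right faces with the right counts", {
  sl <- build_slab(c(1, 1, 1), surface_cells = 4, n_layers = 8,
                   bodies_only = TRUE)
  expect_equal(nrow(sl$bodies), 128)
  top_z <- max(sl$bodies$cz)
  top <- sl$bodies[abs(sl$bodies$cz - top_z) < 1, ]
  expect_equal(nrow(top), 16)
  expect_true(all(top$kind == "np"))
  bot <- sl$bodies[abs(sl$bodies$cz - min(sl$bodies$cz)) < 1, ]
  expect_true(all(bot$kind == "cage"))
  ## periodic in plane only
  expect_equal(sl$periodic, c(TRUE, TRUE, FALSE))
  ## c is perpendicular to a and b
  expect_equal(sum(sl$box[3, ] * sl$box[1, ]), 0, tolerance = 1e-9)
  expect_equal(sum(sl$box[3, ] * sl$box[2, ]), 0, tolerance = 1e-9)

  ## (100): both exposed faces are cage layers
  s100 <- build_slab(c(1, 0, 0), surface_cells = 2, n_layers = 8,
                     bodies_only = TRUE)
  expect_equal(s100$bodies$kind[which.max(s100$bodies$cz)], "cage")
  expect_equal(s100$bodies$kind[which.min(s100$bodies$cz)], "cage")
  ## (100) box is orthogonal
  expect_equal(abs(s100$box[1, ] %*% s100$box[2, ])[1], 0, tolerance = 1e-9)

  expect_error(build_slab(c(2, 1, 0)), "unsupported facet")
})
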