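test_that("broken-bond counting reproduces the exact facet ratios", {
  tab <- broken_bond_gamma_table()
  expect_equal(tab$gamma_rel[tab$facet == "100"], sqrt(3), tolerance = 1e-12)
  expect_equal(tab$gamma_rel[tab$facet == "110"], sqrt(6) / 2,
               tolerance = 1e-12)
  ## per-surface-body counts: (100) -> 2; (111) minimal 1, other 3; (110) 1
  expect_equal(broken_bond_density(c(1, 0, 0))$per_surface_body, 2)
  b111 <- broken_bond_density(c(1, 1, 1))
  expect_equal(b111$per_surface_body, 1)
  expect_equal(broken_bond_density(c(1, 1, 1),
                                   termination = "max")$per_surface_body, 3)
  expect_equal(broken_bond_density(c(1, 1, 0))$per_surface_body, 1)
  ## supercell-size independence
  for (m in c(2L, 5L)) {
    t2 <- broken_bond_gamma_table(supercell = m)
    expect_equal(t2$gamma_rel, tab$gamma_rel, tolerance = 1e-12)
  }
  expect_error(broken_bond_density(c(0, 0, 0)), "Miller")
})

test_that("Wulff construction produces the expected shapes", {
  ## {100} alone: cube, full area in one family
  w <- wulff_construct(c("100" = 1))
  expect_equal(w$label, "cube")
  expect_equal(unname(w$area_fractions[["100"]]), 1)

  ## high gamma100: octahedron with slight {110} edge truncation
  w2 <- wulff_construct(c("100" = 2, "110" = 1.22, "111" = 1))
  expect_equal(unname(w2$area_fractions[["100"]]), 0)
  expect_gt(w2$area_fractions[["110"]], 0)
  expect_lt(w2$area_fractions[["110"]], 0.05)
  expect_match(w2$label, "octahedron")

  ## flexible-DNA regime: octahedron truncated at corners by cube faces
  w3 <- wulff_construct(c("100" = 1.2, "110" = 1.22, "111" = 1))
  expect_gt(w3$area_fractions[["100"]], 0)
  expect_gt(w3$area_fractions[["111"]], 0)
  expect_equal(w3$label, "truncated octahedron")

  ## scale invariance of the shape
  w4 <- wulff_construct(3 * c("100" = 1.2, "110" = 1.22, "111" = 1))
  expect_equal(w4$area_fractions, w3$area_fractions, tolerance = 1e-6)

  ## lambda = gamma / ell constant across retained facets
  expect_lt(w3$lambda_spread, 1e-6)

  ## degenerate / missing families fail loudly
  expect_error(wulff_construct(c("100" = -1)), "")
})

test_that("shape thresholds sit at the analytic Wulff geometry", {
  sc <- shape_threshold_scan(gamma110_rel = 1.22, tol = 1e-4)
  expect_equal(sc$cube_only, 1 / sqrt(3), tolerance = 5e-4)
  ## with gamma110/gamma111 = 1.22 the {100} family vanishes where the
  ## (110)-truncated apex passes the cube plane: sqrt(2) * 1.22
  expect_equal(sc$octahedron_only, sqrt(2) * 1.22, tolerance = 5e-4)
  expect_equal(sc$label_below, "cube")
  expect_match(sc$label_above, "octahedron")
  ## with the exact broken-bond gamma110 ratio the threshold is sqrt(3)
  sc2 <- shape_threshold_scan(gamma110_rel = sqrt(6) / 2, tol = 1e-4)
  expect_equal(sc2$octahedron_only, sqrt(3), tolerance = 5e-4)
})

test_that("facet area fractions are monotone in gamma100/gamma111", {
  rs <- seq(0.7, 1.6, by = 0.15)
  f100 <- vapply(rs, function(r)
    wulff_construct(c("100" = r, "110" = 1.22, "111" = 1))$
      area_fractions[["100"]], numeric(1))
  f111 <- vapply(rs, function(r)
    wulff_construct(c("100" = r, "110" = 1.22, "111" = 1))$
      area_fractions[["111"]], numeric(1))
  expect_true(all(diff(f100) <= 1e-9))
  expect_true(all(diff(f111) >= -1e-9))
})

test_that("slab surface-energy estimator matches the counting oracle on a toy Hamiltonian", {
  ## toy model: energy = -1 per intact nearest-neighbour link; slabs of
  ## each facet lose exactly the broken-bond count
  count_links <- function(sys) {
    nb <- ideal_neighbor_map(sys)
    sum(!is.na(nb))
  }
  bulk <- build_bulk_lattice(3, bodies_only = TRUE)
  e_bulk <- -count_links(bulk)
  gam <- vapply(list(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), function(hkl) {
    sl <- build_slab(hkl, surface_cells = 3, n_layers = 8,
                     bodies_only = TRUE, termination = "min_broken")
    fe <- surface_energy_from_slab(
      e_slab = rep(-count_links(sl), 5), e_bulk = rep(e_bulk, 5),
      n_bodies_slab = nrow(sl$bodies), n_bodies_bulk = nrow(bulk$bodies),
      area = slab_area(sl), hkl = hkl)
    fe$gamma
  }, numeric(1))
  bb <- broken_bond_gamma_table()
  expect_equal(gam[1] / gam[3], bb$gamma_rel[1], tolerance = 1e-9)
  expect_equal(gam[2] / gam[3], bb$gamma_rel[2], tolerance = 1e-9)

  ## restoring periodicity along z (no free surface) gives gamma = 0
  fe0 <- surface_energy_from_slab(rep(e_bulk, 5), rep(e_bulk, 5),
                                  nrow(bulk$bodies), nrow(bulk$bodies),
                                  area = 100)
  expect_equal(fe0$gamma, 0)
  expect_error(surface_energy_from_slab(1, 1, 0, 1, 10), "positive")
})

test_that("slab thickness does not change the counting surface energy", {
  gam_at <- function(n_layers) {
    sl <- build_slab(c(1, 1, 1), surface_cells = 2, n_layers = n_layers,
                     bodies_only = TRUE)
    nb <- ideal_neighbor_map(sl)
    bulk_links_per_body <- 2     # 4 links per cage / 2 bodies
    broken <- bulk_links_per_body * nrow(sl$bodies) * 2 - 2 * sum(!is.na(nb))
    broken / (2 * slab_area(sl))
  }
  expect_equal(gam_at(6), gam_at(8), tolerance = 1e-9)
  expect_equal(gam_at(8), gam_at(10), tolerance = 1e-9)
})

test_that("Wulff OFF export writes a closed mesh header", {
  w <- wulff_construct(c("100" = 1.2, "110" = 1.22, "111" = 1))
  f <- tempfile(fileext = ".off")
  write_wulff_off(w, f)
  lines <- readLines(f)
  expect_equal(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(counts[1], nrow(w$vertices))
  expect_gt(counts[2], 4)
})
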