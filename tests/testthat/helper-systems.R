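## Shared fixtures: tiny systems built in code.

make_bonded_pair <- function(r, kb = 30, R0 = 1.5, eps = 1, Delta = 0) {
  sites <- data.frame(id = 1:2, body = 1L, species = "dna_backbone",
                      base = NA_character_, strand = NA_integer_,
                      diameter = 1, pair_diameter = 1, mass = 1,
                      x = c(0, r), y = 0, z = 0)
  cdlattice:::new_topology(
    sites,
    data.frame(i = 1L, j = 2L, kb = kb, R0 = R0, eps = eps, Delta = Delta,
               role = "test"),
    cdlattice:::empty_angles(),
    data.frame(body = 1L, kind = "np", cx = 0, cy = 0, cz = 0))
}

make_free_site <- function() {
  sites <- data.frame(id = 1L, body = 1L, species = "dna_backbone",
                      base = NA_character_, strand = NA_integer_,
                      diameter = 1, pair_diameter = 1, mass = 1,
                      x = 0, y = 0, z = 0)
  cdlattice:::new_topology(sites, cdlattice:::empty_bonds(),
                           cdlattice:::empty_angles(),
                           data.frame(body = 1L, kind = "np",
                                      cx = 0, cy = 0, cz = 0))
}

## random bonded cluster with angles and mixed base letters, bonds set
## to safe lengths
make_random_cluster <- function(seed = 2, n = 10) {
  set.seed(seed)
  sites <- data.frame(id = 1:n, body = 1L, species = "dna_backbone",
                      base = c(NA, "A", "T", "G", "C", "A", NA, NA, "T", "G"),
                      strand = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
                      diameter = 1, pair_diameter = 1, mass = 1,
                      x = rnorm(n, sd = 1.5), y = rnorm(n, sd = 1.5),
                      z = rnorm(n, sd = 1.5))
  bonds <- data.frame(i = 1:5, j = c(2:5, 6), kb = 30, R0 = 1.5, eps = 1,
                      Delta = 0.5, role = "test")
  angs <- data.frame(i = 1:3, j = 2:4, k = 3:5, ka = 1.2, role = "test")
  top <- cdlattice:::new_topology(
    sites, bonds, angs,
    data.frame(body = 1L, kind = "np", cx = 0, cy = 0, cz = 0))
  pos <- cdlattice:::site_positions(top)
  for (b in seq_len(nrow(bonds))) {
    d <- pos[bonds$j[b], ] - pos[bonds$i[b], ]
    pos[bonds$j[b], ] <- pos[bonds$i[b], ] + d / sqrt(sum(d^2)) * 1.3
  }
  cdlattice:::set_site_positions(top, pos)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
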