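test_that("bond and pair potentials match their closed forms", {
  ## standard FENE minimum: the printed 0.96 rest length
  r0 <- fene_rest_length()
  expect_equal(r0, 0.96, tolerance = 1e-2)
  pe <- potential_energy(make_bonded_pair(r0))
  expect_lt(max(abs(pe$forces)), 1e-3)

  ## expanded WCA vanishes at its cutoff Delta_ij + 2^(1/6)
  s <- make_bonded_pair(1); s$bonds <- s$bonds[0, ]
  s$sites$x[2] <- 2^(1 / 6) + 1e-9
  expect_equal(potential_energy(s)$energy$wca, 0)
  ## repulsive inside the summed radii
  s$sites$x[2] <- 0.95
  expect_gt(potential_energy(s)$energy$wca, 0)
  ## shifted-core pair: contact moves out by (di + dj)/2 - 2^(1/6)
  s$sites$pair_diameter <- c(9.9, 1)
  s$sites$x[2] <- (9.9 + 1) / 2 + 0.05
  expect_equal(potential_energy(s)$energy$wca, 0)
  s$sites$x[2] <- (9.9 + 1) / 2 - 0.05
  expect_gt(potential_energy(s)$energy$wca, 0)

  ## overstretch reports the offending bond
  expect_error(potential_energy(make_bonded_pair(1.55)), "overstretched")
})

test_that("analytic forces match central differences", {
  top <- make_random_cluster()
  pe <- potential_energy(top)
  h <- 1e-6
  cols <- c("x", "y", "z")
  for (i in c(1, 4, 6, 9)) {
    for (k in 1:3) {
      tp <- top; tm <- top
      tp$sites[i, cols[k]] <- tp$sites[i, cols[k]] + h
      tm$sites[i, cols[k]] <- tm$sites[i, cols[k]] - h
      fnum <- -(potential_energy(tp)$energy$total -
                  potential_energy(tm)$energy$total) / (2 * h)
      expect_equal(pe$forces[i, k], fnum,
                   tolerance = 1e-6 * max(1, abs(fnum)))
    }
  }
})

test_that("NVT equipartition and Langevin temperature control", {
  tp <- make_free_site()
  res <- run_nvt(tp, T = 0.5, n_steps = 150000, seed = 3, stride = 25,
                 tethers = data.frame(i = 1L, x = 0, y = 0, z = 0, k = 2))
  u2 <- mean(vapply(res$frames, function(f) sum(f^2), numeric(1)))
  expect_equal(u2, 3 * 0.5 / 2, tolerance = 0.05)
  ## temperature estimator within 3 standard errors
  Tm <- res$thermo$T[-(1:100)]
  se <- sd(Tm) / sqrt(length(Tm))
  expect_lt(abs(mean(Tm) - 0.5), max(3 * se, 0.02))
})

test_that("NVE conserves energy and momentum; restarts are identical", {
  pair <- make_bonded_pair(1.05)
  warm <- run_nvt(pair, T = 0.2, n_steps = 100, seed = 5)
  nve <- run_nve(warm$system, n_steps = 10000, v0 = warm$velocities,
                 thermo_stride = 10)
  E <- nve$thermo$E_pot + nve$thermo$E_kin
  n <- length(E)
  drift <- abs(mean(tail(E, n %/% 10)) - mean(head(E, n %/% 10))) /
    abs(mean(E))
  expect_lt(drift, 1e-4)
  p0 <- colSums(warm$velocities); p1 <- colSums(nve$velocities)
  expect_lt(max(abs(p1 - p0)), 1e-10)

  ## deterministic restart: same seed, same velocities -> same path
  a <- run_nvt(pair, T = 0.2, n_steps = 500, seed = 9, stride = 100)
  b <- run_nvt(pair, T = 0.2, n_steps = 500, seed = 9, stride = 100)
  expect_identical(a$frames, b$frames)
})

test_that("minimisation is monotone non-increasing", {
  top <- make_random_cluster(seed = 7)
  e0 <- potential_energy(top)$energy$total
  mn <- run_minimize(top, n_steps = 200)
  expect_lte(mn$energy$total, e0)
})

test_that("two-strand melting: hybridized cold, melted hot", {
  frac_bound <- function(T, seed) {
    sys <- build_strand_pair()
    res <- run_nvt(sys, T = T, n_steps = 60000, seed = seed, stride = 2000)
    use <- res$frames[round(length(res$frames) / 2):length(res$frames)]
    mean(vapply(use, function(X)
      count_base_pairs(cdlattice:::set_site_positions(sys, X)) >= 4,
      logical(1)))
  }
  expect_gt(frac_bound(0.09, 11), 0.5)
  expect_lt(frac_bound(0.30, 11), 0.5)
})

test_that("bulk cell holds four lattice links through NVT at T = 0.09", {
  cell <- build_bulk_lattice(1)
  h0 <- count_hybridized_pairs(cell)
  expect_equal(unname(h0$per_cage), 4)
  expect_equal(h0$n_reorientation, 0)
  mn <- run_minimize(cell, n_steps = 200)
  res <- run_nvt(mn$system, T = 0.09, n_steps = 5000, seed = 2)
  expect_false(res$aborted)
  h1 <- count_hybridized_pairs(res$system)
  expect_equal(unname(h1$per_cage), 4)
})

test_that("zero-pressure run relaxes the box without diffusion", {
  cell <- build_bulk_lattice(1)
  mn <- run_minimize(cell, n_steps = 200)
  res <- run_npt_zero_pressure(mn$system, T = 0.09, n_steps = 4000,
                               seed = 4, thermo_stride = 200)
  expect_false(res$aborted)
  ## triclinic angles preserved by the isotropic barostat
  L <- sqrt(rowSums(res$system$box^2))
  cth <- sum(res$system$box[1, ] * res$system$box[2, ]) / (L[1] * L[2])
  expect_equal(cth, 0.5, tolerance = 1e-9)
  ## no body moved by more than a quarter lattice spacing
  d0 <- as.matrix(cell$bodies[, c("cx", "cy", "cz")])
  d1 <- as.matrix(res$system$bodies[, c("cx", "cy", "cz")])
  expect_lt(max(abs(d1 - d0)), cell$meta$b / 4)
})
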