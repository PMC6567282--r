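b40 <- default_lattice_constant(40)

test_that("translational plateau matches the oscillator closed form", {
  spec <- harmonic_surrogate_spec(n = 2, b = b40,
                                  ktrans = c(np = 0.5, cage = 0.5),
                                  T = 0.09, n_frames = 8000, seed = 3,
                                  model = "oscillator")
  tr <- sample_independent_oscillators(spec)
  m <- msd_translational(tr, "both")
  ## site-referenced variance: 3 kB T / k
  expect_equal(m$u2, 3 * 0.09 / 0.5, tolerance = 0.03)
  ## lag-curve plateau is twice the site-referenced value
  expect_equal(m$plateau_lag, 2 * m$u2, tolerance = 0.05)
  ## plateau from the curve agrees with the direct variance within 2%
  expect_equal(m$plateau_lag / 2, m$u2, tolerance = 0.02)
})

test_that("temperature scaling diagnostic: T dln<u2>/dlnT = 1", {
  u2_at <- function(T, seed) {
    spec <- harmonic_surrogate_spec(n = 2, b = b40, T = T,
                                    n_frames = 8000, seed = seed,
                                    model = "oscillator")
    msd_translational(sample_independent_oscillators(spec), "both")$u2
  }
  lder <- log(u2_at(0.18, 5) / u2_at(0.09, 5)) / log(2)
  expect_equal(lder, 1, tolerance = 0.05)
})

test_that("rotational curves: static and rigid-rotation geometry", {
  ## static frame: theta(t) identically zero
  lat <- cd_lattice_sites(1, b40)
  nb <- nrow(lat$centers)
  verts <- array(0, c(5, nb, 1, 3))
  for (f in 1:5) for (b in 1:nb) verts[f, b, 1, ] <- c(1, 0, 0)
  tr <- cd_trajectory(array(rep(t(lat$centers), each = 5), c(5, nb, 3)),
                      lat$species, lat$box, vertices = verts)
  m <- suppressWarnings(msd_rotational(tr, "both"))
  expect_equal(max(m$curve$theta2), 0)

  ## rigid rotation by alpha about z with the vertex along x: theta = alpha
  alpha <- 0.3
  R <- rotation_from_vector(c(0, 0, alpha))
  verts2 <- verts
  for (b in 1:nb) verts2[2:5, b, 1, ] <-
    matrix(rep(as.numeric(R %*% c(1, 0, 0)), 4), 4, 3, byrow = TRUE)
  tr2 <- cd_trajectory(tr$coords, lat$species, lat$box, vertices = verts2)
  m2 <- suppressWarnings(msd_rotational(tr2, "both"))
  ## lag-1 value mixes frames; read the raw angle between frames 1 and 2
  v1 <- verts[1, 1, 1, ]; v2 <- verts2[2, 1, 1, ]
  expect_equal(acos(sum(v1 * v2)), alpha, tolerance = 1e-12)
})

test_that("arc-constrained rotations reproduce the size trends", {
  phi2_at <- function(d, seed) {
    spec <- harmonic_surrogate_spec(n = 2, b = b40, arc_s = 5, d_np = d,
                                    d_cage = 40, T = 0.09,
                                    n_frames = 5000, seed = seed)
    tr <- sample_rigid_body_rotations(spec)
    c(np = msd_rotational(tr, "np")$phi2,
      cage = msd_rotational(tr, "cage")$phi2)
  }
  small <- phi2_at(40, 7); large <- phi2_at(120, 7)
  ## NP amplitude falls with d; the cage amplitude is set by the shared
  ## arc on the fixed 40-sigma cage, hence unchanged
  expect_lt(large[["np"]], small[["np"]])
  expect_equal(large[["np"]] / small[["np"]], (40 / 120)^2,
               tolerance = 0.1)
  expect_equal(large[["cage"]] / small[["cage"]], 1, tolerance = 0.1)
})

test_that("entropy decomposition identities", {
  tab <- data.frame(d = c(40, 80), ka = c(0.5, 0.5),
                    u2_np = c(1, exp(1)), u2_cage = c(1, exp(1)),
                    phi2_np = c(0.2, 0.2), phi2_cage = c(0.1, 0.1))
  rep <- entropy_decomposition(tab, T = 0.09)
  ## reference row: all zeros
  expect_equal(rep$dS_trans[1], 0)
  expect_equal(rep$dF[1], 0)
  ## both species' u2 ratios equal e -> dS_trans = 3 kB
  expect_equal(rep$dS_trans[2], 3)
  ## unchanged rotations contribute nothing
  expect_equal(rep$dS_rot[2], 0)
  ## antisymmetry under swapping system and reference
  rev <- entropy_decomposition(tab[2:1, ], T = 0.09, reference = 1)
  expect_equal(rev$dS_trans[2], -rep$dS_trans[2])
  ## errors
  expect_error(entropy_decomposition(transform(tab, u2_np = c(-1, 1))),
               "positive")
})

test_that("energy component: equipartition makes dE vanish at equal T", {
  ## two harmonic surrogates with different springs at the same T have
  ## equal mean potential energy per mode (kB T / 2 each)
  e_of <- function(k, seed) {
    spec <- harmonic_surrogate_spec(n = 2, b = b40,
                                    ktrans = c(np = k, cage = k),
                                    T = 0.09, n_frames = 6000, seed = seed,
                                    model = "oscillator")
    tr <- sample_independent_oscillators(spec)
    lat <- cd_lattice_sites(2, b40)
    en <- vapply(seq_len(dim(tr$coords)[1]), function(f) {
      u <- tr$coords[f, , ] - lat$centers
      0.5 * k * sum(u^2)
    }, numeric(1))
    en
  }
  e1 <- e_of(0.5, 3); e2 <- e_of(2, 4)
  de <- energy_component(e1, e2, n_cells = 8)
  ## per cell: 2 bodies x 3 dof x T/2 = 0.27; dE ~ 0
  expect_equal(mean(e1) / 8, 2 * 3 * 0.09 / 2, tolerance = 0.05)
  expect_lt(abs(de), 0.05 * mean(e1) / 8)
  expect_equal(energy_component(e1, e1, 8), 0)
})

test_that("per-stiffness re-referencing collapses the size dependence", {
  ## amplitudes built as f(d) * g(ka): the per-ka view removes g entirely
  ds <- c(40, 80, 120); kas <- c(0.5, 2.0)
  tab <- expand.grid(d = ds, ka = kas)
  tab$u2_np <- (tab$d / 40) / tab$ka
  tab$u2_cage <- tab$u2_np
  tab$phi2_np <- (40 / tab$d)^2 / tab$ka
  tab$phi2_cage <- (tab$d / 40)^0.5 / tab$ka
  rep <- entropy_decomposition(tab, T = 0.09)
  per <- attr(rep, "per_stiffness")
  for (dd in ds) {
    sub <- per[per$d == dd, ]
    expect_equal(max(sub$dF) - min(sub$dF), 0, tolerance = 1e-12)
  }
})
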