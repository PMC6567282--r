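b40 <- default_lattice_constant(40)
hm <- cd_harmonic_model(b = b40)

test_that("mode amplitudes satisfy equipartition and the analytic covariance", {
  spec <- harmonic_surrogate_spec(n = 2, b = b40, kr = 1, ktheta = 0.1,
                                  T = 0.09, n_frames = 8000, seed = 7)
  traj <- sample_correlated_modes(spec, model = hm)
  ## covariance of the Fourier modes reproduces kB T D(q)^-1 elementwise
  pts <- dispersion_fit_points(2, b40)
  q <- c(pts$qx[2], pts$qy[2], pts$qz[2])
  est <- estimate_dynamical_matrix(traj, q, T = 0.09)
  Cth <- 0.09 * solve(model_dynamical_matrix(hm, q, 1, 0.1))
  expect_lt(max(abs(est$C - Cth)) / max(abs(Cth)), 0.05)
  ## equipartition per mode: omega^2 <|Q|^2> / kB T = 1
  ratio <- est$omega2[est$omega2 > 0] /
    model_frequencies(hm, q, 1, 0.1)[est$omega2 > 0]^2
  expect_true(all(abs(ratio - 1) < 0.06))
})

test_that("doubling T doubles the translational amplitude", {
  u2_at <- function(T) {
    spec <- harmonic_surrogate_spec(n = 2, b = b40, T = T,
                                    n_frames = 4000, seed = 5)
    traj <- sample_correlated_modes(spec, model = hm)
    msd_translational(traj, "both")$u2
  }
  expect_equal(u2_at(0.18) / u2_at(0.09), 2, tolerance = 0.05)
})

test_that("surrogate amplitudes are symmetric across species when springs are", {
  spec <- harmonic_surrogate_spec(n = 2, b = b40, ktrans = c(np = 1, cage = 1),
                                  T = 0.09, n_frames = 6000, seed = 3,
                                  model = "oscillator")
  tr <- sample_independent_oscillators(spec)
  u2n <- msd_translational(tr, "np")$u2
  u2c <- msd_translational(tr, "cage")$u2
  expect_equal(u2n / u2c, 1, tolerance = 0.05)
  expect_equal(u2n, 3 * 0.09 / 1, tolerance = 0.05)
})

test_that("rigid-body rotations have the closed-form amplitude", {
  spec <- harmonic_surrogate_spec(n = 2, b = b40,
                                  krot = c(np = 2, cage = 0.5),
                                  T = 0.09, n_frames = 10000, seed = 9)
  tr <- sample_rigid_body_rotations(spec)
  p2n <- msd_rotational(tr, "np")$phi2
  p2c <- msd_rotational(tr, "cage")$phi2
  ## krot recovered from the plateau within 3%
  expect_equal(3 * 0.09 / p2n, 2, tolerance = 0.03)
  expect_equal(3 * 0.09 / p2c, 0.5, tolerance = 0.03)

  ## arc-length constraint: d_NP = 2 d_cage -> amplitude ratio 1/4
  spec2 <- harmonic_surrogate_spec(n = 2, b = b40, arc_s = 5,
                                   d_np = 80, d_cage = 40, T = 0.09,
                                   n_frames = 8000, seed = 11)
  tr2 <- sample_rigid_body_rotations(spec2)
  r <- msd_rotational(tr2, "np")$phi2 / msd_rotational(tr2, "cage")$phi2
  expect_equal(r, 1 / 4, tolerance = 0.05)

  ## infinite stiffness limit: orientations freeze
  spec3 <- harmonic_surrogate_spec(n = 1, b = b40,
                                   krot = c(np = 1e9, cage = 1e9),
                                   T = 0.09, n_frames = 200, seed = 1)
  tr3 <- sample_rigid_body_rotations(spec3)
  expect_lt(msd_rotational(tr3, "both")$phi2, 1e-6)
})

test_that("perturbed ideal lattice is reproducible and clean at zero amplitude", {
  a <- perturbed_ideal_lattice(2, amplitude = 0.5, seed = 42)
  b <- perturbed_ideal_lattice(2, amplitude = 0.5, seed = 42)
  expect_identical(a$coords, b$coords)
  z <- perturbed_ideal_lattice(2, amplitude = 0)
  lat <- cd_lattice_sites(2, default_lattice_constant(40))
  expect_equal(z$coords[1, , ], lat$centers)
})

test_that("no diffusion: lag MSD plateaus for OU-correlated surrogates", {
  spec <- harmonic_surrogate_spec(n = 2, b = b40, T = 0.09,
                                  n_frames = 4000, seed = 13,
                                  mode_time = "ou", dt = 5)
  traj <- sample_correlated_modes(spec, model = hm)
  m <- msd_translational(traj, "both")
  expect_false(is.na(m$plateau_lag))
  ## lag plateau of uncorrelated tails is twice the site variance
  expect_equal(m$plateau_lag, 2 * m$u2, tolerance = 0.15)
})
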