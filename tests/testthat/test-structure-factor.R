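test_that("ideal lattice shows peaks only at allowed reflections", {
  tr <- perturbed_ideal_lattice(4, amplitude = 0)
  sq <- structure_factor(tr)
  b <- tr$lattice$b

  ## direct-summation oracle at chosen wavevectors (independent code path)
  direct_S <- function(q) {
    R <- tr$coords[1, , ]
    ph <- as.numeric(R %*% q)
    (sum(cos(ph))^2 + sum(sin(ph))^2) / nrow(R) - 1
  }
  q111 <- 2 * pi / b * c(1, 1, 1)
  q200 <- 2 * pi / b * c(2, 0, 0)
  q220 <- 2 * pi / b * c(2, 2, 0)
  N <- 128
  ## (111): the two sublattices interfere with |1 + e^{-i 3 pi/2}|^2 = 2
  expect_equal(direct_S(q111), N / 2 - 1)
  ## (200) forbidden by the diamond selection rule
  expect_equal(direct_S(q200), -1, tolerance = 1e-9)
  ## (220) fully in phase
  expect_equal(direct_S(q220), N - 1)

  ## package values at the same wavevectors agree with the oracle
  v <- sq$vectors
  find_vec <- function(q) {
    i <- which.min((v$qx - q[1])^2 + (v$qy - q[2])^2 + (v$qz - q[3])^2)
    v$S[i]
  }
  expect_equal(find_vec(q111), direct_S(q111), tolerance = 1e-9)
  expect_equal(find_vec(q200), direct_S(q200), tolerance = 1e-9)
  expect_equal(find_vec(q220), direct_S(q220), tolerance = 1e-9)

  ## peak table resolves every allowed reflection in range, and the
  ## (220)/(111) position ratio is sqrt(8/3)
  pt <- sq_peak_table(sq)
  expect_true(all(pt$resolved))
  expect_equal(pt$q_rel_theory[pt$label == "(220)"], sqrt(8 / 3))
})

test_that("uncorrelated positions give S(q) ~ 0", {
  set.seed(4)
  n <- 512
  box <- diag(3) * 50
  coords <- array(runif(3 * n * 4) * 50, c(4, n, 3))
  tr <- cd_trajectory(coords, species = rep("np", n), box = box)
  sq <- structure_factor(tr, q_max = 1.5)
  expect_lt(max(abs(sq$shells$S)), 3 / sqrt(n * 4) * sqrt(max(sq$shells$n_vec)))
  expect_lt(abs(mean(sq$vectors$S)), 3 / sqrt(n * 4))
})

test_that("S(q) is real/even and positions survive uniform dilation", {
  tr <- perturbed_ideal_lattice(2, amplitude = 2, seed = 3, n_frames = 4)
  sq <- structure_factor(tr)
  v <- sq$vectors
  ## even in q: S(q) == S(-q)
  key <- paste(round(-v$qx, 10), round(-v$qy, 10), round(-v$qz, 10))
  mkey <- paste(round(v$qx, 10), round(v$qy, 10), round(v$qz, 10))
  mirror <- match(key, mkey)
  expect_equal(v$S, v$S[mirror], tolerance = 1e-9)
  expect_gte(min(v$S), -1 - 1e-9)

  ## dilation: scale all coordinates and the box by 1.3
  tr2 <- tr
  tr2$coords <- tr$coords * 1.3
  tr2$box <- tr$box * 1.3
  tr2$lattice$b <- tr$lattice$b * 1.3
  sq2 <- structure_factor(tr2)
  p1 <- sq_peak_table(sq)
  p2 <- sq_peak_table(sq2)
  expect_equal(p1$q_rel_theory, p2$q_rel_theory)
  expect_equal(p1$S_peak, p2$S_peak, tolerance = 1e-9)
})

test_that("vibration amplitude damps high-q peaks (Debye-Waller)", {
  stiff <- perturbed_ideal_lattice(4, amplitude = 2, seed = 5, n_frames = 8)
  soft <- perturbed_ideal_lattice(4, amplitude = 8, seed = 5, n_frames = 8)
  rep <- peak_sharpness_report(list(stiff = structure_factor(stiff),
                                    soft = structure_factor(soft)))
  expect_gt(rep$max_resolved_q_rel[rep$system == "stiff"],
            rep$max_resolved_q_rel[rep$system == "soft"])
  expect_true(rep$doublet_resolved[rep$system == "stiff"])
  expect_false(rep$doublet_resolved[rep$system == "soft"])

  ## measured damping ratio between the two disorder levels follows
  ## exp(-q^2 (u2_soft - u2_stiff) / 3) on the strong low-q peaks
  pt_s <- sq_peak_table(structure_factor(soft))
  pt_t <- sq_peak_table(structure_factor(stiff))
  sel <- which(pt_t$q_rel_theory < 2.0)
  q <- pt_t$q_rel_theory[sel] * structure_factor(stiff)$q0
  du2 <- 3 * (8^2 - 2^2)
  ratio <- (pt_s$S_peak[sel] + 1) / (pt_t$S_peak[sel] + 1)
  expect_equal(log(ratio), -q^2 * du2 / 3, tolerance = 0.5)
})

test_that("peak positions are unchanged when only the NP size varies", {
  ## different d changes b, but positions in q/q0 are the same
  p40 <- sq_peak_table(structure_factor(perturbed_ideal_lattice(
    2, amplitude = 1, seed = 2, b = default_lattice_constant(40))))
  p120 <- sq_peak_table(structure_factor(perturbed_ideal_lattice(
    2, amplitude = 1, seed = 2, b = default_lattice_constant(120))))
  expect_equal(p40$q_rel_theory, p120$q_rel_theory)
})
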