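## Harmonic-surrogate trajectory generators: Gaussian lattice vibrations
## with known spring constants and species-dependent rotational
## stiffness, so every analysis stage can be validated against closed
## forms without molecular dynamics.

#' Specification of a harmonic surrogate
#'
#' Two sampling models are available: `"modes"` draws the normal modes
#' of the coupled harmonic lattice (spring constants `kr`, `ktheta`)
#' with equipartition variances kB T / omega^2, giving displacement
#' covariances kB T D(q)^-1; `"oscillator"` treats every body as an
#' independent oscillator with per-species translational stiffness
#' `ktrans` (and, through [sample_rigid_body_rotations()], rotational
#' stiffness `krot`). Frames are i.i.d. by default (the equal-time
#' estimators need no time correlation); `mode_time = "ou"` adds
#' Ornstein-Uhlenbeck memory for testing plateau detection.
#'
#' @param n Lattice replications per axis.
#' @param b Lattice constant; defaults to the d = 40 rest geometry.
#' @param kr,ktheta Spring constants of the coupled model.
#' @param ktrans Named `c(np=, cage=)` translational stiffnesses
#'   (oscillator model).
#' @param krot Named `c(np=, cage=)` rotational stiffnesses; see also
#'   `arc_s` which overrides them via the shared-arc-length constraint
#'   `<phi^2> = (2 s / d)^2` (so krot = 3 kB T / (2 s / d)^2).
#' @param arc_s Shared arc length s (sigma), or `NULL`.
#' @param d_np,d_cage Body diameters entering the arc constraint.
#' @param T Temperature.
#' @param masses Named body masses.
#' @param n_frames Frames to draw.
#' @param seed Integer seed; every draw derives from it.
#' @param model `"modes"` or `"oscillator"`.
#' @param mode_time `"iid"` or `"ou"`.
#' @param dt Frame spacing in reduced time (used by the OU memory and
#'   the time axis).
#' @return List of class `harmonic_surrogate_spec`.
#' @export
harmonic_surrogate_spec <- function(n = 4L, b = default_lattice_constant(40),
                                    kr = 1, ktheta = 0.1,
                                    ktrans = c(np = 1, cage = 1),
                                    krot = c(np = 1, cage = 1),
                                    arc_s = NULL, d_np = 40, d_cage = 40,
                                    T = 0.09, masses = body_masses(),
                                    n_frames = 1000L, seed = 1L,
                                    model = c("modes", "oscillator"),
                                    mode_time = c("iid", "ou"), dt = 10) {
  model <- match.arg(model)
  mode_time <- match.arg(mode_time)
  stopifnot(kr > 0, ktheta >= 0, all(ktrans > 0), all(krot > 0), T > 0)
  if (!is.null(arc_s)) {
    phi2 <- c(np = (2 * arc_s / d_np)^2, cage = (2 * arc_s / d_cage)^2)
    krot <- 3 * T / phi2
  }
  structure(list(n = as.integer(n), b = b, kr = kr, ktheta = ktheta,
                 ktrans = ktrans, krot = krot, arc_s = arc_s,
                 d_np = d_np, d_cage = d_cage, T = T, masses = masses,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 model = model, mode_time = mode_time, dt = dt),
            class = "harmonic_surrogate_spec")
}

## Fractional q-grid of an n^3 supercell with conjugate pairing.
.surrogate_qset <- function(n) {
  f1 <- (0:(n - 1)) / n
  fr <- as.matrix(expand.grid(f1, f1, f1))
  key <- apply(round(fr %% 1, 9), 1, paste, collapse = ",")
  negkey <- apply(round((-fr) %% 1, 9), 1, paste, collapse = ",")
  partner <- match(negkey, key)
  list(frac = fr, partner = partner, self = partner == seq_len(nrow(fr)))
}

#' Sample correlated lattice-vibration trajectories
#'
#' Draws normal-mode amplitudes of the coupled harmonic model as
#' independent Gaussians with variance kB T / omega^2 and back-transforms
#' to real-space body displacements about the ideal lattice. Zero modes
#' (the acoustic branch at the zone center) carry no amplitude, so the
#' center of mass is fixed.
#'
#' @param spec A [harmonic_surrogate_spec()] with `model = "modes"`.
#' @param model Optional precomputed [cd_harmonic_model()] (rebuilt from
#'   the spec otherwise).
#' @return A [cd_trajectory()] with the lattice map attached.
#' @export
sample_correlated_modes <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "harmonic_surrogate_spec"))
  set.seed(spec$seed)
  if (is.null(model))
    model <- cd_harmonic_model(spec$b, spec$masses)
  lat <- cd_lattice_sites(spec$n, spec$b)
  a <- fcc_primitive_vectors(spec$b)
  G <- 2 * pi * t(solve(a))
  qs <- .surrogate_qset(spec$n)
  nq <- nrow(qs$frac)
  ncells <- spec$n^3
  nf <- spec$n_frames

  ## eigen-decompositions; enforce e(-q) = conj(e(q))
  eigs <- vector("list", nq)
  maxev <- 0
  for (iq in seq_len(nq)) {
    if (!is.null(eigs[[iq]])) next
    q <- as.numeric(qs$frac[iq, ] %*% G)
    D <- model_dynamical_matrix(model, q, spec$kr, spec$ktheta)
    e <- eigen(D, symmetric = TRUE)
    eigs[[iq]] <- e
    maxev <- max(maxev, e$values)
    p <- qs$partner[iq]
    if (p != iq && is.null(eigs[[p]]))
      eigs[[p]] <- list(values = e$values, vectors = Conj(e$vectors))
  }
  tol <- 1e-9 * maxev
  for (iq in seq_len(nq))
    if (any(eigs[[iq]]$values < -1e-6 * maxev))
      stop("negative eigenvalue in the harmonic model at q index ", iq)

  ## draw amplitudes: W_hat[iq][[6 x nf]] complex, conjugate-symmetric
  What <- vector("list", nq)
  done <- rep(FALSE, nq)
  for (iq in seq_len(nq)) {
    if (done[iq]) next
    e <- eigs[[iq]]
    sdv <- ifelse(e$values > tol, sqrt(spec$T / pmax(e$values, tol)), 0)
    if (qs$self[iq]) {
      Q <- matrix(stats::rnorm(6 * nf), 6, nf) * sdv
    } else {
      Q <- (matrix(stats::rnorm(6 * nf), 6, nf) +
              1i * matrix(stats::rnorm(6 * nf), 6, nf)) * (sdv / sqrt(2))
    }
    if (spec$mode_time == "ou") {
      rho <- exp(-spec$dt * sqrt(pmax(e$values, tol)))
      for (f in 2:nf)
        Q[, f] <- rho * Q[, f - 1] + sqrt(1 - rho^2) * Q[, f]
    }
    What[[iq]] <- e$vectors %*% Q
    done[iq] <- TRUE
    p <- qs$partner[iq]
    if (p != iq) { What[[p]] <- Conj(What[[iq]]); done[p] <- TRUE }
  }

  ## back-transform: w_R = (1/sqrt(ncells)) sum_q What(q) e^{+i q.R}
  Rcell <- lat$cell %*% a                       # per body
  bodies_np <- which(lat$basis == 1L)
  bodies_cage <- which(lat$basis == 2L)
  cellR <- Rcell[bodies_np, , drop = FALSE]     # one row per cell
  Qv <- qs$frac %*% G
  phase <- exp(1i * (cellR %*% t(Qv)))          # ncells x nq
  ## stack What into (nq x 6) x nf, then contract over q per component
  coords <- array(0, c(nf, nrow(lat$centers), 3))
  for (mu in 1:2) {
    m <- if (mu == 1) spec$masses[["np"]] else spec$masses[["cage"]]
    sel <- if (mu == 1) bodies_np else bodies_cage
    for (al in 1:3) {
      comp <- 3 * (mu - 1) + al
      Amp <- t(vapply(What, function(w) w[comp, ], complex(nf)))  # nq x nf
      u <- Re(phase %*% Amp) / sqrt(ncells) / sqrt(m)             # ncells x nf
      coords[, sel, al] <- t(u)
    }
  }
  for (al in 1:3)
    coords[, , al] <- sweep(coords[, , al], 2, lat$centers[, al], "+")
  cd_trajectory(coords, species = lat$species, box = lat$box,
                lattice = list(cell = lat$cell, basis = lat$basis,
                               b = spec$b, n = spec$n),
                time = (seq_len(nf) - 1) * spec$dt)
}

#' Sample independent-oscillator translations
#'
#' Each body fluctuates about its lattice site as an isotropic harmonic
#' oscillator with species stiffness `ktrans`: displacement components
#' are N(0, kB T / k), so `<u^2> = 3 kB T / k`.
#'
#' @param spec A [harmonic_surrogate_spec()].
#' @return A [cd_trajectory()].
#' @export
sample_independent_oscillators <- function(spec) {
  stopifnot(inherits(spec, "harmonic_surrogate_spec"))
  set.seed(spec$seed + 1L)
  lat <- cd_lattice_sites(spec$n, spec$b)
  nb <- nrow(lat$centers)
  nf <- spec$n_frames
  sdv <- sqrt(spec$T / ifelse(lat$species == "np",
                              spec$ktrans[["np"]], spec$ktrans[["cage"]]))
  coords <- array(0, c(nf, nb, 3))
  if (spec$mode_time == "ou") {
    rho <- exp(-spec$dt * sqrt(ifelse(lat$species == "np",
                                      spec$ktrans[["np"]],
                                      spec$ktrans[["cage"]]) /
                                 ifelse(lat$species == "np",
                                        spec$masses[["np"]],
                                        spec$masses[["cage"]])))
  }
  for (al in 1:3) {
    U <- matrix(stats::rnorm(nf * nb), nf, nb)
    U <- sweep(U, 2, sdv, "*")
    if (spec$mode_time == "ou")
      for (f in 2:nf)
        U[f, ] <- rho * U[f - 1, ] + sqrt(1 - rho^2) * U[f, ]
    coords[, , al] <- sweep(U, 2, lat$centers[, al], "+")
  }
  cd_trajectory(coords, species = lat$species, box = lat$box,
                lattice = list(cell = lat$cell, basis = lat$basis,
                               b = spec$b, n = spec$n),
                time = (seq_len(nf) - 1) * spec$dt)
}

#' Sample rigid-body orientation fluctuations
#'
#' Each body's vertex frame performs small random rotations drawn from
#' an isotropic Gaussian over rotation vectors with per-component
#' variance kB T / krot, so the full rotation-vector variance is
#' `<phi^2> = 3 kB T / krot`. With the arc-length constraint active the
#' spec sets krot so that `<phi^2> = (2 s / d)^2` per species.
#'
#' @param spec A [harmonic_surrogate_spec()].
#' @param n_track Tracked vertex directions per body (the four
#'   tetrahedral directions are used in this order).
#' @return A [cd_trajectory()] whose `vertices` field holds unit vectors
#'   `[frame, body, vertex, 3]`.
#' @export
sample_rigid_body_rotations <- function(spec, n_track = 1L) {
  stopifnot(inherits(spec, "harmonic_surrogate_spec"))
  set.seed(spec$seed + 2L)
  lat <- cd_lattice_sites(spec$n, spec$b)
  nb <- nrow(lat$centers)
  nf <- spec$n_frames
  dirs <- tetrahedron_directions(1L)
  refs <- dirs[seq_len(n_track), , drop = FALSE]
  sd_phi <- sqrt(spec$T / ifelse(lat$species == "np",
                                 spec$krot[["np"]], spec$krot[["cage"]]))
  verts <- array(0, c(nf, nb, n_track, 3))
  if (spec$mode_time == "ou") rho <- exp(-spec$dt * 0.05) else rho <- 0
  phi_prev <- matrix(0, nb, 3)
  for (f in seq_len(nf)) {
    phi <- matrix(stats::rnorm(3 * nb), nb, 3) * sd_phi
    if (spec$mode_time == "ou" && f > 1)
      phi <- rho * phi_prev + sqrt(1 - rho^2) * phi
    phi_prev <- phi
    for (bdy in seq_len(nb)) {
      Rm <- rotation_from_vector(phi[bdy, ])
      verts[f, bdy, , ] <- refs %*% t(Rm)
    }
  }
  coords <- array(rep(t(lat$centers), each = nf), c(nf, nb, 3))
  cd_trajectory(coords, species = lat$species, box = lat$box,
                lattice = list(cell = lat$cell, basis = lat$basis,
                               b = spec$b, n = spec$n),
                time = (seq_len(nf) - 1) * spec$dt, vertices = verts)
}

#' Ideal lattice frame with i.i.d. Gaussian displacements
#'
#' Fixture generator for structure-factor and bond-counting tests: with
#' `amplitude = 0` the frame is the exact cubic-diamond lattice, whose
#' Bragg peaks sit only at the allowed reflections.
#'
#' @param n Replications per axis.
#' @param amplitude Standard deviation of each displacement component.
#' @param seed Integer seed.
#' @param b Lattice constant.
#' @param n_frames Number of independent frames.
#' @return A [cd_trajectory()].
#' @export
perturbed_ideal_lattice <- function(n = 4L, amplitude = 0, seed = 1L,
                                    b = default_lattice_constant(40),
                                    n_frames = 1L) {
  set.seed(seed)
  lat <- cd_lattice_sites(n, b)
  nb <- nrow(lat$centers)
  coords <- array(0, c(n_frames, nb, 3))
  for (f in seq_len(n_frames)) {
    disp <- if (amplitude > 0)
      matrix(stats::rnorm(3 * nb, sd = amplitude), nb, 3)
    else matrix(0, nb, 3)
    coords[f, , ] <- lat$centers + disp
  }
  cd_trajectory(coords, species = lat$species, box = lat$box,
                lattice = list(cell = lat$cell, basis = lat$basis,
                               b = b, n = n))
}
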