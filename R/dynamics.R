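## Fluctuation dynamical matrix from trajectories, dispersion points
## along the symmetry directions, spring-constant fitting, and the
## harmonic free energy by Brillouin-zone integration.

#' Commensurate dispersion points along (100) and (111)
#'
#' For an n-fold supercell the commensurate wavevectors along the two
#' symmetry directions give `n` points each (including the origin); the
#' reduced wavevector is defined as qbar = q b / (2 pi).
#'
#' @param n Supercell replications.
#' @param b Lattice constant.
#' @return data.frame with `direction`, `j`, `qbar`, `qx`, `qy`, `qz`.
#' @export
dispersion_fit_points <- function(n = 4L, b = default_lattice_constant(40)) {
  j <- 0:(n - 1)
  p100 <- data.frame(direction = "100", j = j, qbar = 2 * j / n,
                     qx = 2 * pi / b * 2 * j / n, qy = 0, qz = 0)
  x <- j / n
  p111 <- data.frame(direction = "111", j = j, qbar = sqrt(3) * x,
                     qx = 2 * pi / b * x, qy = 2 * pi / b * x,
                     qz = 2 * pi / b * x)
  rbind(p100, p111)
}

#' Dynamical matrix estimated from displacement fluctuations
#'
#' Computes the equal-time covariance of the mass-weighted lattice
#' Fourier transform of the body displacements (deviations from their
#' mean positions), and inverts it: D(q) = kB T C(q)^-1. Null directions
#' (the acoustic modes at q = 0) are handled by pseudo-inversion and
#' reported as zero frequencies.
#'
#' @param traj A [cd_trajectory()] carrying a lattice map.
#' @param q Wavevector (length 3).
#' @param T Temperature (reduced units).
#' @param masses Named body masses.
#' @param null_tol Relative eigenvalue cutoff of the pseudo-inverse.
#' @return List with `D` (6x6 Hermitian), `C`, `omega` (6, sorted),
#'   `omega2`, `n_frames`.
#' @export
estimate_dynamical_matrix <- function(traj, q, T,
                                      masses = body_masses(),
                                      null_tol = 1e-8) {
  lat <- traj$lattice
  if (is.null(lat) || is.null(lat$cell))
    stop("trajectory carries no lattice map")
  nf <- n_frames(traj)
  if (nf < 10) stop("too few frames (", nf, "); supply >= 500 frames ",
                    "for a usable covariance")
  a <- fcc_primitive_vectors(lat$b)
  Rcell <- lat$cell %*% a
  phase <- exp(-1i * as.numeric(Rcell %*% q))
  ncells <- nrow(lat$cell) / 2
  W <- matrix(0i, nf, 6)
  for (mu in 1:2) {
    sel <- which(lat$basis == mu)
    m <- if (mu == 1) masses[["np"]] else masses[["cage"]]
    for (al in 1:3) {
      U <- traj$coords[, sel, al, drop = TRUE]
      if (is.null(dim(U))) U <- matrix(U, nf, length(sel))
      U <- sweep(U, 2, colMeans(U), "-")
      W[, 3 * (mu - 1) + al] <-
        (U %*% phase[sel]) * sqrt(m) / sqrt(ncells)
    }
  }
  C <- (t(W) %*% Conj(W)) / nf
  C <- (C + Conj(t(C))) / 2
  ec <- eigen(C, symmetric = TRUE)
  lam <- ec$values
  keep <- lam > null_tol * max(lam)
  if (!any(keep)) stop("singular covariance: increase the frame count")
  inv_lam <- ifelse(keep, 1 / lam, 0)
  D <- ec$vectors %*% diag(T * inv_lam) %*% Conj(t(ec$vectors))
  D <- (D + Conj(t(D))) / 2
  omega2 <- sort(ifelse(keep, T / lam, 0))
  list(D = D, C = C, omega = sqrt(pmax(omega2, 0)), omega2 = omega2,
       n_frames = nf, n_null = sum(!keep))
}

## Reduce 6 branch frequencies to the fitted pair (TA = mean of the two
## degenerate lowest branches, LA = third branch).
.reduce_branches <- function(omega) {
  w <- sort(omega)
  c(TA = mean(w[1:2]), LA = w[3])
}

#' Dispersion relation from a trajectory
#'
#' Estimates the dynamical matrix at every commensurate wavevector along
#' (100) and (111) and reports the two lowest distinct branches (the two
#' lowest branches are degenerate along both directions and are merged).
#'
#' @inheritParams estimate_dynamical_matrix
#' @return data.frame of class `cd_dispersion` with columns `direction`,
#'   `j`, `qbar`, `branch`, `omega` (and the wavevector components).
#' @export
dispersion_from_trajectory <- function(traj, T, masses = body_masses()) {
  lat <- traj$lattice
  pts <- dispersion_fit_points(lat$n, lat$b)
  out <- lapply(seq_len(nrow(pts)), function(i) {
    est <- estimate_dynamical_matrix(
      traj, c(pts$qx[i], pts$qy[i], pts$qz[i]), T, masses)
    br <- .reduce_branches(est$omega)
    data.frame(direction = pts$direction[i], j = pts$j[i],
               qbar = pts$qbar[i], branch = names(br), omega = unname(br),
               qx = pts$qx[i], qy = pts$qy[i], qz = pts$qz[i])
  })
  res <- do.call(rbind, out)
  class(res) <- c("cd_dispersion", class(res))
  res
}

#' Deduplicated fit points of a dispersion table
#'
#' Removes the shared-origin duplicates: all branches at the origin have
#' zero frequency, and the origin is common to the two directions, so
#' for a 4-fold lattice 16 raw points reduce to 13 unique ones.
#'
#' @param disp A dispersion table from [dispersion_from_trajectory()] or
#'   [model_dispersion()].
#' @return The deduplicated table.
#' @export
unique_fit_points <- function(disp) {
  origin <- disp$j == 0
  keep_origin <- which(origin)[1]
  disp[c(keep_origin, which(!origin)), ]
}

#' Dispersion of the harmonic model at the fit points
#'
#' @param model A [cd_harmonic_model()].
#' @param kr,ktheta Spring constants.
#' @param n Supercell replications (sets the commensurate points).
#' @return Same layout as [dispersion_from_trajectory()].
#' @export
model_dispersion <- function(model, kr, ktheta, n = 4L) {
  pts <- dispersion_fit_points(n, model$b)
  out <- lapply(seq_len(nrow(pts)), function(i) {
    w <- model_frequencies(model, c(pts$qx[i], pts$qy[i], pts$qz[i]),
                           kr, ktheta)
    br <- .reduce_branches(w)
    data.frame(direction = pts$direction[i], j = pts$j[i],
               qbar = pts$qbar[i], branch = names(br), omega = unname(br),
               qx = pts$qx[i], qy = pts$qy[i], qz = pts$qz[i])
  })
  res <- do.call(rbind, out)
  class(res) <- c("cd_dispersion", class(res))
  res
}

#' Fit the radial and angular spring constants to a dispersion
#'
#' Nonlinear least squares of the measured branch frequencies against
#' the harmonic model's eigenvalues at the same wavevectors, using the
#' unique fit points (13 for a 4-fold lattice).
#'
#' @param disp Measured dispersion table.
#' @param model A [cd_harmonic_model()].
#' @param init Initial `c(kr, ktheta)`.
#' @return List with `kr`, `ktheta`, `residual_rms`, `points` (with a
#'   `fitted` column), and the `optim` convergence code.
#' @export
fit_spring_constants <- function(disp, model, init = c(1, 0.1)) {
  pts <- unique_fit_points(disp)
  qs <- unique(pts[, c("qx", "qy", "qz")])
  predict_all <- function(kr, ktheta) {
    pred <- apply(qs, 1, function(q)
      .reduce_branches(model_frequencies(model, as.numeric(q), kr, ktheta)))
    key <- paste(round(qs$qx, 10), round(qs$qy, 10), round(qs$qz, 10))
    pkey <- paste(round(pts$qx, 10), round(pts$qy, 10), round(pts$qz, 10))
    vapply(seq_len(nrow(pts)), function(i)
      pred[pts$branch[i], match(pkey[i], key)], numeric(1))
  }
  obj <- function(lp) {
    p <- exp(lp)
    sum((pts$omega - predict_all(p[1], p[2]))^2)
  }
  opt <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  p <- exp(opt$par)
  pts$fitted <- predict_all(p[1], p[2])
  list(kr = p[1], ktheta = p[2],
       residual_rms = sqrt(opt$value / nrow(pts)),
       points = pts, convergence = opt$convergence)
}

#' Harmonic free energy per primitive cell
#'
#' Classical normal-mode free energy, integrated over a uniform shifted
#' grid in the Brillouin zone (the shift excludes the acoustic zeros at
#' the origin, which carry zero measure): F = kB T sum_lambda
#' < ln omega_lambda(q) > + C, with the temperature- and hbar-dependent
#' constant C identical for all parameter sets and therefore dropped --
#' only differences of the returned values are meaningful.
#'
#' @param model A [cd_harmonic_model()].
#' @param kr,ktheta Spring constants.
#' @param T Temperature.
#' @param grid Grid points per reciprocal axis.
#' @return List of class `cd_free_energy` with `F_rel` (kB T units, per
#'   primitive cell, additive constant dropped), `kr`, `ktheta`, `T`,
#'   `grid`.
#' @export
harmonic_free_energy <- function(model, kr, ktheta, T = 0.09, grid = 16L) {
  a <- fcc_primitive_vectors(model$b)
  G <- 2 * pi * t(solve(a))
  f1 <- (seq_len(grid) - 0.5) / grid
  fr <- as.matrix(expand.grid(f1, f1, f1))
  qs <- fr %*% G
  tot <- 0
  for (i in seq_len(nrow(qs))) {
    w <- model_frequencies(model, qs[i, ], kr, ktheta)
    if (any(w <= 0))
      stop("unstable mode (omega <= 0) off the zone center: the model ",
           "is not positive definite for kr=", kr, ", ktheta=", ktheta)
    tot <- tot + sum(log(w))
  }
  structure(list(F_rel = T * tot / nrow(qs), kr = kr, ktheta = ktheta,
                 T = T, grid = grid),
            class = "cd_free_energy")
}

#' Free-energy difference between two parameter sets
#'
#' @param fe,fe_ref `cd_free_energy` results at the same temperature and
#'   grid.
#' @return Numeric: F - F_ref in kB T... (energy units of the reduced
#'   system) per primitive cell.
#' @export
delta_free_energy <- function(fe, fe_ref) {
  stopifnot(fe$T == fe_ref$T, fe$grid == fe_ref$grid)
  fe$F_rel - fe_ref$F_rel
}
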