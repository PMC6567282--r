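## Harmonic lattice model on the ideal cubic-diamond lattice: radial
## springs kr on the four nearest-neighbour links and angular springs
## ktheta on the bond-angle triplets at each body,
##   V = kr/2 sum (|r_ij| - r0)^2 + r0 ktheta / 2 sum (theta - theta0)^2.
## Force constants are extracted once per geometry by differentiating the
## two quadratic forms separately (the Hessian is linear in kr and
## ktheta), then assembled into the mass-weighted dynamical matrix D(q)
## whose eigenvalues are the squared branch frequencies.

## Energy and analytic gradient of the model on a periodic supercell of
## n^3 primitive cells, given body displacements u (rows: bodies).
.hm_energy_grad <- function(u, geom, kr, ktheta) {
  pos <- geom$centers + u
  E <- 0
  G <- matrix(0, nrow(pos), 3)
  ## bonds
  d <- pos[geom$bond_j, ] - pos[geom$bond_i, ] + geom$bond_shift
  dn <- sqrt(rowSums(d^2))
  if (kr != 0) {
    E <- E + kr / 2 * sum((dn - geom$r0)^2)
    f <- kr * (dn - geom$r0) / dn
    gv <- d * f
    for (a in 1:3) {
      G[, a] <- G[, a] + tapply_add(gv[, a], geom$bond_j, nrow(pos)) -
        tapply_add(gv[, a], geom$bond_i, nrow(pos))
    }
  }
  if (ktheta != 0) {
    ## angles at body i between bonds to j and k
    uv <- pos[geom$ang_j, ] - pos[geom$ang_i, ] + geom$ang_shift_j
    vv <- pos[geom$ang_k, ] - pos[geom$ang_i, ] + geom$ang_shift_k
    un <- sqrt(rowSums(uv^2)); vn <- sqrt(rowSums(vv^2))
    uh <- uv / un; vh <- vv / vn
    cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(uh * vh)))
    th <- acos(cth)
    sth <- sqrt(1 - cth^2)
    pref <- geom$r0 * ktheta
    E <- E + pref / 2 * sum((th - geom$theta0)^2)
    dVdth <- pref * (th - geom$theta0)
    dthdu <- (uh * cth - vh) / (un * sth)
    dthdv <- (vh * cth - uh) / (vn * sth)
    gu <- dthdu * dVdth
    gv2 <- dthdv * dVdth
    for (a in 1:3) {
      G[, a] <- G[, a] + tapply_add(gu[, a], geom$ang_j, nrow(pos)) +
        tapply_add(gv2[, a], geom$ang_k, nrow(pos)) -
        tapply_add(gu[, a] + gv2[, a], geom$ang_i, nrow(pos))
    }
  }
  list(E = E, G = G)
}

tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

## Ideal-lattice geometry and bonded topology on an n^3 supercell with
## periodic minimum-image shifts resolved once (ideal coordinates).
.hm_geometry <- function(b, n = 4L) {
  lat <- cd_lattice_sites(n, b)
  ctr <- lat$centers
  nb_cage <- cd_bond_vectors(b)
  r0 <- sqrt(3) * b / 4
  cages <- which(lat$species == "cage")
  nps <- which(lat$species == "np")
  box <- lat$box
  ## bonds: cage -> 4 NP neighbours; bond_shift is defined so that the
  ## true neighbour position is pos[j] + shift (periodic image resolved
  ## on the ideal coordinates once)
  bi <- c(); bj <- c(); bshift <- NULL
  for (ci in cages) {
    for (m in 1:4) {
      tgt <- ctr[ci, ] + nb_cage[m, ]
      dr <- sweep(ctr[nps, , drop = FALSE], 2, tgt, "-")
      f <- round(dr %*% solve(box))
      drw <- dr - f %*% box
      hit <- which(rowSums(drw^2) < 1e-12)
      stopifnot(length(hit) == 1)
      bi <- c(bi, ci); bj <- c(bj, nps[hit])
      bshift <- rbind(bshift, tgt - ctr[nps[hit], ])
    }
  }
  ## angles: at every body, between each pair of its 4 bonds
  ai <- c(); aj <- c(); ak <- c(); ash_j <- NULL; ash_k <- NULL
  bond_list <- split(seq_along(bi), bi)          # bonds at each cage
  add_angles <- function(center, partners, shifts) {
    cmb <- utils::combn(length(partners), 2)
    for (t in seq_len(ncol(cmb))) {
      ai <<- c(ai, center)
      aj <<- c(aj, partners[cmb[1, t]]); ak <<- c(ak, partners[cmb[2, t]])
      ash_j <<- rbind(ash_j, shifts[cmb[1, t], ])
      ash_k <<- rbind(ash_k, shifts[cmb[2, t], ])
    }
  }
  for (ci in cages) {
    ix <- bond_list[[as.character(ci)]]
    add_angles(ci, bj[ix], bshift[ix, , drop = FALSE])
  }
  ## NP-centred angles: invert the bond list
  for (ni in nps) {
    ix <- which(bj == ni)
    ## partner (cage) position relative to NP: pos_cage - shift... the
    ## bond as seen from the NP: cage at pos[i] = pos[j] + shift - d
    add_angles(ni, bi[ix], -bshift[ix, , drop = FALSE])
  }
  theta0 <- acos(-1 / 3)
  list(centers = ctr, species = lat$species, box = box, n = n, b = b,
       r0 = r0, bond_i = bi, bond_j = bj, bond_shift = bshift,
       ang_i = ai, ang_j = aj, ang_k = ak, ang_shift_j = ash_j,
       ang_shift_k = ash_k, theta0 = theta0,
       cell = lat$cell, basis = lat$basis)
}

## Force-constant blocks Phi[(basis0, alpha), (cell, basis, beta)] by
## central differences of the analytic gradient; returns a 6 x (6 n^3)
## matrix per quadratic form, with the acoustic sum rule enforced.
.hm_force_constants <- function(geom, which = c("r", "theta"), h = 1e-5) {
  which <- match.arg(which)
  kr <- if (which == "r") 1 else 0
  kt <- if (which == "theta") 1 else 0
  nb <- nrow(geom$centers)
  ## the two basis bodies of cell (0,0,0)
  i_np <- which(geom$basis == 1L & rowSums(abs(geom$cell)) == 0)
  i_cage <- which(geom$basis == 2L & rowSums(abs(geom$cell)) == 0)
  rows <- c(i_np, i_cage)
  Phi <- matrix(0, 6, 3 * nb)
  for (r in 1:2) {
    for (a in 1:3) {
      up <- matrix(0, nb, 3); up[rows[r], a] <- h
      gp <- .hm_energy_grad(up, geom, kr, kt)$G
      gm <- .hm_energy_grad(-up, geom, kr, kt)$G
      Phi[3 * (r - 1) + a, ] <- as.numeric(t((gp - gm) / (2 * h)))
    }
  }
  ## acoustic sum rule: uniform translation costs nothing
  for (rr in 1:6) {
    a <- (rr - 1) %% 3 + 1
    sel <- seq(a, 3 * nb, by = 3)
    self <- 3 * (rows[(rr - 1) %/% 3 + 1] - 1) + a
    Phi[rr, self] <- Phi[rr, self] - sum(Phi[rr, sel])
  }
  Phi
}

#' Harmonic cubic-diamond lattice model
#'
#' Precomputes the force-constant blocks of the radial and angular
#' quadratic forms on the ideal lattice, from which the dynamical matrix
#' at any wavevector is assembled as `kr * Dr(q) + ktheta * Dtheta(q)`.
#'
#' @param b Lattice constant in sigma.
#' @param masses Named vector `c(np=, cage=)` of total body masses;
#'   defaults to the site counts of the full bead model.
#' @param n Supercell used to house the force constants (4 is ample: the
#'   interactions reach second neighbours only).
#' @return Object of class `cd_harmonic_model`.
#' @export
cd_harmonic_model <- function(b = default_lattice_constant(40),
                              masses = body_masses(), n = 4L) {
  geom <- .hm_geometry(b, n)
  Phi_r <- .hm_force_constants(geom, "r")
  Phi_t <- .hm_force_constants(geom, "theta")
  ## column metadata: cell lattice vector per column, wrapped to the
  ## minimum image so D(q) is exact at every wavevector (the force
  ## constants reach only nearest cells)
  a <- fcc_primitive_vectors(b)
  cell_mi <- ((geom$cell + n %/% 2) %% n) - n %/% 2
  Rcell <- cell_mi %*% a                   # one row per body
  col_body <- rep(seq_len(nrow(geom$centers)), each = 3)
  structure(list(b = b, n = n, r0 = geom$r0, masses = masses,
                 Phi_r = Phi_r, Phi_t = Phi_t,
                 Rcell = Rcell, basis = geom$basis, col_body = col_body,
                 geom = geom),
            class = "cd_harmonic_model")
}

#' Dynamical matrix of the harmonic model at a wavevector
#'
#' Mass-weighted lattice Fourier transform of the force constants; its
#' eigenvalues are the squared vibrational frequencies (Hermitian, 6x6
#' for the two-body basis).
#'
#' @param model A [cd_harmonic_model()].
#' @param q Wavevector (length-3, units 1/sigma).
#' @param kr,ktheta Spring constants.
#' @return Complex 6 x 6 Hermitian matrix.
#' @export
model_dynamical_matrix <- function(model, q, kr, ktheta) {
  Phi <- kr * model$Phi_r + ktheta * model$Phi_t
  phase <- exp(1i * as.numeric(model$Rcell %*% q))   # per body
  ## projector: column (body, beta) -> column (basis, beta) with phase
  ncol3 <- ncol(Phi)
  P <- matrix(0i, ncol3, 6)
  beta <- (seq_len(ncol3) - 1) %% 3 + 1
  col6 <- 3 * (model$basis[model$col_body] - 1) + beta
  P[cbind(seq_len(ncol3), col6)] <- phase[model$col_body]
  D <- Phi %*% P
  mrow <- rep(c(model$masses[["np"]], model$masses[["cage"]]), each = 3)
  D <- D / sqrt(outer(mrow, mrow))
  (D + Conj(t(D))) / 2
}

#' Branch frequencies of the harmonic model
#'
#' @param model A [cd_harmonic_model()].
#' @param q Wavevector.
#' @inheritParams model_dynamical_matrix
#' @return Sorted vector of 6 frequencies (sqrt of eigenvalues; small
#'   negatives from round-off are clipped to 0).
#' @export
model_frequencies <- function(model, q, kr, ktheta) {
  D <- model_dynamical_matrix(model, q, kr, ktheta)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(sort(ev), 0))
}
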