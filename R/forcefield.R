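## Force-field evaluation and reduced-scale molecular dynamics on
## cd_topology systems. Energies are in reduced units (eps = kB = 1),
## the timestep in sigma sqrt(m / eps).

#' Default complementary-base pair well depth
#'
#' Depth of the 12-6 attraction between complementary nucleobases of
#' distinct strands, calibrated with the package's two-strand melting
#' scan so the 8-mer sticky end is hybridized at T = 0.09 and melted at
#' T = 0.30.
#'
#' @return Numeric scalar (reduced energy units).
#' @export
default_base_pair_epsilon <- function() 0.55

.base_codes <- c(A = 1L, T = 2L, C = 3L, G = 4L)

#' Rest length of the shifted FENE bond
#'
#' Minimum of the FENE-plus-truncated-LJ bond potential; for the
#' standard parameters (kb = 30, R0 = 1.5, eps = 1, Delta = 0) it sits
#' at ~0.9609, printed as 0.96 in the parameter tables.
#'
#' @param kb,R0,eps FENE parameters.
#' @param Delta Shift of the equilibrium length.
#' @return The separation minimising the bond potential.
#' @export
fene_rest_length <- function(kb = 30, R0 = 1.5, eps = 1, Delta = 0) {
  V <- function(r) {
    s <- r - Delta
    v <- -0.5 * kb * R0^2 * log(1 - (s / R0)^2)
    if (s < 2^(1 / 6)) v <- v + 4 * eps * (s^-12 - s^-6) + eps
    v
  }
  stats::optimize(V, c(Delta + 0.5, Delta + 0.99 * R0),
                  tol = 1e-12)$minimum
}

## Convert a cd_topology into the flat arrays the C++ core expects.
md_system_arrays <- function(top, eps_bp = default_base_pair_epsilon(),
                             skin = 0.3, tethers = NULL) {
  s <- top$sites
  box <- top$box
  if (is.null(box)) {
    ext <- max(apply(s[, c("x", "y", "z")], 2,
                     function(v) diff(range(v)))) + 200
    box <- diag(3) * ext
  }
  bc <- .base_codes[s$base]
  bc[is.na(bc)] <- 0L
  strand_gid <- ifelse(is.na(s$strand), 0L, s$body * 100L + s$strand)
  lst <- list(
    x = as.matrix(s[, c("x", "y", "z")]),
    mass = s$mass,
    pair_diameter = s$pair_diameter,
    basecode = as.integer(bc),
    strand_gid = as.integer(strand_gid),
    box = box,
    periodic = top$periodic,
    bond_i = as.integer(top$bonds$i - 1L),
    bond_j = as.integer(top$bonds$j - 1L),
    bond_kb = top$bonds$kb, bond_R0 = top$bonds$R0,
    bond_eps = top$bonds$eps, bond_Delta = top$bonds$Delta,
    ang_i = as.integer(top$angles$i - 1L),
    ang_j = as.integer(top$angles$j - 1L),
    ang_k = as.integer(top$angles$k - 1L),
    ang_ka = top$angles$ka,
    eps_bp = eps_bp, sig_bp = 2^(-1 / 6), rc_bp = 2.5,
    skin = skin)
  ## the cage central site provides excluded volume for strands only:
  ## its own rigid frame (edge/truncation beads) sits inside the 40-sigma
  ## exclusion zone by construction and is excluded pairwise
  cage_bodies <- top$bodies$body[top$bodies$kind == "cage"]
  if (length(cage_bodies)) {
    ctr <- s$id[s$species == "cage_center"]
    names(ctr) <- s$body[s$species == "cage_center"]
    edge <- s[s$species == "cage_edge", c("id", "body")]
    if (nrow(edge)) {
      lst$excl_i <- as.integer(unname(ctr[as.character(edge$body)]) - 1L)
      lst$excl_j <- as.integer(edge$id - 1L)
    }
  }
  if (!is.null(tethers)) {
    lst$tether_i <- as.integer(tethers$i - 1L)
    lst$tether_pos <- as.matrix(tethers[, c("x", "y", "z")])
    lst$tether_k <- tethers$k
  }
  lst
}

#' Potential energy and forces of a system
#'
#' Evaluates the full potential (shifted FENE bonds, cosine angle
#' bending, expanded WCA repulsion, complementary-base attraction) and
#' its analytic forces.
#'
#' @param top A `cd_topology`.
#' @param eps_bp Base-pair well depth.
#' @return List with `energy` (named terms and `total`), `forces`
#'   (n x 3), and `virial`.
#' @export
potential_energy <- function(top, eps_bp = default_base_pair_epsilon()) {
  out <- md_energy_forces(md_system_arrays(top, eps_bp))
  if (isTRUE(out$overstretch))
    stop("FENE bond ", out$bad_bond, " overstretched (length outside ",
         "(Delta, Delta + R0))")
  list(energy = out$energy, forces = out$forces, virial = out$virial)
}

.run_md <- function(top, mode, T, n_steps, dt, damp_t, damp_p, seed,
                    stride, thermo_stride, eps_bp, tethers, v0) {
  arr <- md_system_arrays(top, eps_bp, tethers = tethers)
  out <- md_run(arr, as.integer(n_steps), dt, T, mode, damp_t, damp_p,
                as.integer(seed), as.integer(stride),
                as.integer(thermo_stride), v0)
  top2 <- set_site_positions(top, out$x)
  top2$box <- out$box
  ## refresh body centers from the central sites (when present)
  ctr <- top2$sites[top2$sites$species %in% c("cage_center", "np_center"), ]
  ctr <- ctr[order(ctr$body), ]
  if (nrow(ctr) == nrow(top2$bodies))
    top2$bodies[, c("cx", "cy", "cz")] <- as.matrix(ctr[, c("x", "y", "z")])
  structure(list(system = top2, frames = out$frames,
                 thermo = out$thermo, velocities = out$v,
                 forces = out$forces, energy = out$energy,
                 aborted = out$aborted, abort_step = out$abort_step,
                 mode = mode, T = T, dt = dt, seed = seed),
            class = "cd_md_result")
}

#' @export
print.cd_md_result <- function(x, ...) {
  cat("cd_md_result:", x$mode, "run,", length(x$frames), "stored frames",
      if (x$aborted) paste("(ABORTED at step", x$abort_step, ")") else "",
      "\n")
  if (nrow(x$thermo))
    cat("final T =", signif(utils::tail(x$thermo$T, 1), 4),
        " E_pot =", signif(utils::tail(x$thermo$E_pot, 1), 6), "\n")
  invisible(x)
}

#' Run constant-temperature molecular dynamics
#'
#' @param top A `cd_topology`.
#' @param T Temperature (reduced; the lattice default is 0.09).
#' @param n_steps Number of timesteps.
#' @param dt Timestep (default 0.003).
#' @param thermostat `"langevin"` (default: robust for small systems) or
#'   `"nose_hoover"` (damping 1.0, as used for the lattice runs).
#' @param damp_t Thermostat damping time.
#' @param seed Integer seed (drives the deterministic internal RNG).
#' @param stride Store coordinates every `stride` steps (0 = none).
#' @param thermo_stride Record thermodynamics every this many steps.
#' @param eps_bp Base-pair well depth.
#' @param tethers Optional data.frame `i`, `x`, `y`, `z`, `k` of
#'   harmonic site tethers.
#' @param v0 Optional initial velocities (n x 3) for exact restarts.
#' @return A `cd_md_result` (updated system, frames, thermo series).
#' @export
run_nvt <- function(top, T = 0.09, n_steps = 1000L, dt = 0.003,
                    thermostat = c("langevin", "nose_hoover"),
                    damp_t = 1.0, seed = 1L, stride = 0L,
                    thermo_stride = 100L,
                    eps_bp = default_base_pair_epsilon(),
                    tethers = NULL, v0 = NULL) {
  thermostat <- match.arg(thermostat)
  mode <- if (thermostat == "langevin") "nvt_langevin" else "nvt_nh"
  .run_md(top, mode, T, n_steps, dt, damp_t, 3.0, seed, stride,
          thermo_stride, eps_bp, tethers, v0)
}

#' Run zero-pressure constant-temperature dynamics
#'
#' Nose-Hoover thermostat (damping 1.0) with an isotropic cell
#' relaxation toward zero virial pressure (damping 3.0); the triclinic
#' cell shape (angles) is preserved, only the scale changes.
#'
#' @inheritParams run_nvt
#' @param damp_p Barostat damping time.
#' @return A `cd_md_result`.
#' @export
run_npt_zero_pressure <- function(top, T = 0.09, n_steps = 1000L,
                                  dt = 0.003, damp_t = 1.0, damp_p = 3.0,
                                  seed = 1L, stride = 0L,
                                  thermo_stride = 100L,
                                  eps_bp = default_base_pair_epsilon(),
                                  v0 = NULL) {
  .run_md(top, "npt", T, n_steps, dt, damp_t, damp_p, seed, stride,
          thermo_stride, eps_bp, NULL, v0)
}

#' Relax a system by energy minimisation
#'
#' Adaptive steepest descent on the full potential (the T = 0 limit:
#' the energy is non-increasing along the path).
#'
#' @inheritParams run_nvt
#' @return A `cd_md_result`.
#' @export
run_minimize <- function(top, n_steps = 500L,
                         eps_bp = default_base_pair_epsilon()) {
  .run_md(top, "min", 0, n_steps, 0.003, 1.0, 3.0, 1L, 0L, 0L,
          eps_bp, NULL, NULL)
}

#' Run constant-energy dynamics (thermostat off)
#'
#' @inheritParams run_nvt
#' @return A `cd_md_result`.
#' @export
run_nve <- function(top, T = 0.09, n_steps = 1000L, dt = 0.003,
                    seed = 1L, stride = 0L, thermo_stride = 10L,
                    eps_bp = default_base_pair_epsilon(), v0 = NULL) {
  .run_md(top, "nve", T, n_steps, dt, 1.0, 3.0, seed, stride,
          thermo_stride, eps_bp, NULL, v0)
}

#' Count hybridized cage-NP links in a configuration
#'
#' A cage-NP link is counted when at least `nmin` of the 8 sticky base
#' pairs of a strand pair are simultaneously within `rhyb`. Links
#' between ideal lattice neighbours are "lattice bonds"; links between
#' non-neighbour bodies are "reorientation bonds" (surface bodies
#' rotating to reach unused interior strands). The criterion is a
#' diagnostic only; it never enters the dynamics.
#'
#' @param top A `cd_topology` system (current coordinates).
#' @param nmin Minimum simultaneous close base pairs (default 4).
#' @param rhyb Distance criterion in sigma (default 1.5).
#' @return List with `links` (data.frame cage body, np body, n_close,
#'   lattice flag), `per_cage` (bond counts), `n_lattice`,
#'   `n_reorientation`.
#' @export
count_hybridized_pairs <- function(top, nmin = 4L, rhyb = 1.5) {
  s <- top$sites
  bases <- s[s$species == "dna_base" & !is.na(s$base) & s$base != "N", ]
  kinds <- top$bodies$kind[match(bases$body, top$bodies$body)]
  cb <- bases[kinds == "cage", ]
  nb <- bases[kinds == "np", ]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  links <- list()
  if (nrow(cb) && nrow(nb)) {
    nb_pos <- as.matrix(nb[, c("x", "y", "z")])
    for (key in unique(paste(cb$body, cb$strand))) {
      sel <- cb[paste(cb$body, cb$strand) == key, ]
      pos <- as.matrix(sel[, c("x", "y", "z")])
      hits <- integer(0)
      for (r in seq_len(nrow(sel))) {
        dr <- sweep(nb_pos, 2, pos[r, ], "-")
        if (!is.null(top$box)) dr <- minimum_image(dr, top$box, top$periodic)
        ok <- which(rowSums(dr^2) < rhyb^2 &
                      nb$base == comp[[sel$base[r]]])
        hits <- c(hits, ok)
      }
      if (!length(hits)) next
      tab <- table(paste(nb$body[hits], nb$strand[hits]))
      for (pk in names(tab)) {
        if (tab[[pk]] >= nmin) {
          pk2 <- as.integer(strsplit(pk, " ")[[1]])
          links[[length(links) + 1]] <-
            data.frame(cage = sel$body[1], cage_strand = sel$strand[1],
                       np = pk2[1], np_strand = pk2[2],
                       n_close = as.integer(tab[[pk]]))
        }
      }
    }
  }
  links <- if (length(links)) unique(do.call(rbind, links)) else
    data.frame(cage = integer(), cage_strand = integer(), np = integer(),
               np_strand = integer(), n_close = integer())
  nbmap <- ideal_neighbor_map(top)
  links$lattice <- vapply(seq_len(nrow(links)), function(i)
    links$np[i] %in% nbmap[as.character(links$cage[i]), ], logical(1))
  cages <- top$bodies$body[top$bodies$kind == "cage"]
  per_cage <- vapply(cages, function(cg) sum(links$cage == cg), numeric(1))
  list(links = links, per_cage = setNames(per_cage, cages),
       n_lattice = sum(links$lattice),
       n_reorientation = sum(!links$lattice))
}

#' Prepare a fully bonded lattice by the two-step protocol
#'
#' Step 1: a single primitive cell with the NP and cage centers tethered
#' to their ideal sites by stiff harmonic springs is annealed in the NVT
#' ensemble at `T` until all four cage strands are hybridized (retrying
#' with a new seed up to `retries` times). Step 2: the bonded cell is
#' replicated (unwrapped) to `n^3` cells, the tethers are removed, and
#' the lattice is relaxed at zero pressure.
#'
#' @param n Final replications per axis.
#' @param d,ka NP diameter and DNA stiffness.
#' @param T Temperature (default 0.09, below the strand melting point).
#' @param steps1,steps2 Timesteps of the two stages.
#' @param k_tether Tether spring constant.
#' @param seed Integer seed.
#' @param retries Re-anneal attempts before failing.
#' @param eps_bp Base-pair well depth.
#' @return List with the final `system`, the two `cd_md_result` stages,
#'   and the final hybridization table.
#' @export
prepare_bonded_lattice <- function(n = 2L, d = 40, ka = 1, T = 0.09,
                                   steps1 = 20000L, steps2 = 5000L,
                                   k_tether = 50, seed = 1L, retries = 2L,
                                   eps_bp = default_base_pair_epsilon()) {
  cell <- build_bulk_lattice(1L, d = d, ka = ka)
  cell <- run_minimize(cell, n_steps = 300L, eps_bp = eps_bp)$system
  ctr_ids <- cell$sites$id[cell$sites$species %in%
                             c("cage_center", "np_center")]
  teth <- data.frame(i = ctr_ids,
                     x = cell$sites$x[ctr_ids], y = cell$sites$y[ctr_ids],
                     z = cell$sites$z[ctr_ids], k = k_tether)
  stage1 <- NULL
  for (try in 0:retries) {
    res <- run_nvt(cell, T = T, n_steps = steps1, seed = seed + try,
                   tethers = teth, eps_bp = eps_bp, thermo_stride = 1000L)
    hyb <- count_hybridized_pairs(res$system)
    if (all(hyb$per_cage == 4)) { stage1 <- res; break }
  }
  if (is.null(stage1))
    stop("hybridization not achieved within the step budget after ",
         retries + 1, " attempts")

  ## replicate the bonded cell (unwrapped coordinates)
  relaxed <- stage1$system
  a <- fcc_primitive_vectors(relaxed$meta$b)
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  tops <- lapply(seq_len(nrow(idx)), function(i)
    transform_topology(relaxed, shift = as.numeric(idx[i, ] %*% a)))
  lat <- cd_lattice_sites(n, relaxed$meta$b)
  sys <- merge_topologies(tops, box = lat$box,
                          periodic = c(TRUE, TRUE, TRUE),
                          meta = utils::modifyList(relaxed$meta,
                                                   list(n = n, lattice = lat)))
  ## body bookkeeping: cells in build order, basis from kind
  sys$bodies$basis <- ifelse(sys$bodies$kind == "np", 1L, 2L)
  cellrep <- idx[rep(seq_len(nrow(idx)), each = 2), ]
  sys$bodies$cell1 <- cellrep[, 1]; sys$bodies$cell2 <- cellrep[, 2]
  sys$bodies$cell3 <- cellrep[, 3]

  stage2 <- run_npt_zero_pressure(sys, T = T, n_steps = steps2,
                                  seed = seed + 100L, eps_bp = eps_bp,
                                  thermo_stride = 500L)
  hyb2 <- count_hybridized_pairs(stage2$system)
  list(system = stage2$system, stage1 = stage1, stage2 = stage2,
       hybridization = hyb2)
}
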