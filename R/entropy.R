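## Translational and rotational mean-squared displacements, their
## plateaus <u^2> and <phi^2>, and the independent-oscillator entropy
## decomposition of the relative lattice free energy.

## Log-log slope (and its standard error) of the trailing part of a
## curve.
.tail_slope <- function(t, y) {
  ok <- t > 0 & y > 0
  t <- t[ok]; y <- y[ok]
  if (length(t) < 4) return(c(NA_real_, NA_real_))
  half <- t >= stats::median(t)
  fit <- stats::lm(log(y[half]) ~ log(t[half]))
  summary(fit)$coefficients[2, 1:2]
}

## Plateau of a saturating curve: mean over the trailing window where
## the log-log slope has fallen below `slope_tol` (or is statistically
## indistinguishable from zero).
.plateau <- function(t, y, slope_tol = 0.05) {
  ss <- .tail_slope(t, y)
  sl <- ss[1]
  flat <- !is.na(sl) && (abs(sl) <= slope_tol ||
                           (!is.na(ss[2]) && abs(sl) <= 3 * ss[2]))
  if (!flat) {
    warning("no plateau detected (log-log tail slope ", signif(sl, 2),
            "): the bodies may be diffusing")
    return(list(value = NA_real_, slope = sl, window = NULL))
  }
  win <- t >= stats::median(t[t > 0])
  list(value = mean(y[win]), slope = sl, window = range(t[win]))
}

#' Translational mean-squared displacement and vibration plateau
#'
#' Computes both the site-referenced amplitude `<u^2>` (variance of the
#' body centers about their mean lattice positions: the quantity entering
#' the oscillator entropy, since the oscillator energy is referenced to
#' the site) and the multi-origin time-lag curve `<r^2(t)>`, whose
#' saturation value is `2 <u^2>` for uncorrelated frames.
#'
#' @param traj A [cd_trajectory()].
#' @param species `"np"`, `"cage"`, or `"both"` (pooled).
#' @param max_origins Time origins used for the lag curve.
#' @param slope_tol Plateau detector threshold on the log-log slope.
#' @return List of class `cd_msd`: `curve` (data.frame `t`, `msd`),
#'   `u2` (site-referenced), `plateau_lag`, `species`.
#' @export
msd_translational <- function(traj, species = "both", max_origins = 200L,
                              slope_tol = 0.05) {
  sel <- if (species == "both") seq_along(traj$species)
         else which(traj$species == species)
  nf <- n_frames(traj)
  X <- traj$coords[, sel, , drop = FALSE]
  mu <- apply(X, c(2, 3), mean)
  u2 <- mean(vapply(seq_along(sel), function(b)
    mean((sweep(X[, b, , drop = TRUE], 2, mu[b, ]))^2) * 3, numeric(1)))

  lags <- unique(round(c(0, exp(seq(0, log(nf - 1), length.out = 40)))))
  origins <- unique(round(seq(1, nf, length.out = min(max_origins, nf))))
  msd <- vapply(lags, function(lg) {
    o <- origins[origins + lg <= nf]
    if (!length(o)) return(NA_real_)
    d <- X[o + lg, , , drop = FALSE] - X[o, , , drop = FALSE]
    mean(apply(d^2, 1, sum) / length(sel))
  }, numeric(1))
  curve <- data.frame(t = traj$time[lags + 1] - traj$time[1], msd = msd)
  pl <- .plateau(curve$t, curve$msd, slope_tol)
  structure(list(curve = curve, u2 = u2, plateau_lag = pl$value,
                 tail_slope = pl$slope, species = species),
            class = "cd_msd")
}

#' Rotational mean-squared displacement and orientation plateau
#'
#' theta(t) is the angle between a body's center-to-vertex vector at
#' times t0 and t0 + t, averaged over tracked vertices and origins. The
#' reported `<phi^2>` is the full rotation-vector variance: for small
#' isotropic rotations the single-vertex lag plateau equals
#' (4/3) `<phi^2>` (a vertex is blind to rotations about its own axis,
#' and the lag compares two independent orientations), and the
#' site-referenced angle variance equals (2/3) `<phi^2>`.
#'
#' @inheritParams msd_translational
#' @return List of class `cd_msd`: `curve` (`t`, `theta2`), `phi2`,
#'   `plateau_lag`, `species`.
#' @export
msd_rotational <- function(traj, species = "both", max_origins = 200L,
                           slope_tol = 0.05) {
  if (is.null(traj$vertices))
    stop("trajectory carries no vertex orientations")
  sel <- if (species == "both") seq_along(traj$species)
         else which(traj$species == species)
  V <- traj$vertices
  if (length(dim(V)) == 3) V <- array(V, c(dim(V)[1], dim(V)[2], 1, 3))
  V <- V[, sel, , , drop = FALSE]
  nf <- dim(V)[1]; nb <- dim(V)[2]; nk <- dim(V)[3]

  lags <- unique(round(c(0, exp(seq(0, log(nf - 1), length.out = 40)))))
  origins <- unique(round(seq(1, nf, length.out = min(max_origins, nf))))
  th2 <- vapply(lags, function(lg) {
    o <- origins[origins + lg <= nf]
    if (!length(o)) return(NA_real_)
    dots <- V[o + lg, , , , drop = FALSE] * V[o, , , , drop = FALSE]
    cth <- pmin(1, pmax(-1, apply(dots, c(1, 2, 3), sum)))
    mean(acos(cth)^2)
  }, numeric(1))
  curve <- data.frame(t = traj$time[lags + 1] - traj$time[1], theta2 = th2)
  pl <- .plateau(curve$t, curve$theta2, slope_tol)

  ## site-referenced variance about the mean orientation
  vbar <- apply(V, c(2, 3, 4), mean)
  nrm <- sqrt(apply(vbar^2, c(1, 2), sum))
  th_ref <- 0
  for (b in seq_len(nb)) for (k in seq_len(nk)) {
    vb <- vbar[b, k, ] / nrm[b, k]
    cth <- pmin(1, pmax(-1, V[, b, k, ] %*% vb))
    th_ref <- th_ref + mean(acos(cth)^2)
  }
  th_ref <- th_ref / (nb * nk)
  structure(list(curve = curve, phi2 = 1.5 * th_ref,
                 plateau_lag = pl$value, tail_slope = pl$slope,
                 species = species),
            class = "cd_msd")
}

#' Entropy decomposition relative to a reference system
#'
#' Independent-oscillator relative entropies: the translational part is
#' (3/2) kB [ln(<u2>/<u2_ref>)_NP + ln(<u2>/<u2_ref>)_cage] and the
#' rotational part the same expression in `<phi^2>`. Energies, when
#' supplied, enter as dF = dE - T dS.
#'
#' @param tab data.frame with one row per system and columns `d`, `ka`,
#'   `u2_np`, `u2_cage`, `phi2_np`, `phi2_cage`, optionally `E` (mean
#'   potential energy per primitive cell).
#' @param T Temperature.
#' @param reference Row index of the reference system, or `NULL` to use
#'   the smallest (d, ka).
#' @return data.frame of class `cd_entropy_report` with dS_trans, dS_rot
#'   (total and per species), -T dS columns, dE and dF, plus the
#'   per-stiffness re-referenced view in `attr(, "per_stiffness")`.
#' @export
entropy_decomposition <- function(tab, T = 0.09, reference = NULL,
                                  .per_stiffness = TRUE) {
  need <- c("d", "ka", "u2_np", "u2_cage", "phi2_np", "phi2_cage")
  stopifnot(all(need %in% names(tab)))
  if (any(tab[need[-(1:2)]] <= 0, na.rm = TRUE))
    stop("all plateaus must be positive")
  if (is.null(reference))
    reference <- order(tab$d, tab$ka)[1]
  ref <- tab[reference, ]
  decomp <- function(x, xref) 1.5 * log(x / xref)
  out <- data.frame(
    d = tab$d, ka = tab$ka,
    dS_trans = decomp(tab$u2_np, ref$u2_np) +
      decomp(tab$u2_cage, ref$u2_cage),
    dS_rot_np = decomp(tab$phi2_np, ref$phi2_np),
    dS_rot_cage = decomp(tab$phi2_cage, ref$phi2_cage))
  out$dS_rot <- out$dS_rot_np + out$dS_rot_cage
  out$mTdS_trans <- -T * out$dS_trans
  out$mTdS_rot <- -T * out$dS_rot
  out$dE <- if ("E" %in% names(tab)) tab$E - ref$E else 0
  out$dF <- out$dE - T * (out$dS_trans + out$dS_rot)

  ## per-stiffness view: each ka re-referenced to its smallest-d system
  if (.per_stiffness) {
    per_ka <- do.call(rbind, lapply(split(seq_len(nrow(tab)), tab$ka),
      function(ix)
        entropy_decomposition(tab[ix, , drop = FALSE], T = T,
                              reference = which.min(tab$d[ix]),
                              .per_stiffness = FALSE)))
    rownames(per_ka) <- NULL
    attr(out, "per_stiffness") <- per_ka
  }
  class(out) <- c("cd_entropy_report", class(out))
  out
}

#' Energetic component of the relative free energy
#'
#' Difference of mean total potential energies per primitive cell.
#'
#' @param e,e_ref Energy time series (total potential energies).
#' @param n_cells,n_cells_ref Primitive-cell counts of the two systems.
#' @return dE per primitive cell.
#' @export
energy_component <- function(e, e_ref, n_cells, n_cells_ref = n_cells) {
  mean(e) / n_cells - mean(e_ref) / n_cells_ref
}
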