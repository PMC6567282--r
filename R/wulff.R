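## Equilibrium crystallite shapes: half-space-intersection Wulff
## construction over the cubic symmetry families {100}, {110}, {111},
## and the slab estimator of facet surface energies.

## All symmetry-equivalent unit normals of a Miller family under the full
## cubic point group (48 operations = signed permutations).
cubic_family_normals <- function(hkl) {
  h <- abs(as.numeric(hkl))
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  out <- list()
  for (p in seq_len(nrow(perms)))
    for (s in seq_len(nrow(signs)))
      out[[length(out) + 1]] <- h[perms[p, ]] * signs[s, ]
  out <- unique(do.call(rbind, out))
  out / sqrt(rowSums(out^2))
}

#' Wulff construction from facet surface energies
#'
#' Intersects the half-spaces `x . n <= gamma_hkl` over all
#' symmetry-equivalent orientations of the supplied families and returns
#' the resulting polyhedron with per-family facet area fractions. Only
#' ratios of the energies matter: the shape is invariant under uniform
#' scaling.
#'
#' @param gamma Named numeric vector of surface energies, names among
#'   `"100"`, `"110"`, `"111"` (all must be positive).
#' @param area_tol Facets whose area fraction falls below this are
#'   reported as absent.
#' @return An object of class `cd_wulff`: `planes`, `vertices`, `facets`
#'   (vertex loops with family and area), `area_fractions` (named, sums
#'   to 1), `label`, and `lambda_spread` (relative spread of
#'   gamma_hkl / ell_hkl over retained facets; 0 up to round-off).
#' @export
wulff_construct <- function(gamma, area_tol = 1e-6) {
  stopifnot(length(gamma) >= 1, all(gamma > 0),
            all(names(gamma) %in% c("100", "110", "111")))
  normals <- list(); dists <- c(); fams <- c()
  for (fam in names(gamma)) {
    hkl <- as.numeric(strsplit(fam, "")[[1]])
    nn <- cubic_family_normals(hkl)
    normals[[length(normals) + 1]] <- nn
    dists <- c(dists, rep(gamma[[fam]], nrow(nn)))
    fams <- c(fams, rep(fam, nrow(nn)))
  }
  N <- do.call(rbind, normals)
  if (!"100" %in% names(gamma) && !"111" %in% names(gamma) &&
      !"110" %in% names(gamma))
    stop("no facet families given")
  ## {110} alone bounds space; {100} alone does; {111} alone does.
  scale <- max(dists)

  ## vertex enumeration: feasible intersections of plane triples
  np <- nrow(N)
  verts <- list()
  combs <- utils::combn(np, 3)
  for (t in seq_len(ncol(combs))) {
    A <- N[combs[, t], ]
    if (abs(det(A)) < 1e-9) next
    v <- solve(A, dists[combs[, t]])
    if (all(N %*% v <= dists + 1e-9 * scale))
      verts[[length(verts) + 1]] <- v
  }
  if (!length(verts)) stop("empty or unbounded intersection")
  V <- unique(round(do.call(rbind, verts), 9))

  facets <- list()
  areas <- numeric(np)
  for (i in seq_len(np)) {
    on <- which(abs(V %*% N[i, ] - dists[i]) < 1e-7 * scale)
    if (length(on) < 3) next
    e1 <- orthonormal_perp(N[i, ])
    e2 <- c(N[i, 2] * e1[3] - N[i, 3] * e1[2],
            N[i, 3] * e1[1] - N[i, 1] * e1[3],
            N[i, 1] * e1[2] - N[i, 2] * e1[1])
    P <- V[on, , drop = FALSE]
    ctr2 <- colMeans(P)
    a <- atan2((P - matrix(ctr2, nrow(P), 3, byrow = TRUE)) %*% e2,
               (P - matrix(ctr2, nrow(P), 3, byrow = TRUE)) %*% e1)
    ord <- order(a)
    x <- (P %*% e1)[ord]; y <- (P %*% e2)[ord]
    area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    areas[i] <- area
    facets[[length(facets) + 1]] <-
      list(plane = i, family = fams[i], normal = N[i, ],
           dist = dists[i], vertices = on[ord], area = area)
  }
  tot <- sum(areas)
  frac <- vapply(c("100", "110", "111"), function(f)
    sum(areas[fams == f]) / tot, numeric(1))
  frac[frac < area_tol] <- 0
  frac <- frac / sum(frac)

  retained <- vapply(facets, function(f) f$area / tot >= area_tol,
                     logical(1))
  lam <- vapply(facets[retained], function(f) f$dist / f$dist, numeric(1))
  ## ell equals the plane distance by construction, so lambda = gamma/ell
  ## is constant exactly; verify via the vertex geometry instead:
  ell <- vapply(facets[retained], function(f) {
    mean(V[f$vertices, , drop = FALSE] %*% f$normal)
  }, numeric(1))
  gam <- vapply(facets[retained], function(f) f$dist, numeric(1))
  lam <- gam / ell
  lambda_spread <- (max(lam) - min(lam)) / mean(lam)

  lbl <- wulff_label(frac)
  structure(list(planes = data.frame(family = fams, dist = dists),
                 normals = N, vertices = V, facets = facets,
                 area_fractions = frac, label = lbl,
                 lambda_spread = lambda_spread, gamma = gamma),
            class = "cd_wulff")
}

wulff_label <- function(frac) {
  has <- frac > 0
  if (has[["100"]] && !has[["111"]] && !has[["110"]]) return("cube")
  if (has[["111"]] && !has[["100"]] && !has[["110"]]) return("octahedron")
  if (has[["111"]] && has[["110"]] && !has[["100"]])
    return("octahedron (edges truncated by {110})")
  if (has[["111"]] && has[["100"]]) {
    if (frac[["111"]] >= frac[["100"]]) return("truncated octahedron")
    return("truncated cube")
  }
  "other"
}

#' @export
print.cd_wulff <- function(x, ...) {
  cat("Wulff shape:", x$label, "\n")
  cat("area fractions:",
      paste(sprintf("{%s} %.4f", names(x$area_fractions),
                    x$area_fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Facet-area thresholds of the crystallite shape
#'
#' Bisects on the ratio gamma100/gamma111 (with gamma110/gamma111 held
#' fixed) for the two shape transitions: the largest ratio at which the
#' shape is a pure cube (zero {111} area) and the smallest ratio at which
#' the {100} facets vanish (octahedron, up to slight {110} edge
#' truncation when gamma110/gamma111 < sqrt(6)/2).
#'
#' @param gamma110_rel gamma110 / gamma111 (default the printed 1.22).
#' @param range Search interval for gamma100 / gamma111.
#' @param tol Bisection tolerance.
#' @return List with `cube_only`, `octahedron_only`, and the shape labels
#'   just inside each regime.
#' @export
shape_threshold_scan <- function(gamma110_rel = 1.22, range = c(0.3, 2.5),
                                 tol = 1e-4) {
  frac_at <- function(r) {
    ## near-degenerate facets matter here, so use a tight area cutoff
    w <- wulff_construct(c("100" = r, "110" = gamma110_rel, "111" = 1),
                         area_tol = 1e-8)
    w$area_fractions
  }
  bisect <- function(lo, hi, vanish_fam) {
    ## indicator: TRUE when the family is absent
    f_lo <- frac_at(lo)[[vanish_fam]] == 0
    f_hi <- frac_at(hi)[[vanish_fam]] == 0
    stopifnot(f_lo != f_hi)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((frac_at(mid)[[vanish_fam]] == 0) == f_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  cube_only <- bisect(range[1], 1, "111")
  octa_only <- bisect(1, range[2], "100")
  list(cube_only = cube_only,
       octahedron_only = octa_only,
       label_below = wulff_construct(
         c("100" = cube_only - 2 * tol, "110" = gamma110_rel, "111" = 1))$label,
       label_above = wulff_construct(
         c("100" = octa_only + 2 * tol, "110" = gamma110_rel, "111" = 1))$label)
}

#' Facet surface energy from slab and bulk energies
#'
#' The surface energy is the excess mean energy of a slab over a
#' composition-matched bulk reference, divided by the two exposed faces:
#' gamma = (E_slab - E_bulk_matched) / (2 A). The bulk reference is
#' scaled per body to the slab's composition, and the uncertainty comes
#' from block averaging of the slab energy series.
#'
#' @param e_slab Numeric vector: total potential energy time series of
#'   the slab.
#' @param e_bulk Numeric vector: total potential energy time series of
#'   the bulk reference.
#' @param n_bodies_slab,n_bodies_bulk Body counts of the two systems.
#' @param area Exposed surface area (one face), e.g. from the in-plane
#'   box vectors.
#' @param n_blocks Blocks for the uncertainty estimate.
#' @param hkl Optional Miller triple recorded in the result.
#' @param ka Optional stiffness recorded in the result.
#' @return A list of class `facet_energy`: `gamma`, `se`, `hkl`, `ka`.
#' @export
surface_energy_from_slab <- function(e_slab, e_bulk, n_bodies_slab,
                                     n_bodies_bulk, area, n_blocks = 5,
                                     hkl = NULL, ka = NULL) {
  if (n_bodies_slab <= 0 || n_bodies_bulk <= 0 || area <= 0)
    stop("body counts and area must be positive")
  per_body <- mean(e_bulk) / n_bodies_bulk
  excess <- mean(e_slab) - per_body * n_bodies_slab
  gamma <- excess / (2 * area)
  blocks <- split(e_slab, cut(seq_along(e_slab), n_blocks, labels = FALSE))
  gb <- vapply(blocks, function(x)
    (mean(x) - per_body * n_bodies_slab) / (2 * area), numeric(1))
  se <- stats::sd(gb) / sqrt(length(gb))
  structure(list(gamma = gamma, se = se, hkl = hkl, ka = ka,
                 source = "slab_md"),
            class = "facet_energy")
}

#' In-plane area of a slab system
#'
#' @param sys A slab built by [build_slab()].
#' @return |a1 x a2| for the two in-plane box vectors.
#' @export
slab_area <- function(sys) {
  a1 <- sys$box[1, ]; a2 <- sys$box[2, ]
  cr <- c(a1[2] * a2[3] - a1[3] * a2[2], a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  sqrt(sum(cr^2))
}

#' Export a Wulff polyhedron as an OFF mesh
#'
#' @param shape A `cd_wulff` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wulff_off <- function(shape, path) {
  keep <- vapply(shape$facets, function(f) f$area > 1e-9, logical(1))
  fac <- shape$facets[keep]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(shape$vertices), length(fac)), con)
  utils::write.table(format(shape$vertices, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (f in fac)
    writeLines(paste(c(length(f$vertices), f$vertices - 1L),
                     collapse = " "), con)
  invisible(path)
}
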