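## Readers and writers: extended XYZ, LAMMPS data / dump (orthogonal and
## triclinic with tilt factors), and a YAML system manifest.

## LAMMPS triclinic convention: a1 along x, a2 in the xy plane. Returns
## the rotated box parameters and the rotation applied.
.lammps_cell <- function(box) {
  a1 <- box[1, ]; a2 <- box[2, ]; a3 <- box[3, ]
  lx <- sqrt(sum(a1^2))
  xy <- sum(a2 * a1) / lx
  ly <- sqrt(sum(a2^2) - xy^2)
  xz <- sum(a3 * a1) / lx
  yz <- (sum(a2 * a3) - xy * xz) / ly
  lz <- sqrt(sum(a3^2) - xz^2 - yz^2)
  H <- rbind(c(lx, 0, 0), c(xy, ly, 0), c(xz, yz, lz))
  R <- t(solve(box, H))        # rotation: pos %*% t(R) maps into H frame
  list(lx = lx, ly = ly, lz = lz, xy = xy, xz = xz, yz = yz,
       H = H, R = R)
}

#' Write a system or trajectory as extended XYZ
#'
#' One block per frame with columns: species, body id, x, y, z.
#'
#' @param x A `cd_topology` (site-level) or [cd_trajectory()]
#'   (body-center level).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "cd_topology")) {
    s <- x$sites
    writeLines(as.character(nrow(s)), con)
    writeLines(paste0("frame=0 species body x y z"), con)
    utils::write.table(
      data.frame(s$species, s$body, format(s$x, digits = 10),
                 format(s$y, digits = 10), format(s$z, digits = 10)),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (inherits(x, "cd_trajectory")) {
    nf <- n_frames(x)
    for (f in seq_len(nf)) {
      writeLines(as.character(length(x$species)), con)
      writeLines(sprintf("frame=%d species body x y z", f - 1), con)
      R <- x$coords[f, , , drop = TRUE]
      if (is.null(dim(R))) R <- matrix(R, 1, 3)
      utils::write.table(
        data.frame(x$species, seq_along(x$species),
                   format(R[, 1], digits = 10), format(R[, 2], digits = 10),
                   format(R[, 3], digits = 10)),
        con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  } else stop("unsupported object")
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path File written by [write_xyz()] (or any XYZ whose extra
#'   columns are species and an integer body id).
#' @param box Optional 3 x 3 box to attach.
#' @return A [cd_trajectory()].
#' @export
read_xyz <- function(path, box = NULL) {
  lines <- readLines(path)
  frames <- list(); species <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop("malformed XYZ at line ", i)
    n <- as.integer(lines[i])
    if (i + 1 + n > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    sp <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p)
      as.numeric(p[3:5]), numeric(3)))
    if (is.null(species)) species <- sp
    else if (!identical(species, sp))
      stop("frame/topology mismatch at line ", i)
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  coords <- array(0, c(length(frames), length(species), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  cd_trajectory(coords, species = species, box = box)
}

#' Write a LAMMPS data file
#'
#' Atoms (molecular style: id, mol, type, x, y, z), bonds and angles,
#' with bond/angle types grouped by their parameter rows; triclinic tilt
#' factors are emitted when the box is non-orthogonal. The parameter
#' catalogue is written as comment lines, since the FENE/angle styles
#' carry their coefficients in the input script.
#'
#' @param top A `cd_topology` with a box.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(top, path) {
  stopifnot(!is.null(top$box))
  cell <- .lammps_cell(top$box)
  s <- top$sites
  pos <- as.matrix(s[, c("x", "y", "z")]) %*% t(cell$R)
  type_key <- paste(s$species, s$diameter)
  types <- unique(type_key)
  t_id <- match(type_key, types)
  bk <- paste(top$bonds$kb, top$bonds$R0, top$bonds$eps, top$bonds$Delta)
  btypes <- unique(bk)
  ak <- as.character(top$angles$ka)
  atypes <- unique(ak)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines("LAMMPS data file generated by cdlattice", con)
  writeLines("", con)
  writeLines(sprintf("%d atoms", nrow(s)), con)
  writeLines(sprintf("%d bonds", nrow(top$bonds)), con)
  writeLines(sprintf("%d angles", nrow(top$angles)), con)
  writeLines(sprintf("%d atom types", length(types)), con)
  writeLines(sprintf("%d bond types", length(btypes)), con)
  writeLines(sprintf("%d angle types", length(atypes)), con)
  writeLines("", con)
  writeLines(sprintf("0.0 %.10g xlo xhi", cell$lx), con)
  writeLines(sprintf("0.0 %.10g ylo yhi", cell$ly), con)
  writeLines(sprintf("0.0 %.10g zlo zhi", cell$lz), con)
  if (max(abs(c(cell$xy, cell$xz, cell$yz))) > 1e-10)
    writeLines(sprintf("%.10g %.10g %.10g xy xz yz",
                       cell$xy, cell$xz, cell$yz), con)
  writeLines("", con)
  writeLines("Masses", con)
  writeLines("", con)
  for (t in seq_along(types))
    writeLines(sprintf("%d %.10g  # %s", t,
                       s$mass[match(types[t], type_key)], types[t]), con)
  writeLines("", con)
  for (b in seq_along(btypes))
    writeLines(sprintf("# bond type %d: kb R0 eps Delta = %s",
                       b, btypes[b]), con)
  for (a in seq_along(atypes))
    writeLines(sprintf("# angle type %d: ka = %s", a, atypes[a]), con)
  writeLines("", con)
  writeLines("Atoms", con)
  writeLines("", con)
  writeLines(sprintf("%d %d %d %.10g %.10g %.10g",
                     s$id, s$body, t_id, pos[, 1], pos[, 2], pos[, 3]), con)
  writeLines("", con)
  if (nrow(top$bonds)) {
    writeLines("Bonds", con)
    writeLines("", con)
    writeLines(sprintf("%d %d %d %d", seq_len(nrow(top$bonds)),
                       match(bk, btypes), top$bonds$i, top$bonds$j), con)
    writeLines("", con)
  }
  if (nrow(top$angles)) {
    writeLines("Angles", con)
    writeLines("", con)
    writeLines(sprintf("%d %d %d %d %d", seq_len(nrow(top$angles)),
                       match(ak, atypes), top$angles$i, top$angles$j,
                       top$angles$k), con)
  }
  invisible(path)
}

#' Write a LAMMPS dump trajectory
#'
#' `ITEM:` blocks with id, type, x, y, z; triclinic boxes carry tilt
#' factors in the bounds block.
#'
#' @param traj A [cd_trajectory()] with a box.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path) {
  stopifnot(!is.null(traj$box))
  cell <- .lammps_cell(traj$box)
  tri <- max(abs(c(cell$xy, cell$xz, cell$yz))) > 1e-10
  con <- file(path, "w")
  on.exit(close(con))
  type <- ifelse(traj$species == "np", 1L, 2L)
  for (f in seq_len(n_frames(traj))) {
    R <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(R))) R <- matrix(R, 1, 3)
    R <- R %*% t(cell$R)
    writeLines("ITEM: TIMESTEP", con)
    writeLines(as.character(f - 1), con)
    writeLines("ITEM: NUMBER OF ATOMS", con)
    writeLines(as.character(nrow(R)), con)
    if (tri) {
      writeLines("ITEM: BOX BOUNDS xy xz yz pp pp pp", con)
      xlo_b <- 0 + min(0, cell$xy, cell$xz, cell$xy + cell$xz)
      xhi_b <- cell$lx + max(0, cell$xy, cell$xz, cell$xy + cell$xz)
      ylo_b <- min(0, cell$yz); yhi_b <- cell$ly + max(0, cell$yz)
      writeLines(sprintf("%.10g %.10g %.10g", xlo_b, xhi_b, cell$xy), con)
      writeLines(sprintf("%.10g %.10g %.10g", ylo_b, yhi_b, cell$xz), con)
      writeLines(sprintf("%.10g %.10g %.10g", 0, cell$lz, cell$yz), con)
    } else {
      writeLines("ITEM: BOX BOUNDS pp pp pp", con)
      writeLines(sprintf("%.10g %.10g", 0, cell$lx), con)
      writeLines(sprintf("%.10g %.10g", 0, cell$ly), con)
      writeLines(sprintf("%.10g %.10g", 0, cell$lz), con)
    }
    writeLines("ITEM: ATOMS id type x y z", con)
    writeLines(sprintf("%d %d %.10g %.10g %.10g", seq_len(nrow(R)),
                       type, R[, 1], R[, 2], R[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump trajectory
#'
#' Supports orthogonal and triclinic (`xy xz yz`) bounds blocks and the
#' `id type x y z` atom columns (extra columns are ignored). Atoms are
#' re-ordered by id.
#'
#' @param path Dump file.
#' @return A [cd_trajectory()]; species are `"np"` for type 1 and
#'   `"cage"` for type 2, other types keep `"site<k>"`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  i <- 1; frames <- list(); box <- NULL; species <- NULL
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP"))
      stop("malformed dump at line ", i)
    n <- as.integer(lines[i + 3])
    bline <- lines[i + 4]
    tri <- grepl("xy xz yz", bline)
    nb <- if (tri) 3 else 2
    bb <- do.call(rbind, lapply(lines[(i + 5):(i + 7)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    hdr <- strsplit(sub("ITEM: ATOMS ", "", lines[i + 8]), "\\s+")[[1]]
    if (i + 8 + n > length(lines))
      stop("truncated dump frame starting at line ", i)
    block <- lines[(i + 9):(i + 8 + n)]
    M <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"),
                               as.numeric))
    colnames(M) <- hdr[seq_len(ncol(M))]
    M <- M[order(M[, "id"]), , drop = FALSE]
    if (is.null(species)) {
      tp <- as.integer(M[, "type"])
      species <- ifelse(tp == 1L, "np", ifelse(tp == 2L, "cage",
                                               paste0("site", tp)))
    }
    frames[[length(frames) + 1]] <- M[, c("x", "y", "z"), drop = FALSE]
    if (is.null(box)) {
      if (tri) {
        xy <- bb[1, 3]; xz <- bb[2, 3]; yz <- bb[3, 3]
        xlo <- bb[1, 1] - min(0, xy, xz, xy + xz)
        xhi <- bb[1, 2] - max(0, xy, xz, xy + xz)
        ylo <- bb[2, 1] - min(0, yz); yhi <- bb[2, 2] - max(0, yz)
        box <- rbind(c(xhi - xlo, 0, 0), c(xy, yhi - ylo, 0),
                     c(xz, yz, bb[3, 2] - bb[3, 1]))
      } else {
        box <- diag(c(bb[1, 2] - bb[1, 1], bb[2, 2] - bb[2, 1],
                      bb[3, 2] - bb[3, 1]))
      }
    }
    i <- i + 9 + n
  }
  coords <- array(0, c(length(frames), length(species), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  cd_trajectory(coords, species = species, box = box)
}

#' Write a YAML manifest of a system
#'
#' Records the build parameters, body table and box so body/species
#' structure can be reconstructed alongside coordinate files.
#'
#' @param sys A `cd_topology`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sys, path) {
  m <- list(
    package = "cdlattice",
    n_sites = nrow(sys$sites), n_bodies = nrow(sys$bodies),
    box = if (!is.null(sys$box)) as.numeric(t(sys$box)) else NULL,
    periodic = as.logical(sys$periodic),
    bodies = list(kind = sys$bodies$kind),
    meta = sys$meta[setdiff(names(sys$meta), c("lattice", "geometry"))])
  yaml::write_yaml(m, path)
  invisible(path)
}
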