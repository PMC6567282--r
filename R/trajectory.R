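## Body-center trajectory container used by the analysis stages.

#' Construct a body-center trajectory
#'
#' @param coords Array `[n_frames, n_bodies, 3]` of body-center
#'   positions (sigma), or a matrix for a single frame.
#' @param species Character vector `"np"`/`"cage"` per body.
#' @param box 3 x 3 row-vector box matrix (may be `NULL` for open
#'   boundaries).
#' @param lattice Optional cell map: list with `cell` (n_bodies x 3
#'   integers), `basis` (1 = NP, 2 = cage), `b`, `n`.
#' @param time Optional frame times (reduced units).
#' @param vertices Optional array `[n_frames, n_bodies, 3]` of one
#'   tracked vertex direction per body (unit vectors), or
#'   `[n_frames, n_bodies, n_vertices, 3]` for several.
#' @return An object of class `cd_trajectory`.
#' @export
cd_trajectory <- function(coords, species, box = NULL, lattice = NULL,
                          time = NULL, vertices = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == length(species))
  if (is.null(time)) time <- seq_len(dim(coords)[1]) - 1
  structure(list(coords = coords, species = species, box = box,
                 lattice = lattice, time = time, vertices = vertices),
            class = "cd_trajectory")
}

#' @export
print.cd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("cd_trajectory:", d[1], "frames x", d[2], "bodies",
      if (!is.null(x$vertices)) "(with orientations)" else "", "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Trajectory of an ideal lattice (single static frame)
#'
#' @param sys A lattice system with a cell map.
#' @return A one-frame `cd_trajectory` of the body centers.
#' @export
ideal_frame <- function(sys) {
  lat <- sys$meta$lattice
  cd_trajectory(as.matrix(sys$bodies[, c("cx", "cy", "cz")]),
                species = sys$bodies$kind, box = sys$box,
                lattice = list(cell = as.matrix(
                  sys$bodies[, c("cell1", "cell2", "cell3")]),
                  basis = sys$bodies$basis, b = sys$meta$b,
                  n = sys$meta$n))
}
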