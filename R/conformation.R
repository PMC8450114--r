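# 3D conformations: construction of initial states and XYZ import/export.
# Coordinates are in nm; row i of the coordinate matrix is lattice site i-1.

#' Conformation object
#'
#' Holds the 3D coordinates (nm) of every nucleosome, plus optional
#' kinetochore bead coordinates.
#'
#' @param coords numeric matrix (nucleosomes x 3), finite values only.
#' @param kinetochore optional numeric matrix (beads x 3).
#' @param step simulation block index the snapshot belongs to.
#' @return An object of class `conformation`.
#' @export
conformation <- function(coords, kinetochore = NULL, step = NA_integer_) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  if (!is.null(kinetochore)) {
    kinetochore <- as.matrix(kinetochore)
    stopifnot(ncol(kinetochore) == 3, all(is.finite(kinetochore)))
  }
  structure(list(coords = coords, kinetochore = kinetochore, step = step),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d nucleosomes%s (step %s)\n", nrow(x$coords),
              if (is.null(x$kinetochore)) "" else
                sprintf(" + %d kinetochore beads", nrow(x$kinetochore)),
              format(x$step)))
  invisible(x)
}

#' Random-walk initial conformation
#'
#' Places successive nucleosomes at distance `bond_length` in uniformly random
#' directions (a freely jointed chain). Self-crossing is allowed; the
#' soft-core repulsion relaxes overlaps during the 3D run.
#'
#' @param spec a [chromosome_spec()].
#' @param bond_length bond length in nm (default 10, the fibre diameter).
#' @param seed optional RNG seed.
#' @return A [conformation()].
#' @export
random_walk_conformation <- function(spec, bond_length = 10, seed = NULL) {
  stopifnot(bond_length > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_nucleosomes
  # uniform directions on the sphere
  u <- runif(n - 1, -1, 1)
  phi <- runif(n - 1, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  steps <- bond_length * cbind(s * cos(phi), s * sin(phi), u)
  coords <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  conformation(coords, step = 0L)
}

#' Kinetochore-stage initial conformation
#'
#' Builds the aligned starting structure for 3D runs with a kinetochore
#' plate: anchor nucleosomes are placed collinear on the z-axis at uniform
#' spacing and each loop's interior nucleosomes are laid out as a straight
#' out-and-back excursion along +x from its base. Anchors are the centromeric
#' nucleosomes; for a monocentric chromosome the axial nucleosomes outside
#' the centromeric region (taken from `state`) are placed on the z-axis as
#' well. Kinetochore beads sit on a fixed rectangular grid parallel to the
#' centromere line, offset to one side (+y), with length proportional to the
#' number of centromeric nucleosomes.
#'
#' @param spec a [chromosome_spec()].
#' @param state the final [extruder_state()] of the 1D run; supplies the loop
#'   structure (which nucleosomes are loop bases).
#' @param spacing z-spacing of anchor nucleosomes in nm (default 10).
#' @param kinetochore logical; add the kinetochore bead grid.
#' @param grid_rows,grid_spacing,grid_offset kinetochore grid geometry: number
#'   of bead rows across x, bead spacing in nm, and y-offset of the plate from
#'   the centromere line. The default offset (12 nm) puts the plate just
#'   outside the repulsion cutoff of the tethered centromeric line, so the
#'   impassable plate barrier does not overlap the centromeres at start; the
#'   default 5 rows make the plate wider than a single nucleosome, as a
#'   plate-like multiprotein complex.
#' @return A [conformation()] with a `kinetochore` matrix when requested.
#' @export
kinetochore_initial_conformation <- function(spec, state, spacing = 10,
                                             kinetochore = TRUE,
                                             grid_rows = 5L,
                                             grid_spacing = 10,
                                             grid_offset = 12) {
  n <- spec$n_nucleosomes
  cen <- spec$centromere_positions
  if (any(c(state$left, state$right) >= n) || any(state$left < 0)) {
    stop("extruder state is inconsistent with the chromosome spec")
  }
  monocentric <- !is.null(spec$layout) &&
    identical(spec$layout$kind, "monocentric")
  anchors <- cen
  if (monocentric) {
    ax <- axial_nucleosomes(state)
    rs <- spec$layout$region_start
    re <- rs + spec$layout$region_sites
    anchors <- sort(union(cen, ax[ax < rs | ax >= re]))
  }
  if (!length(anchors)) stop("no anchor nucleosomes to align")

  coords <- matrix(0, n, 3)
  zs <- spacing * (seq_along(anchors) - 1)
  coords[anchors + 1L, 3] <- zs

  lay_loop <- function(sites, z0, z1) {
    # straight out-and-back excursion along +x between two z anchors
    m <- length(sites)
    if (!m) return()
    tri <- pmin(seq_len(m), m + 1L - seq_len(m))
    coords[sites + 1L, 1] <<- 5 * tri
    coords[sites + 1L, 3] <<- z0 + (z1 - z0) * seq_len(m) / (m + 1)
  }
  bounds <- c(-1L, anchors, n)
  zb <- c(zs[1], zs, zs[length(zs)])
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    if (hi - lo > 1L) lay_loop((lo + 1L):(hi - 1L), zb[i], zb[i + 1L])
  }

  kin <- NULL
  if (kinetochore) {
    n_cen <- length(cen)
    if (n_cen < 2L) stop("kinetochore grid needs at least 2 centromeric sites")
    # grid spans the centromeric anchor line, proportional to centromere count
    cen_z <- coords[cen + 1L, 3]
    grid_len <- (n_cen - 1L) * spacing
    z0 <- min(cen_z)
    zg <- seq(z0, z0 + grid_len, by = grid_spacing)
    xg <- (seq_len(grid_rows) - (grid_rows + 1) / 2) * grid_spacing
    kin <- as.matrix(expand.grid(x = xg, y = grid_offset, z = zg))
    dimnames(kin) <- NULL
  }
  conformation(coords, kinetochore = kin, step = 0L)
}

#' Write / read conformations in XYZ format
#'
#' One atom record per bead; the element tag distinguishes non-centromeric
#' (`C`), centromeric (`N`) and kinetochore (`K`) beads. Multiple
#' conformations can be appended as successive XYZ frames.
#'
#' @param conf a [conformation()].
#' @param path file path.
#' @param spec optional [chromosome_spec()] used to tag centromeric beads.
#' @param append append as an extra frame.
#' @export
write_xyz <- function(conf, path, spec = NULL, append = FALSE) {
  tags <- rep("C", nrow(conf$coords))
  if (!is.null(spec) && length(spec$centromere_positions)) {
    tags[spec$centromere_positions + 1L] <- "N"
  }
  coords <- conf$coords
  if (!is.null(conf$kinetochore)) {
    tags <- c(tags, rep("K", nrow(conf$kinetochore)))
    coords <- rbind(coords, conf$kinetochore)
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(coords)),
               sprintf("step %s", format(conf$step))), con)
  writeLines(sprintf("%s %.4f %.4f %.4f", tags, coords[, 1], coords[, 2],
                     coords[, 3]), con)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    step <- suppressWarnings(as.integer(sub("^step ", "", lines[i + 1L])))
    rec <- do.call(rbind, strsplit(lines[(i + 2L):(i + 1L + n)], " +"))
    xyz <- matrix(as.numeric(rec[, 2:4]), ncol = 3)
    kin <- rec[, 1] == "K"
    frames[[length(frames) + 1L]] <- conformation(
      xyz[!kin, , drop = FALSE],
      kinetochore = if (any(kin)) xyz[kin, , drop = FALSE] else NULL,
      step = step)
    i <- i + 2L + n
  }
  if (length(frames) == 1L) frames[[1L]] else frames
}
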