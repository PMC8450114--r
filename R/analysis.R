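# Structural analysis of 3D conformations: spacing histograms, axial spacing
# and 3D chromosome length, contact matrices, contact probability curves,
# centromere ordering and groove profiles.

frames_list <- function(frames) {
  if (inherits(frames, "trajectory")) return(frames$frames)
  if (inherits(frames, "conformation")) return(list(frames))
  frames
}

#' Histogram of distances between genomically adjacent centromeres
#'
#' Pools, over the given frames, the 3D distance between centromeric
#' nucleosomes that are adjacent in the linear genome, and bins it.
#'
#' @param frames a `trajectory`, a [conformation()], or a list of
#'   conformations.
#' @param spec a [chromosome_spec()] with at least 2 centromeric sites.
#' @param bin_width histogram bin width in nm (default 0.5).
#' @return List with `distances` (pooled, nm), `mids`, `counts` and the
#'   `breaks` of the histogram.
#' @export
centromere_spacing_histogram <- function(frames, spec, bin_width = 0.5) {
  cen <- spec$centromere_positions
  if (length(cen) < 2L) stop("need at least 2 centromeric sites")
  frames <- frames_list(frames)
  d <- unlist(lapply(frames, function(fr) {
    xyz <- fr$coords[cen + 1L, , drop = FALSE]
    sqrt(rowSums(diff(xyz)^2))
  }))
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  list(distances = d, mids = h$mids, counts = h$counts, breaks = breaks)
}

#' Axial spacing and 3D chromosome length
#'
#' Measures the distances between sequence-consecutive axial nucleosomes over
#' a window of conformations, reports their median and peak (the most
#' populated 0.5 nm histogram bin), and estimates the 3D chromosome length as
#' the number of axial nucleosomes in the final conformation times the median
#' (or peak) distance.
#'
#' @param frames conformations of the last analysis window (>= 1; the
#'   standard protocol uses 10 snapshots over the last 10000 blocks).
#' @param state_final the final [extruder_state()], from which the axial set
#'   is computed.
#' @param bin_width peak-histogram bin width in nm (default 0.5).
#' @return List with `median_distance`, `peak_distance`, `n_axial`,
#'   `chromosome_length_3d` (median-based), `chromosome_length_3d_peak`, and
#'   the pooled `distances`.
#' @export
axial_spacing <- function(frames, state_final, bin_width = 0.5) {
  ax <- axial_nucleosomes(state_final)
  if (!length(ax)) stop("empty axial set")
  frames <- frames_list(frames)
  d <- unlist(lapply(frames, function(fr) {
    xyz <- fr$coords[ax + 1L, , drop = FALSE]
    sqrt(rowSums(diff(xyz)^2))
  }))
  med <- median(d)
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  peak <- h$mids[which.max(h$counts)]
  list(median_distance = med, peak_distance = peak, n_axial = length(ax),
       chromosome_length_3d = length(ax) * med,
       chromosome_length_3d_peak = length(ax) * peak, distances = d)
}

#' Contact matrix over genomic bins
#'
#' Counts, pooled over frames, every nucleosome pair within `radius` nm, and
#' accumulates the counts into symmetric genomic bins. Bins are half-open
#' windows of `bin_bp` base pairs; the analysis region defaults to a
#' `region_bp`-wide window centred on the chromosome.
#'
#' @param frames a `trajectory`, conformation, or list of conformations, all
#'   sharing `spec`.
#' @param spec a [chromosome_spec()].
#' @param region_bp width of the analysed region in bp (default 4e6, clipped
#'   to the chromosome).
#' @param bin_bp bin size in bp (default 4000, i.e. 20 nucleosomes).
#' @param radius contact radius in nm between bead centres (default 200).
#' @param region_start_bp optional region start in bp (0-based; default
#'   centres the region).
#' @return An object of class `contact_map`: `matrix` (raw symmetric counts),
#'   `bin_size`, `region` (site interval), `contact_radius`, `n_frames`.
#' @export
contact_map <- function(frames, spec, region_bp = 4e6, bin_bp = 4000,
                        radius = 200, region_start_bp = NULL) {
  frames <- frames_list(frames)
  bpn <- spec$bp_per_nucleosome
  n <- spec$n_nucleosomes
  region_sites <- min(n, as.integer(region_bp / bpn))
  if (is.null(region_start_bp)) {
    from <- (n - region_sites) %/% 2L
  } else {
    from <- as.integer(region_start_bp / bpn)
  }
  to <- from + region_sites - 1L
  if (from < 0L || to >= n) stop("analysis region outside the chromosome")
  bin_sites <- max(1L, as.integer(bin_bp / bpn))
  M <- cpp_contact_map(lapply(frames, `[[`, "coords"), from, to, bin_sites,
                       radius)
  structure(list(matrix = M, bin_size = bin_bp,
                 region = c(from, to), contact_radius = radius,
                 n_frames = length(frames), spec = spec),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf(
    "<contact_map> %d x %d bins of %g bp, sites %d-%d, %d frame(s)\n",
    nrow(x$matrix), ncol(x$matrix), x$bin_size, x$region[1], x$region[2],
    x$n_frames))
  invisible(x)
}

#' Export a contact map as dense TSV plus cooler-style bin/pixel tables
#'
#' `write_contact_map` writes the dense matrix; `write_contact_tables`
#' writes a `<prefix>.bins.tsv` (chrom, start, end) and `<prefix>.pixels.tsv`
#' (bin1_id, bin2_id, count) pair with upper-triangle pixels.
#'
#' @param cmap a `contact_map`.
#' @param path,prefix output paths.
#' @export
write_contact_map <- function(cmap, path) {
  write.table(cmap$matrix, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
write_contact_tables <- function(cmap, prefix) {
  nb <- nrow(cmap$matrix)
  bpn <- cmap$spec$bp_per_nucleosome
  start_bp <- (cmap$region[1] + (seq_len(nb) - 1L) *
                 (cmap$bin_size %/% bpn)) * bpn
  bins <- data.frame(chrom = "chr1", start = start_bp,
                     end = start_bp + cmap$bin_size)
  ut <- which(upper.tri(cmap$matrix, diag = TRUE) & cmap$matrix > 0,
              arr.ind = TRUE)
  pixels <- data.frame(bin1_id = ut[, 1] - 1L, bin2_id = ut[, 2] - 1L,
                       count = cmap$matrix[ut])
  write.table(bins, paste0(prefix, ".bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pixels, paste0(prefix, ".pixels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Contact probability as a function of genomic separation
#'
#' For log-spaced separation bins between `s_min` and `s_max`, divides the
#' number of observed contacts (pairs within `radius` nm) by the number of
#' all possible nucleosome pairs in the same separation range (exact counts,
#' including chromosome-end effects). Uses a single conformation, as in the
#' standard protocol.
#'
#' @param frame a [conformation()].
#' @param spec a [chromosome_spec()].
#' @param s_min,s_max genomic separation range in bp (defaults 10 kb, 20 Mb).
#' @param radius contact radius in nm.
#' @param bins_per_decade log-bin density.
#' @return data.frame with `s_bp` (geometric bin midpoint), `prob`,
#'   `contacts`, `possible`.
#' @export
contact_probability <- function(frame, spec, s_min = 1e4, s_max = 2e7,
                                radius = 200, bins_per_decade = 8) {
  if (s_min >= s_max) stop("s_min must be smaller than s_max")
  bpn <- spec$bp_per_nucleosome
  n_dec <- log10(s_max / s_min)
  n_bins <- max(1L, ceiling(n_dec * bins_per_decade))
  breaks_bp <- 10^seq(log10(s_min), log10(s_max), length.out = n_bins + 1L)
  res <- cpp_contact_probability(frame$coords, radius, breaks_bp / bpn)
  keep <- res$possible > 0
  data.frame(
    s_bp = sqrt(breaks_bp[-length(breaks_bp)] * breaks_bp[-1])[keep],
    prob = (res$contacts / pmax(res$possible, 1))[keep],
    contacts = res$contacts[keep], possible = res$possible[keep])
}

#' Fraction of genomically ordered consecutive centromere pairs
#'
#' Projects the centromeric nucleosomes onto the principal axis of the
#' conformation and reports the fraction of genomically consecutive pairs
#' whose projections advance monotonically (in either global direction).
#' Values near 1 indicate the line-like holocentromere, where centromere
#' order along the axis follows genome order.
#'
#' @param frame a [conformation()].
#' @param spec a [chromosome_spec()].
#' @param axis optional axis vector; defaults to the first principal
#'   component of the centromeric coordinates.
#' @param window if set, use a locally fitted axis instead of the single
#'   global one: the axis for pair `(i, i+1)` is the first principal
#'   component of the centromeres within `window` genomic neighbours, with
#'   its sign oriented by the global genomic direction. Condensed
#'   chromosomes are curved cylinders, so a straight global axis conflates
#'   bending with loss of order; the local axis follows the centromeric
#'   line. Ignored when `axis` is given.
#' @return Fraction in `[0, 1]`.
#' @export
centromere_order_fraction <- function(frame, spec, axis = NULL,
                                      window = NULL) {
  cen <- spec$centromere_positions
  if (length(cen) < 3L) stop("need at least 3 centromeric sites")
  xyz <- frame$coords[cen + 1L, , drop = FALSE]
  nc <- nrow(xyz)
  if (is.null(axis) && !is.null(window)) {
    ok <- logical(nc - 1L)
    for (i in seq_len(nc - 1L)) {
      lo <- max(1L, i - window)
      hi <- min(nc, i + 1L + window)
      local_axis <- prcomp(xyz[lo:hi, , drop = FALSE],
                           center = TRUE)$rotation[, 1]
      # orient the local axis along increasing genomic order
      if (sum((xyz[hi, ] - xyz[lo, ]) * local_axis) < 0) {
        local_axis <- -local_axis
      }
      ok[i] <- sum((xyz[i + 1L, ] - xyz[i, ]) * local_axis) > 0
    }
    return(mean(ok))
  }
  if (is.null(axis)) {
    axis <- prcomp(xyz, center = TRUE)$rotation[, 1]
  }
  proj <- as.vector(xyz %*% axis)
  steps <- diff(proj)
  max(mean(steps > 0), mean(steps < 0))
}

#' Angular chromatin density around the centromere line (groove profile)
#'
#' Splits the conformation into longitudinal slabs along the centromere axis
#' and, within each slab, bins the chromatin beads by their azimuthal angle
#' around the axis. The kinetochore side defines angle 0. The groove
#' statistic is the chromatin density in the half-cylinder behind the
#' kinetochore plate (|angle| < 90 degrees, beyond the plate offset) divided
#' by the density in the opposite half-cylinder.
#'
#' @param frame a [conformation()] with kinetochore beads.
#' @param spec a [chromosome_spec()].
#' @param n_sectors angular sectors per slab (default 12).
#' @param n_slabs longitudinal slabs (default 10).
#' @param region_filter restrict the profiled chromatin beads to those whose
#'   genomic position lies `"inside"` or `"outside"` the centromeric layout
#'   region (monocentric analyses), or use `"all"` beads (default).
#' @return List with the per-slab, per-sector `density` matrix, the sector
#'   `angles` (radians, kinetochore side at 0), and `depletion_ratio`: the
#'   chromatin bead count in the rectangular shadow box directly behind the
#'   plate (beyond the plate plane, within its footprint, to a depth of the
#'   plate half-width) divided by the count in the mirrored box on the
#'   chromatin side. Values near 0 mean a groove; near 1, no groove.
#' @export
groove_profile <- function(frame, spec, n_sectors = 12, n_slabs = 10,
                           region_filter = c("all", "inside", "outside")) {
  region_filter <- match.arg(region_filter)
  if (is.null(frame$kinetochore)) stop("no kinetochore beads in frame")
  cen <- spec$centromere_positions
  cxyz <- frame$coords[cen + 1L, , drop = FALSE]
  axis <- prcomp(cxyz, center = TRUE)$rotation[, 1]
  centre <- colMeans(cxyz)
  # kinetochore direction, orthogonal to the axis
  kdir <- colMeans(frame$kinetochore) - centre
  kdir <- kdir - sum(kdir * axis) * axis
  kdist <- sqrt(sum(kdir^2))
  kdir <- kdir / kdist
  e2 <- c(axis[2] * kdir[3] - axis[3] * kdir[2],
          axis[3] * kdir[1] - axis[1] * kdir[3],
          axis[1] * kdir[2] - axis[2] * kdir[1])

  beads <- frame$coords
  if (region_filter != "all") {
    if (is.null(spec$layout$region_start)) {
      stop("region filtering requires a monocentric layout")
    }
    idx <- seq(spec$layout$region_start,
               spec$layout$region_start + spec$layout$region_sites - 1L) + 1L
    if (region_filter == "outside") idx <- setdiff(seq_len(nrow(beads)), idx)
    beads <- beads[idx, , drop = FALSE]
  }
  rel <- sweep(beads, 2, centre)
  t_ax <- as.vector(rel %*% axis)
  u <- as.vector(rel %*% kdir)
  v <- as.vector(rel %*% e2)
  ang <- atan2(v, u)

  cen_t <- as.vector(sweep(cxyz, 2, centre) %*% axis)
  in_span <- t_ax >= min(cen_t) & t_ax <= max(cen_t)
  slab <- cut(t_ax[in_span], breaks = n_slabs, labels = FALSE)
  sector <- cut(ang[in_span], breaks = seq(-pi, pi, length.out = n_sectors + 1),
                labels = FALSE, include.lowest = TRUE)
  density <- matrix(0, n_slabs, n_sectors)
  tab <- table(factor(slab, levels = 1:n_slabs),
               factor(sector, levels = 1:n_sectors))
  density[] <- as.numeric(tab)

  # shadow-box statistic: the groove is the chromatin-free furrow directly
  # behind the plate, which chromatin can only reach around the plate edges
  kin_rel <- sweep(frame$kinetochore, 2, centre)
  k_u <- as.vector(kin_rel %*% kdir)      # plate plane offset
  k_v <- as.vector(kin_rel %*% e2)        # plate width axis
  k_t <- as.vector(kin_rel %*% axis)      # plate length axis
  half_w <- max(abs(k_v - mean(k_v))) + 5 # footprint half-width + bead radius
  depth <- max(half_w, 10)
  plate_u <- max(k_u)
  in_foot <- abs(v) <= half_w & t_ax >= min(k_t) - 5 & t_ax <= max(k_t) + 5
  n_kin_side <- sum(in_foot & u > plate_u & u <= plate_u + depth)
  n_opposite <- sum(in_foot & u < -plate_u & u >= -plate_u - depth)
  list(density = density,
       angles = (seq_len(n_sectors) - 0.5) * 2 * pi / n_sectors - pi,
       n_kinetochore_side = n_kin_side, n_opposite = n_opposite,
       depletion_ratio = n_kin_side / max(n_opposite, 1L))
}

#' Corner enrichment of inter-centromere blocks in a contact map
#'
#' The anchoring effect produces square blocks between consecutive
#' centromeric bins whose off-diagonal corners are enriched; blocking
#' produces squares lacking the corners. The statistic is the mean contact
#' count in the 3x3 bins at the two off-diagonal corners of each
#' inter-centromere block divided by the block mean, averaged over blocks.
#'
#' @param cmap a `contact_map`.
#' @param spec a [chromosome_spec()].
#' @return Mean corner-to-block contact ratio across inter-centromere blocks.
#' @export
corner_enrichment <- function(cmap, spec = cmap$spec) {
  bpn <- spec$bp_per_nucleosome
  bin_sites <- cmap$bin_size %/% bpn
  cen <- spec$centromere_positions
  cen <- cen[cen >= cmap$region[1] & cen <= cmap$region[2]]
  bins <- (cen - cmap$region[1]) %/% bin_sites + 1L
  bins <- unique(bins)
  if (length(bins) < 2L) stop("fewer than 2 centromeric bins in the region")
  M <- cmap$matrix
  ratios <- c()
  for (i in seq_len(length(bins) - 1L)) {
    b1 <- bins[i]; b2 <- bins[i + 1L]
    if (b2 - b1 < 4L) next # block too small for a 3x3 corner
    block <- M[b1:b2, b1:b2]
    k <- min(3L, nrow(block))
    corner <- block[seq_len(k), ncol(block) - k + seq_len(k)]
    ratios <- c(ratios, mean(corner) / mean(block))
  }
  if (!length(ratios)) stop("no inter-centromere block wide enough")
  mean(ratios)
}
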