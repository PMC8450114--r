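# Chromosome specifications: the lattice chromosome and centromere layouts.
# Lattice indices are 0-based throughout (they index C++ arrays and genomic
# offsets alike); 3D space is in nm.

#' Create a chromosome specification
#'
#' A chromosome is a chain of `n_nucleosomes` lattice sites, each representing
#' one nucleosome (~200 bp of DNA including linker), with an ordered set of
#' centromeric sites. Centromeric nucleosomes differ from the rest only in how
#' they interact with loop extruders in the 1D simulation.
#'
#' @param n_nucleosomes number of lattice sites (>= 2).
#' @param centromere_positions integer vector of 0-based lattice indices,
#'   strictly increasing, within `[0, n_nucleosomes)`. May be empty.
#' @param bp_per_nucleosome base pairs represented by one site (default 200).
#' @param layout optional metadata list describing how the layout was drawn.
#' @return An object of class `chromosome_spec`.
#' @seealso [holocentric_spec()], [monocentric_spec()]
#' @export
chromosome_spec <- function(n_nucleosomes, centromere_positions = integer(),
                            bp_per_nucleosome = 200, layout = NULL) {
  n_nucleosomes <- as.integer(n_nucleosomes)
  centromere_positions <- as.integer(centromere_positions)
  stopifnot(n_nucleosomes >= 2L)
  if (length(centromere_positions)) {
    if (any(centromere_positions < 0L) ||
        any(centromere_positions >= n_nucleosomes)) {
      stop("centromere positions must lie in [0, n_nucleosomes)")
    }
    if (any(diff(centromere_positions) <= 0L)) {
      stop("centromere positions must be strictly increasing")
    }
  }
  if (length(centromere_positions) > n_nucleosomes) {
    stop("more centromeric sites than nucleosomes")
  }
  structure(
    list(n_nucleosomes = n_nucleosomes,
         centromere_positions = centromere_positions,
         bp_per_nucleosome = bp_per_nucleosome,
         layout = layout),
    class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  kind <- if (is.null(x$layout)) "custom" else x$layout$kind
  cat(sprintf(
    "<chromosome_spec> %d nucleosomes (~%.1f Mb), %d centromeric (%s)\n",
    x$n_nucleosomes, x$n_nucleosomes * x$bp_per_nucleosome / 1e6,
    length(x$centromere_positions), kind))
  invisible(x)
}

#' Holocentric centromere layout
#'
#' Spreads `n_centromeric` centromeric nucleosomes over the whole chromosome.
#' By default positions are drawn uniformly at random without replacement;
#' with `even = TRUE` they are placed deterministically at the midpoints of
#' `n_centromeric` equal intervals.
#'
#' @inheritParams chromosome_spec
#' @param n_centromeric number of centromeric nucleosomes.
#' @param seed optional RNG seed for the random layout.
#' @param even logical; deterministic even spacing instead of uniform random.
#' @return A `chromosome_spec`.
#' @examples
#' holocentric_spec(1000, 10, even = TRUE)$centromere_positions
#' @export
holocentric_spec <- function(n_nucleosomes, n_centromeric, seed = NULL,
                             even = FALSE, bp_per_nucleosome = 200) {
  n_nucleosomes <- as.integer(n_nucleosomes)
  n_centromeric <- as.integer(n_centromeric)
  if (n_centromeric > n_nucleosomes) {
    stop("n_centromeric must not exceed n_nucleosomes")
  }
  if (n_centromeric == 0L) {
    pos <- integer()
  } else if (even) {
    # midpoints of n_centromeric equal intervals
    width <- n_nucleosomes / n_centromeric
    pos <- as.integer(floor((seq_len(n_centromeric) - 0.5) * width))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pos <- sort(sample.int(n_nucleosomes, n_centromeric) - 1L)
  }
  chromosome_spec(n_nucleosomes, pos, bp_per_nucleosome,
                  layout = list(kind = "holocentric",
                                n_centromeric = n_centromeric,
                                even = even, seed = seed))
}

#' Monocentric centromere layout
#'
#' Confines `n_centromeric` centromeric nucleosomes to a contiguous window of
#' `region_bp / bp_per_nucleosome` lattice sites, centred on the chromosome
#' midpoint by default.
#'
#' @inheritParams holocentric_spec
#' @param region_bp extent of the centromeric region in base pairs.
#' @param region_start optional 0-based start site of the window; default
#'   centres the window on the chromosome.
#' @return A `chromosome_spec`; its `layout` records `region_start` and
#'   `region_sites` for downstream region-restricted analyses.
#' @export
monocentric_spec <- function(n_nucleosomes, n_centromeric, region_bp,
                             bp_per_nucleosome = 200, seed = NULL,
                             even = FALSE, region_start = NULL) {
  n_nucleosomes <- as.integer(n_nucleosomes)
  n_centromeric <- as.integer(n_centromeric)
  region_sites <- as.integer(region_bp / bp_per_nucleosome)
  if (region_sites > n_nucleosomes) {
    stop("centromeric region larger than the chromosome")
  }
  if (region_sites < n_centromeric) {
    stop("centromeric region smaller than n_centromeric sites")
  }
  if (is.null(region_start)) {
    region_start <- as.integer((n_nucleosomes - region_sites) %/% 2)
  }
  region_start <- as.integer(region_start)
  if (n_centromeric == 0L) {
    pos <- integer()
  } else if (even) {
    width <- region_sites / n_centromeric
    pos <- region_start +
      as.integer(floor((seq_len(n_centromeric) - 0.5) * width))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pos <- region_start + sort(sample.int(region_sites, n_centromeric) - 1L)
  }
  chromosome_spec(n_nucleosomes, pos, bp_per_nucleosome,
                  layout = list(kind = "monocentric",
                                n_centromeric = n_centromeric,
                                region_start = region_start,
                                region_sites = region_sites,
                                even = even, seed = seed))
}

#' Serialize / deserialize a chromosome specification
#'
#' Chromosome specs round-trip through a small YAML document.
#'
#' @param spec a `chromosome_spec`.
#' @param path file path.
#' @return `read_chromosome_spec` returns a `chromosome_spec`.
#' @export
write_chromosome_spec <- function(spec, path) {
  doc <- list(n_nucleosomes = spec$n_nucleosomes,
              bp_per_nucleosome = spec$bp_per_nucleosome,
              centromere_positions = as.integer(spec$centromere_positions),
              layout = spec$layout)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_chromosome_spec
#' @export
read_chromosome_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  chromosome_spec(doc$n_nucleosomes, doc$centromere_positions,
                  doc$bp_per_nucleosome, layout = doc$layout)
}
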