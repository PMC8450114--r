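# 1D loop-extrusion simulation: parameter objects, the engine wrapper, and
# bond-trace accessors. Lattice positions are 0-based.

#' Loop-extrusion parameters
#'
#' @param n_les number of loop extruders; constant for the whole run.
#' @param lifetime mean residence time in 1D steps; each unanchored LE unbinds
#'   with per-step probability `1/lifetime` and rebinds immediately at a random
#'   free adjacent pair (default 1000).
#' @param mode centromere interaction mode: `"none"` (LEs ignore centromeric
#'   nucleosomes), `"blocking"` (a centromeric site arrests the approaching
#'   leg; the LE may still unbind) or `"anchoring"` (blocking plus permanent
#'   binding: an LE with a leg arrested at a centromeric site never unbinds).
#'   In blocking/anchoring modes centromeric sites can never be occupied by an
#'   LE leg.
#' @param n_steps number of 1D steps to simulate.
#' @param seed RNG seed recorded with the trace; `NULL` leaves the RNG state
#'   untouched.
#' @return An object of class `extrusion_params`.
#' @export
extrusion_params <- function(n_les, lifetime = 1000, mode = c("none",
                             "blocking", "anchoring"), n_steps = 100000,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_les >= 1, lifetime > 0, n_steps >= 0)
  structure(list(n_les = as.integer(n_les), lifetime = lifetime, mode = mode,
                 n_steps = as.integer(n_steps), seed = seed),
            class = "extrusion_params")
}

mode_code <- function(mode) {
  match(mode, c("none", "blocking", "anchoring")) - 1L
}

#' Run the 1D loop-extrusion simulation
#'
#' Simulates `params$n_steps` steps of two-sided loop extrusion on the lattice
#' chromosome. Each LE binds a pair of nucleosomes `(left, right)`; once per
#' step each leg moves one site outward unless the destination is occupied by
#' another LE leg, is a centromeric site (blocking/anchoring modes), or is a
#' chromosome end. Unanchored LEs unbind with probability `1/lifetime` per
#' step and rebind at a uniformly random free adjacent pair, so the number of
#' LEs is constant throughout.
#'
#' @param spec a [chromosome_spec()].
#' @param params an [extrusion_params()].
#' @param sample_every record the full bond list every this many steps
#'   (step 0 and the final step are always recorded).
#' @param max_tries bound on rejection-sampling attempts when rebinding; if no
#'   free pair is found the LE waits one step at its old pair.
#' @return A `bond_trace`: sampled bond lists (`steps`, matrices `left` and
#'   `right` of dimension samples x LEs), the final [extruder_state()], the
#'   total number of unbinding events, `spec` and `params`.
#' @examples
#' spec <- holocentric_spec(500, 5, even = TRUE)
#' tr <- run_extrusion(spec, extrusion_params(10, mode = "anchoring",
#'                                            n_steps = 2000, seed = 1))
#' final_state(tr)
#' @export
run_extrusion <- function(spec, params, sample_every = max(1L,
                          params$n_steps %/% 100L), max_tries = 1000L) {
  stopifnot(inherits(spec, "chromosome_spec"),
            inherits(params, "extrusion_params"))
  if (2L * params$n_les > spec$n_nucleosomes) {
    stop("each LE needs two free sites: 2 * n_les must not exceed the ",
         "number of nucleosomes")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_run_extrusion(spec$n_nucleosomes, spec$centromere_positions,
                           params$n_les, params$lifetime,
                           mode_code(params$mode), params$n_steps,
                           as.integer(sample_every), as.integer(max_tries))
  structure(
    list(steps = res$steps, left = res$left, right = res$right,
         final = extruder_state(res$final_left, res$final_right,
                                anchored_left = res$anchored_left,
                                anchored_right = res$anchored_right,
                                step = params$n_steps),
         n_unbind = res$n_unbind, n_rebind_fail = res$n_rebind_fail,
         spec = spec, params = params, sample_every = sample_every),
    class = "bond_trace")
}

#' @export
print.bond_trace <- function(x, ...) {
  cat(sprintf(
    "<bond_trace> %d LEs, mode %s, %d steps (%d sampled states), %d unbinds\n",
    x$params$n_les, x$params$mode, x$params$n_steps, length(x$steps),
    x$n_unbind))
  invisible(x)
}

#' Extruder state: the bond list at one 1D step
#'
#' @param left,right integer vectors of 0-based lattice positions, one entry
#'   per LE, with `left < right` elementwise.
#' @param anchored_left,anchored_right optional per-leg flags marking legs
#'   arrested at a centromeric site in anchoring mode.
#' @param step the 1D step this state was sampled at.
#' @return An object of class `extruder_state`.
#' @export
extruder_state <- function(left, right, anchored_left = NULL,
                           anchored_right = NULL, step = NA_integer_) {
  left <- as.integer(left); right <- as.integer(right)
  stopifnot(length(left) == length(right), all(left < right))
  legs <- c(left, right)
  if (anyDuplicated(legs)) stop("a site is occupied by more than one LE leg")
  structure(list(left = left, right = right,
                 anchored_left = anchored_left,
                 anchored_right = anchored_right, step = step),
            class = "extruder_state")
}

#' @export
print.extruder_state <- function(x, ...) {
  cat(sprintf("<extruder_state> %d LEs at step %s\n", length(x$left),
              format(x$step)))
  invisible(x)
}

#' Extract one sampled state from a bond trace
#'
#' @param trace a `bond_trace`.
#' @param i sample index (1-based row into the sampled states); defaults to
#'   the last sample.
#' @return An [extruder_state()].
#' @export
state_at <- function(trace, i = length(trace$steps)) {
  extruder_state(trace$left[i, ], trace$right[i, ], step = trace$steps[i])
}

#' @rdname state_at
#' @export
final_state <- function(trace) trace$final

#' Export / import a bond trace as TSV
#'
#' One row per sampled LE bond: `step`, `le_id` (1-based), `left`, `right`.
#' A JSON sidecar (`<path>.json`) stores the chromosome spec and parameters.
#'
#' @param trace a `bond_trace`.
#' @param path TSV file path.
#' @export
write_bond_trace <- function(trace, path) {
  n_les <- ncol(trace$left)
  df <- data.frame(
    step = rep(trace$steps, each = n_les),
    le_id = rep(seq_len(n_les), times = length(trace$steps)),
    left = as.vector(t(trace$left)),
    right = as.vector(t(trace$right)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  header <- list(
    n_nucleosomes = trace$spec$n_nucleosomes,
    bp_per_nucleosome = trace$spec$bp_per_nucleosome,
    centromere_positions = as.integer(trace$spec$centromere_positions),
    params = trace$params[c("n_les", "lifetime", "mode", "n_steps")],
    seed = trace$params$seed, n_unbind = trace$n_unbind,
    sample_every = trace$sample_every)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bond_trace
#' @export
read_bond_trace <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  steps <- unique(df$step)
  n_les <- header$params$n_les
  left <- matrix(df$left, ncol = n_les, byrow = TRUE)
  right <- matrix(df$right, ncol = n_les, byrow = TRUE)
  spec <- chromosome_spec(header$n_nucleosomes, header$centromere_positions,
                          header$bp_per_nucleosome)
  params <- extrusion_params(n_les, header$params$lifetime,
                             header$params$mode, header$params$n_steps,
                             seed = header$seed)
  structure(
    list(steps = steps, left = left, right = right,
         final = extruder_state(left[nrow(left), ], right[nrow(right), ],
                                step = steps[length(steps)]),
         n_unbind = header$n_unbind, n_rebind_fail = NA,
         spec = spec, params = params, sample_every = header$sample_every),
    class = "bond_trace")
}
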