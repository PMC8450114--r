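# 1D compaction observables: axial nucleosomes, loop lengths, fraction of the
# chromosome outside loops, side-by-side loop counts, equilibrium detection
# and LE localization.

state_legs <- function(state) {
  list(left = state$left, right = state$right)
}

# coverage depth of the *open* intervals (left, right) at positions p,
# counting every LE: depth(p) = #{l < p} - #{r <= p}
open_interval_depth <- function(p, left, right) {
  sl <- sort(left); sr <- sort(right)
  findInterval(p - 1L, sl) - findInterval(p, sr)
}

#' Axial nucleosomes of an extruder state
#'
#' Axial nucleosomes are the nucleosomes bound by LEs that are not strictly
#' inside any other LE's loop span. They form the axis of the condensed
#' chromosome; their count is the model's (1D) chromosome length. With no
#' nested loops this count is exactly twice the number of LEs.
#'
#' @param state an [extruder_state()].
#' @return Sorted integer vector of 0-based axial site indices.
#' @examples
#' s <- extruder_state(c(10, 15, 50), c(40, 25, 60))
#' axial_nucleosomes(s) # 10, 40, 50, 60: the loop (15,25) is nested
#' @export
axial_nucleosomes <- function(state) {
  legs <- c(state$left, state$right)
  depth <- open_interval_depth(legs, state$left, state$right)
  sort(legs[depth == 0L])
}

#' Chromosome length in axial nucleosomes
#'
#' @inheritParams axial_nucleosomes
#' @return Count of axial nucleosomes.
#' @export
chromosome_length_1d <- function(state) length(axial_nucleosomes(state))

#' Average chromatin loop length
#'
#' The sum over LEs of the nucleosomes strictly between the bound pair,
#' divided by the number of LEs. Nucleosomes inside nested loops contribute to
#' every enclosing loop, so `avg_loop_length * n_les` can exceed the
#' chromosome size in deeply nested states.
#'
#' @inheritParams axial_nucleosomes
#' @return Mean nucleosomes per loop.
#' @export
average_loop_length <- function(state) {
  if (!length(state$left)) stop("state has no LEs")
  mean(state$right - state$left - 1L)
}

#' Fraction of nucleosomes outside all chromatin loops
#'
#' A nucleosome is outside loops if it is not covered by any LE's closed span
#' `[left, right]`. At the anchoring-mode equilibrium essentially only the
#' centromeric nucleosomes themselves remain outside.
#'
#' @inheritParams axial_nucleosomes
#' @param n_nucleosomes chromosome size in sites.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_outside_loops <- function(state, n_nucleosomes) {
  if (!length(state$left)) return(1)
  o <- order(state$left)
  l <- state$left[o]; r <- cummax(state$right[o])
  starts <- which(c(TRUE, l[-1] > r[-length(r)] + 1L))
  ends <- c(starts[-1] - 1L, length(l))
  covered <- sum(r[ends] - l[starts] + 1L)
  1 - covered / n_nucleosomes
}

#' Count side-by-side (non-nested) loops
#'
#' A loop is side-by-side if it is not nested strictly inside another LE's
#' span; side-by-side loops share the chromosome axis. At the anchoring-mode
#' plateau roughly one or two such loops sit between each pair of adjacent
#' centromeric nucleosomes.
#'
#' @inheritParams axial_nucleosomes
#' @return Count of non-nested loops.
#' @export
side_by_side_loops <- function(state) {
  depth <- open_interval_depth(state$left, state$left, state$right)
  sum(depth == 0L)
}

#' Classify a state as sparse or compacted
#'
#' A chromosome is sparse when its loops cannot cover it:
#' `avg_loop_length * n_les < n_nucleosomes`. Ties go to `"compacted"`.
#'
#' @param avg_loop_length mean loop length in nucleosomes.
#' @param n_les number of LEs.
#' @param n_nucleosomes chromosome size in sites.
#' @return `"sparse"` or `"compacted"`.
#' @export
sparse_or_compacted <- function(avg_loop_length, n_les, n_nucleosomes) {
  if (avg_loop_length * n_les < n_nucleosomes) "sparse" else "compacted"
}

#' Per-sample compaction metrics of a bond trace
#'
#' @param trace a `bond_trace`.
#' @param replicate optional replicate id recorded in the output.
#' @return A data.frame with one row per sampled state: `step`,
#'   `chromosome_length`, `avg_loop_length`, `frac_outside`,
#'   `n_side_by_side`, `state` (sparse/compacted) and `replicate`.
#' @export
compaction_series <- function(trace, replicate = 1L) {
  n <- trace$spec$n_nucleosomes
  n_les <- trace$params$n_les
  rows <- lapply(seq_along(trace$steps), function(i) {
    st <- state_at(trace, i)
    all_len <- average_loop_length(st)
    data.frame(step = trace$steps[i],
               chromosome_length = chromosome_length_1d(st),
               avg_loop_length = all_len,
               frac_outside = fraction_outside_loops(st, n),
               n_side_by_side = side_by_side_loops(st),
               state = sparse_or_compacted(all_len, n_les, n),
               replicate = replicate)
  })
  do.call(rbind, rows)
}

#' Equilibrium detection on a compaction series
#'
#' The simulation is considered equilibrated when the windowed means of the
#' chromosome length and the average loop length are stable over time: the
#' means over the last two non-overlapping windows differ by less than `tol`
#' relatively.
#'
#' @param series a data.frame from [compaction_series()] (single replicate).
#' @param window window length in 1D steps; default 10% of the covered range.
#' @param tol relative tolerance (default 0.05).
#' @return Logical.
#' @export
equilibrium_reached <- function(series, window = NULL, tol = 0.05) {
  span <- diff(range(series$step))
  if (is.null(window)) window <- span / 10
  if (span < 2 * window) {
    stop("series must cover at least two windows of steps")
  }
  t_end <- max(series$step)
  w2 <- series[series$step > t_end - window, , drop = FALSE]
  w1 <- series[series$step > t_end - 2 * window &
               series$step <= t_end - window, , drop = FALSE]
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
  rel(mean(w1$chromosome_length), mean(w2$chromosome_length)) < tol &&
    rel(mean(w1$avg_loop_length), mean(w2$avg_loop_length)) < tol
}

#' Colocalization of LE legs with centromeric nucleosomes
#'
#' Fraction of LE legs lying within `radius` lattice sites of the nearest
#' centromeric site. With no centromeres the fraction is 0 by convention.
#'
#' @inheritParams axial_nucleosomes
#' @param spec a [chromosome_spec()].
#' @param radius distance threshold in lattice sites.
#' @return Fraction in `[0, 1]`.
#' @export
le_localization <- function(state, spec, radius = 1L) {
  cen <- spec$centromere_positions
  if (!length(cen)) return(0)
  legs <- c(state$left, state$right)
  idx <- findInterval(legs, cen)
  d_lo <- ifelse(idx >= 1L, legs - cen[pmax(idx, 1L)], Inf)
  d_hi <- ifelse(idx < length(cen), cen[pmin(idx + 1L, length(cen))] - legs,
                 Inf)
  mean(pmin(d_lo, d_hi) <= radius)
}

#' Mean equilibrium metrics over the tail of a trace
#'
#' Averages [compaction_series()] columns over the sampled states in the last
#' `tail_frac` of the run, the window the model treats as equilibrated.
#'
#' @param trace a `bond_trace`.
#' @param tail_frac fraction of the run to average over (default 0.5).
#' @return One-row data.frame of tail means plus the final-state values
#'   (`*_final` columns).
#' @export
equilibrium_summary <- function(trace, tail_frac = 0.5) {
  ser <- compaction_series(trace)
  t_cut <- max(ser$step) - tail_frac * diff(range(ser$step))
  tail_ser <- ser[ser$step > t_cut, , drop = FALSE]
  fin <- final_state(trace)
  data.frame(
    chromosome_length = mean(tail_ser$chromosome_length),
    avg_loop_length = mean(tail_ser$avg_loop_length),
    frac_outside = mean(tail_ser$frac_outside),
    n_side_by_side = mean(tail_ser$n_side_by_side),
    chromosome_length_final = chromosome_length_1d(fin),
    avg_loop_length_final = average_loop_length(fin),
    frac_outside_final = fraction_outside_loops(fin,
                                                trace$spec$n_nucleosomes),
    n_side_by_side_final = side_by_side_loops(fin))
}

#' Loop sizes inside and outside a genomic region
#'
#' Splits loops by whether their span lies entirely within the given window
#' (e.g. the monocentric centromeric region) and averages their lengths. The
#' condensed monocentric chromosome shows much smaller loops inside the
#' centromeric region than outside it.
#'
#' @inheritParams axial_nucleosomes
#' @param region_start,region_end 0-based site window, half-open
#'   `[region_start, region_end)`.
#' @return List with `inside`, `outside` (mean loop lengths in nucleosomes)
#'   and the corresponding loop counts.
#' @export
loop_sizes_by_region <- function(state, region_start, region_end) {
  len <- state$right - state$left - 1L
  inside <- state$left >= region_start & state$right < region_end
  list(inside = if (any(inside)) mean(len[inside]) else NA_real_,
       outside = if (any(!inside)) mean(len[!inside]) else NA_real_,
       n_inside = sum(inside), n_outside = sum(!inside))
}

#' Loops per inter-centromere interval
#'
#' Counts side-by-side (non-nested) loops whose span lies strictly between
#' consecutive centromeric nucleosomes. At the anchoring plateau >=90% of the
#' intervals hold one or two loops.
#'
#' @inheritParams le_localization
#' @return Integer vector, one count per interval between adjacent
#'   centromeric sites.
#' @export
loops_per_interval <- function(state, spec) {
  cen <- spec$centromere_positions
  if (length(cen) < 2L) return(integer())
  depth <- open_interval_depth(state$left, state$left, state$right)
  top_l <- state$left[depth == 0L]
  top_r <- state$right[depth == 0L]
  vapply(seq_len(length(cen) - 1L), function(i) {
    sum(top_l > cen[i] & top_r < cen[i + 1L])
  }, integer(1))
}
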