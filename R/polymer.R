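# Coarse-grained Langevin dynamics of the chromatin fibre with replayed LE
# bonds and the optional kinetochore plate.
#
# Reduced units: length nm, energy kBT, bead mass 1. The dynamics are only
# required to reach conformational equilibrium; no real-time mapping is
# implied.

#' Force-field parameters for the chromatin fibre
#'
#' The fibre force field has three terms valid for all nucleosomes: (i) a
#' harmonic backbone bond with 10 nm mean distance whose strength is set by
#' the wiggle distance (RMS bond-length fluctuation; `k = kBT / wiggle^2`),
#' (ii) an angular stiffness penalty `k_ang * (1 - cos(theta))` on consecutive
#' bond angles, and (iii) a pairwise soft-core repulsion vanishing beyond
#' `repulsion_range` with a finite barrier at full overlap, so two chromatin
#' strands can pass through each other (a topoisomerase II-like crossing at
#' `crossing_energy` = 5 kBT) while the kinetochore barrier
#' (`kinetochore_crossing_energy` = 10000 kBT) is impassable. LE bonds are
#' harmonic with 5 nm mean distance; tethers are harmonic wells.
#'
#' @param bond_mean backbone bond mean distance, nm.
#' @param bond_wiggle backbone wiggle distance, nm.
#' @param stiffness_k angular stiffness constant, kBT.
#' @param repulsion_range soft-core repulsion cutoff, nm.
#' @param crossing_energy chromatin-chromatin overlap barrier, kBT.
#' @param kinetochore_crossing_energy overlap barrier for pairs involving a
#'   kinetochore bead, kBT.
#' @param le_bond_mean LE bond mean distance, nm.
#' @param le_bond_k LE bond spring constant, kBT/nm^2.
#' @param tether_k tether spring constant, kBT/nm^2.
#' @return An object of class `ff_params`.
#' @export
forcefield_params <- function(bond_mean = 10, bond_wiggle = 1,
                              stiffness_k = 1, repulsion_range = 10.5,
                              crossing_energy = 5,
                              kinetochore_crossing_energy = 10000,
                              le_bond_mean = 5, le_bond_k = 0.5,
                              tether_k = 5) {
  p <- list(bond_mean = bond_mean, bond_wiggle = bond_wiggle,
            stiffness_k = stiffness_k, repulsion_range = repulsion_range,
            crossing_energy = crossing_energy,
            kinetochore_crossing_energy = kinetochore_crossing_energy,
            le_bond_mean = le_bond_mean, le_bond_k = le_bond_k,
            tether_k = tether_k)
  stopifnot(all(unlist(p) > 0),
            kinetochore_crossing_energy > crossing_energy)
  structure(p, class = "ff_params")
}

#' Integrator parameters
#'
#' Fixed-step BAOAB Langevin integration in reduced units (kBT = 1, bead mass
#' 1). `steps_per_block` is the 1D-to-3D coupling ratio: one 1D step of the
#' bond trace corresponds to one block of 3D steps.
#'
#' @param kBT thermal energy in reduced units (default 1; the simulated
#'   temperature only sets the scale of fluctuations).
#' @param friction Langevin friction, reduced units (1/time).
#' @param dt time step, reduced units.
#' @param steps_per_block 3D steps per block (default 100).
#' @param n_blocks_warmup blocks run without LE bonds before extrusion.
#' @param n_blocks_extrusion blocks run with LE bonds replayed per block.
#' @param snapshot_every store a conformation every this many blocks.
#' @param seed optional RNG seed.
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(kBT = 1, friction = 0.5, dt = 0.08,
                              steps_per_block = 100, n_blocks_warmup = 10000,
                              n_blocks_extrusion = 40000,
                              snapshot_every = 100, seed = NULL) {
  stopifnot(kBT >= 0, friction >= 0, dt > 0, steps_per_block >= 1)
  structure(list(kBT = kBT, friction = friction, dt = dt,
                 steps_per_block = as.integer(steps_per_block),
                 n_blocks_warmup = as.integer(n_blocks_warmup),
                 n_blocks_extrusion = as.integer(n_blocks_extrusion),
                 snapshot_every = as.integer(snapshot_every), seed = seed),
            class = "integrator_params")
}

#' Evaluate the chromatin force field on one conformation
#'
#' Computes per-bead force vectors and the total potential energy for the
#' fibre force field, optionally including LE bonds and tethers. Useful for
#' inspecting the force field; the integrator uses the same kernel.
#'
#' @param conf a [conformation()]; kinetochore beads, if present, are
#'   appended after the chromatin beads.
#' @param ff a [forcefield_params()].
#' @param le_bonds optional [extruder_state()] whose pairs become LE bonds.
#' @param tether_idx,tether_ref optional 0-based bead indices and reference
#'   coordinates for tethers.
#' @return List with `forces` (beads x 3) and `energy` (kBT).
#' @export
chromatin_forces <- function(conf, ff = forcefield_params(), le_bonds = NULL,
                             tether_idx = integer(), tether_ref = NULL) {
  coords <- conf$coords
  n_chrom <- nrow(coords)
  if (!is.null(conf$kinetochore)) coords <- rbind(coords, conf$kinetochore)
  le_a <- integer(); le_b <- integer()
  if (!is.null(le_bonds)) {
    le_a <- le_bonds$left
    le_b <- le_bonds$right
  }
  if (is.null(tether_ref)) tether_ref <- matrix(0, 0, 3)
  cpp_chromatin_forces(coords, n_chrom, 1 / ff$bond_wiggle^2, ff$bond_mean,
                       ff$stiffness_k, ff$crossing_energy,
                       ff$kinetochore_crossing_energy, ff$repulsion_range,
                       as.integer(le_a), as.integer(le_b), ff$le_bond_k,
                       ff$le_bond_mean, as.integer(tether_idx),
                       as.matrix(tether_ref), ff$tether_k)
}

#' LE bond set replayed at a given block
#'
#' Maps a 3D block index onto the 1D bond trace (one 1D step per block) and
#' returns the harmonic LE bond pairs active in that block.
#'
#' @param trace a `bond_trace`.
#' @param block 1-based block index into the extrusion phase.
#' @param trace_start 1D step corresponding to block 1 (default: step 1).
#' @return An [extruder_state()] with the active pairs.
#' @export
replay_le_bonds <- function(trace, block, trace_start = 1L) {
  step_1d <- trace_start + block - 1L
  if (step_1d > max(trace$steps)) stop("block index beyond the bond trace")
  row <- findInterval(step_1d, trace$steps)
  state_at(trace, row)
}

block_schedule <- function(trace, ip, trace_start) {
  # per-block row of the sampled trace (0-based for C++); -1 during warmup
  sched <- rep(-1L, ip$n_blocks_warmup)
  if (ip$n_blocks_extrusion > 0L) {
    steps_1d <- trace_start + seq_len(ip$n_blocks_extrusion) - 1L
    if (max(steps_1d) > max(trace$steps)) {
      stop("bond trace too short for n_blocks_extrusion")
    }
    sched <- c(sched, findInterval(steps_1d, trace$steps) - 1L)
  }
  sched
}

#' Run Langevin dynamics with replayed loop extrusion
#'
#' Integrates the chromatin fibre with the standard two-phase schedule: first
#' `n_blocks_warmup` blocks without LE bonds, then `n_blocks_extrusion`
#' blocks during which the LE bond set is updated every block from the 1D
#' bond trace.
#'
#' @param conf0 initial [conformation()].
#' @param spec a [chromosome_spec()].
#' @param trace a `bond_trace` from [run_extrusion()].
#' @param ff a [forcefield_params()].
#' @param ip an [integrator_params()].
#' @param trace_start 1D step replayed in the first extrusion block.
#' @param tether_idx,tether_ref optional harmonic tethers (0-based indices
#'   into the full bead list, reference coordinates in nm).
#' @param plane optional `c(y0, xmin, xmax, zmin, zmax)` plate footprint for
#'   the through-plane crossing counter.
#' @param zero_velocities start from zero velocities instead of a
#'   Maxwell-Boltzmann draw.
#' @param freeze_idx 0-based indices of beads held immobile for the whole
#'   run (rigid objects such as the kinetochore plate).
#' @return A `trajectory`: list of snapshot [conformation()]s, per-snapshot
#'   energies, the plane-crossing count, and run metadata.
#' @export
run_dynamics <- function(conf0, spec, trace = NULL, ff = forcefield_params(),
                         ip = integrator_params(), trace_start = 1L,
                         tether_idx = integer(), tether_ref = NULL,
                         plane = numeric(), zero_velocities = FALSE,
                         freeze_idx = integer()) {
  coords <- conf0$coords
  n_chrom <- nrow(coords)
  n_kin <- 0L
  if (!is.null(conf0$kinetochore)) {
    coords <- rbind(coords, conf0$kinetochore)
    n_kin <- nrow(conf0$kinetochore)
  }
  if (is.null(trace)) {
    if (ip$n_blocks_extrusion > 0L) stop("extrusion blocks require a trace")
    sched <- rep(-1L, ip$n_blocks_warmup)
    tl <- matrix(0L, 1, 1); tr <- matrix(1L, 1, 1)
  } else {
    sched <- block_schedule(trace, ip, trace_start)
    tl <- trace$left; tr <- trace$right
  }
  if (is.null(tether_ref)) tether_ref <- matrix(0, 0, 3)
  if (!is.null(ip$seed)) set.seed(ip$seed)
  res <- cpp_run_dynamics(coords, n_chrom, 1 / ff$bond_wiggle^2,
                          ff$bond_mean, ff$stiffness_k, ff$crossing_energy,
                          ff$kinetochore_crossing_energy, ff$repulsion_range,
                          tl, tr, sched, ff$le_bond_k, ff$le_bond_mean,
                          as.integer(tether_idx), as.matrix(tether_ref),
                          ff$tether_k, ip$kBT, ip$friction, ip$dt,
                          ip$steps_per_block, ip$snapshot_every, plane,
                          zero_velocities, as.integer(freeze_idx))
  frames <- lapply(seq_along(res$frames), function(i) {
    m <- res$frames[[i]]
    conformation(m[seq_len(n_chrom), , drop = FALSE],
                 kinetochore = if (n_kin) m[n_chrom + seq_len(n_kin), ,
                                            drop = FALSE],
                 step = res$frame_block[i])
  })
  structure(list(frames = frames, frame_block = res$frame_block,
                 potential_energy = res$potential_energy,
                 kinetic_energy = res$kinetic_energy,
                 plane_crossings = res$plane_crossings,
                 crossing_beads = res$crossing_beads,
                 crossing_blocks = res$crossing_blocks,
                 spec = spec, ff = ff, ip = ip, n_chrom = n_chrom,
                 n_kin = n_kin),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d snapshots of %d beads%s\n", length(x$frames),
              x$n_chrom,
              if (x$n_kin) sprintf(" + %d kinetochore beads", x$n_kin) else ""))
  invisible(x)
}

#' Run the kinetochore-stage dynamics
#'
#' Starts from the aligned [kinetochore_initial_conformation()] and evolves
#' the chromatin loops under replayed LE bonds. The kinetochore beads are
#' held at fixed grid positions (a rigid plate: a harmonic tether would be
#' overwhelmed by the impassable-barrier contact forces and let the plate
#' deform); the centromeric nucleosomes are tethered to their initial
#' positions by harmonic wells. Pairs involving kinetochore beads use the
#' impassable repulsion barrier; through-plate crossings of chromatin beads
#' are counted and reported (they should be zero). By default the replay starts at the
#' midpoint of the 1D run, so the loop structure is already equilibrated while
#' extrusion continues.
#'
#' @inheritParams run_dynamics
#' @param trace_start first replayed 1D step; defaults to half of the trace.
#' @return A `trajectory` (see [run_dynamics()]).
#' @note The default integrator uses a smaller time step than plain chromatin
#'   runs: the impassable kinetochore barrier is much stiffer than the
#'   chromatin repulsion, and the fixed-step integrator must resolve it.
#' @export
run_kinetochore_dynamics <- function(conf0, spec, trace,
                                     ff = forcefield_params(),
                                     ip = integrator_params(dt = 0.02),
                                     trace_start = NULL) {
  if (is.null(conf0$kinetochore)) {
    stop("conf0 must carry kinetochore beads; see ",
         "kinetochore_initial_conformation()")
  }
  if (is.null(trace_start)) {
    trace_start <- max(1L, trace$params$n_steps %/% 2L)
  }
  n_chrom <- nrow(conf0$coords)
  n_kin <- nrow(conf0$kinetochore)
  tether_idx <- spec$centromere_positions
  tether_ref <- conf0$coords[spec$centromere_positions + 1L, , drop = FALSE]
  freeze_idx <- n_chrom + seq_len(n_kin) - 1L
  kin <- conf0$kinetochore
  # crossing counter covers the plate interior: footprint inset by one bead
  # radius so beads sliding around the plate edge are not miscounted
  half <- ff$bond_mean / 2
  plane <- c(kin[1, 2], min(kin[, 1]) + half, max(kin[, 1]) - half,
             min(kin[, 3]) + half, max(kin[, 3]) - half)
  run_dynamics(conf0, spec, trace, ff, ip, trace_start = trace_start,
               tether_idx = tether_idx, tether_ref = tether_ref,
               plane = plane, freeze_idx = freeze_idx)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @param spec optional spec for centromere tags.
#' @export
write_trajectory_xyz <- function(traj, path, spec = traj$spec) {
  for (i in seq_along(traj$frames)) {
    write_xyz(traj$frames[[i]], path, spec = spec, append = i > 1L)
  }
  invisible(path)
}
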