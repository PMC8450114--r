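# 3D polymer engine: force-field values, integrator behaviour, LE bond
# replay, chain integrity, and kinetochore tethering.

test_that("force field reproduces its specified ranges and minima", {
  # bonded pair at the 10 nm equilibrium distance: no force, no energy
  f <- chromatin_forces(conformation(rbind(c(0, 0, 0), c(10, 0, 0))))
  expect_lt(max(abs(f$forces)), 1e-10)
  expect_equal(f$energy, 0)

  # straight three-bead chain: zero stiffness force; bent 90 degrees: 1 kBT
  fs <- chromatin_forces(conformation(cbind(c(0, 10, 20), 0, 0)))
  expect_lt(max(abs(fs$forces)), 1e-10)
  f90 <- chromatin_forces(conformation(rbind(c(0, 0, 0), c(10, 0, 0),
                                             c(10, 10, 0))))
  expect_equal(f90$energy, 1)

  # non-bonded repulsion: zero beyond 10.5 nm, 5 kBT at overlap
  three <- function(gap) {
    # fold bead 3 back near bead 1; beads 1 and 3 are non-bonded
    conformation(rbind(c(0, 0, 0), c(10, 0, 0), c(gap, 0, 1e-4)))
  }
  f_far <- chromatin_forces(conformation(rbind(c(0, 0, 0), c(10, 0, 0),
                                               c(10, 10.6, 0))))
  # 90-degree angle (1 kBT) plus the 0.6 nm bond stretch; beads 1,3 are
  # beyond the repulsion cutoff
  expect_equal(f_far$energy, 1 + 0.5 * 0.6^2, tolerance = 1e-12)
  f0 <- chromatin_forces(three(0))
  # overlap energy = 5 (repulsion) + 2 (angle at pi) + bond ~0
  expect_equal(f0$energy, 7, tolerance = 1e-3)

  # parameter validation
  expect_error(forcefield_params(crossing_energy = 20000))
})

test_that("forces are the negative energy gradient (numerical check)", {
  set.seed(4)
  coords <- matrix(rnorm(8 * 3, sd = 6), 8, 3)
  st <- extruder_state(c(0L, 2L), c(5L, 7L))
  f <- chromatin_forces(conformation(coords), le_bonds = st,
                        tether_idx = 0L, tether_ref = matrix(0, 1, 3))
  h <- 1e-6
  for (probe in list(c(1, 1), c(4, 2), c(8, 3))) {
    cp <- coords; cm <- coords
    cp[probe[1], probe[2]] <- cp[probe[1], probe[2]] + h
    cm[probe[1], probe[2]] <- cm[probe[1], probe[2]] - h
    ep <- chromatin_forces(conformation(cp), le_bonds = st, tether_idx = 0L,
                           tether_ref = matrix(0, 1, 3))$energy
    em <- chromatin_forces(conformation(cm), le_bonds = st, tether_idx = 0L,
                           tether_ref = matrix(0, 1, 3))$energy
    expect_equal(f$forces[probe[1], probe[2]], -(ep - em) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("with the thermostat off, total energy is conserved", {
  spec <- chromosome_spec(100)
  c0 <- random_walk_conformation(spec, 10, seed = 11)
  ip <- integrator_params(friction = 0, dt = 0.02, steps_per_block = 100,
                          n_blocks_warmup = 50, n_blocks_extrusion = 0,
                          snapshot_every = 5, seed = 12)
  traj <- run_dynamics(c0, spec, ip = ip)
  etot <- traj$potential_energy + traj$kinetic_energy
  drift <- abs(etot - etot[1]) / abs(etot[1])
  expect_lt(max(drift), 0.02)
})

test_that("a stretched dimer relaxes toward the bond minimum at T = 0", {
  spec <- chromosome_spec(2)
  c0 <- conformation(rbind(c(0, 0, 0), c(12, 0, 0)))
  ip <- integrator_params(kBT = 0, friction = 2, dt = 0.05,
                          steps_per_block = 20, n_blocks_warmup = 40,
                          n_blocks_extrusion = 0, snapshot_every = 4)
  traj <- run_dynamics(c0, spec, ip = ip, zero_velocities = TRUE)
  lens <- sapply(traj$frames, function(fr) {
    sqrt(sum(diff(fr$coords)^2))
  })
  err <- abs(lens - 10)
  expect_lt(err[length(err)], 0.01)
  # approach is essentially monotone (overdamped)
  expect_true(all(diff(err) < 1e-6))
})

test_that("thermal bond fluctuations match the wiggle-distance scale", {
  spec <- chromosome_spec(200)
  c0 <- random_walk_conformation(spec, 10, seed = 14)
  ip <- integrator_params(n_blocks_warmup = 150, n_blocks_extrusion = 0,
                          snapshot_every = 10, seed = 15)
  traj <- run_dynamics(c0, spec, ip = ip)
  skip_frames <- traj$frame_block > 50 # discard equilibration
  d <- unlist(lapply(traj$frames[skip_frames], function(fr) {
    sqrt(rowSums(diff(fr$coords)^2))
  }))
  # equipartition on U = 1/2 (kBT/wiggle^2) dr^2 gives sd(dr) ~ wiggle
  expect_equal(sd(d), 1, tolerance = 0.2)
  # kinetic energy per dof ~ kBT/2
  ke_per_dof <- traj$kinetic_energy[skip_frames] / (1.5 * 200)
  expect_equal(mean(ke_per_dof), 1, tolerance = 0.15)
  # chain integrity: bonds never stray beyond 5 wiggle distances
  expect_true(all(abs(d - 10) < 5))
})

test_that("LE bonds are replayed blockwise from the trace", {
  spec <- chromosome_spec(60)
  tr <- run_extrusion(spec, extrusion_params(2, lifetime = Inf,
                                             n_steps = 10, seed = 16),
                      sample_every = 1)
  # bond set changes exactly at block boundaries
  b1 <- replay_le_bonds(tr, block = 1)
  b2 <- replay_le_bonds(tr, block = 2)
  expect_equal(b2$left, pmax(b1$left - 1L, 0L))
  expect_equal(b2$right, pmin(b1$right + 1L, 59L))
  expect_equal(length(b1$left), 2L)
  expect_error(replay_le_bonds(tr, block = 99), "beyond")

  # replayed bonds pull the pair together during dynamics
  spec2 <- chromosome_spec(30)
  tr2 <- run_extrusion(spec2, extrusion_params(1, lifetime = Inf,
                                               n_steps = 20, seed = 17),
                       sample_every = 1)
  c0 <- random_walk_conformation(spec2, 10, seed = 18)
  ip <- integrator_params(n_blocks_warmup = 0, n_blocks_extrusion = 20,
                          steps_per_block = 50, snapshot_every = 20,
                          seed = 19)
  traj <- run_dynamics(c0, spec2, tr2, ip = ip)
  st <- final_state(tr2)
  fin <- traj$frames[[length(traj$frames)]]$coords
  d_pair <- sqrt(sum((fin[st$left + 1, ] - fin[st$right + 1, ])^2))
  expect_lt(d_pair, 30) # far closer than a random-coil separation
})

test_that("kinetochore beads stay put and the plate is impassable", {
  spec <- holocentric_spec(400, 8, even = TRUE)
  tr <- run_extrusion(spec, extrusion_params(16, mode = "anchoring",
                                             n_steps = 2000, seed = 20),
                      sample_every = 1)
  conf0 <- kinetochore_initial_conformation(spec, final_state(tr))
  ip <- integrator_params(dt = 0.02, n_blocks_warmup = 0,
                          n_blocks_extrusion = 500, steps_per_block = 20,
                          snapshot_every = 100, seed = 21)
  traj <- run_kinetochore_dynamics(conf0, spec, tr, ip = ip,
                                   trace_start = 1000)
  # the plate is rigid: kinetochore beads never move
  fin <- traj$frames[[length(traj$frames)]]
  expect_equal(fin$kinetochore, conf0$kinetochore)
  # no chromatin bead passes through the plate
  expect_equal(traj$plane_crossings, 0)
  # centromeric nucleosomes stay near their tethered line positions
  cen_fin <- fin$coords[spec$centromere_positions + 1, ]
  cen_0 <- conf0$coords[spec$centromere_positions + 1, ]
  expect_lt(max(sqrt(rowSums((cen_fin - cen_0)^2))), 10)
})
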