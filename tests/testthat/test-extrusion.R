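# 1D loop-extrusion engine: placement rules, motion rules, centromere
# effects, unbinding statistics, and draw-for-draw equivalence with the
# plain reference interpreter.

test_that("initial placement binds disjoint adjacent pairs, avoiding centromeres", {
  spec <- chromosome_spec(4)
  tr <- run_extrusion(spec, extrusion_params(1, n_steps = 0, seed = 7))
  st <- final_state(tr)
  expect_true(st$right == st$left + 1L)
  expect_true(st$left %in% 0:2)

  # many LEs: all pairs adjacent and site-disjoint
  spec <- chromosome_spec(1000)
  tr <- run_extrusion(spec, extrusion_params(200, n_steps = 0, seed = 1))
  st <- final_state(tr)
  expect_true(all(st$right == st$left + 1L))
  expect_equal(anyDuplicated(c(st$left, st$right)), 0L)

  # blocking mode never occupies a centromeric site
  spec <- chromosome_spec(50, centromere_positions = c(5L, 20L, 35L))
  for (seed in 1:20) {
    tr <- run_extrusion(spec, extrusion_params(10, mode = "blocking",
                                               n_steps = 0, seed = seed))
    st <- final_state(tr)
    expect_length(intersect(c(st$left, st$right), c(5L, 20L, 35L)), 0)
  }
})

test_that("an unobstructed LE extrudes two-sidedly, one site per leg per step", {
  spec <- chromosome_spec(100)
  # single LE, infinite lifetime: deterministic outward motion
  tr <- run_extrusion(spec, extrusion_params(1, lifetime = Inf,
                                             n_steps = 10, seed = 3),
                      sample_every = 1)
  start <- c(tr$left[1, 1], tr$right[1, 1])
  for (i in 1:10) {
    expect_equal(tr$left[i + 1, 1], max(start[1] - i, 0L))
    expect_equal(tr$right[i + 1, 1], min(start[2] + i, 99L))
  }
})

test_that("chromosome ends are permanent barriers", {
  spec <- chromosome_spec(60)
  tr <- run_extrusion(spec, extrusion_params(1, lifetime = Inf,
                                             n_steps = 200, seed = 5))
  st <- final_state(tr)
  expect_equal(st$left, 0L)
  expect_equal(st$right, 59L)
})

test_that("blocking arrests the approaching leg but the other leg reels on", {
  # centromere at 8; an LE starting right of it gets its left leg arrested
  # at site 9 while the right leg keeps extruding
  spec <- chromosome_spec(200, centromere_positions = 8L)
  found <- FALSE
  for (seed in 1:50) {
    tr <- run_extrusion(spec, extrusion_params(1, lifetime = Inf,
                                               mode = "blocking",
                                               n_steps = 250, seed = seed),
                        sample_every = 1)
    if (tr$left[1, 1] > 9) {
      found <- TRUE
      expect_true(all(tr$left[, 1] >= 9L))
      expect_equal(tr$left[nrow(tr$left), 1], 9L)
      expect_equal(tr$right[nrow(tr$right), 1], 199L)
    }
  }
  expect_true(found)
})

test_that("anchored LEs never unbind, even far past their lifetime", {
  # two centromeres close together: the LE between them arrests on both
  # sides and must survive 10+ lifetimes with the same pair
  spec <- chromosome_spec(100, centromere_positions = c(40L, 60L))
  lifetime <- 50
  for (seed in 1:10) {
    tr <- run_extrusion(spec, extrusion_params(1, lifetime = lifetime,
                                               mode = "anchoring",
                                               n_steps = 20 * lifetime,
                                               seed = seed),
                        sample_every = 10)
    st <- final_state(tr)
    if (st$left == 41L && st$right == 59L) {
      # arrested on both flanks: state must be frozen in the trace tail
      tail_rows <- tr$left[tr$steps > 10 * lifetime, 1]
      expect_true(all(tail_rows == 41L))
      expect_true(st$anchored_left && st$anchored_right)
    }
  }
  # in blocking mode the same configuration does unbind
  trb <- run_extrusion(spec, extrusion_params(1, lifetime = 10,
                                              mode = "blocking",
                                              n_steps = 5000, seed = 1))
  expect_gt(trb$n_unbind, 100)
})

test_that("occupancy and ordering invariants hold at every sampled step", {
  spec <- holocentric_spec(400, 8, seed = 2)
  for (mode in c("none", "blocking", "anchoring")) {
    tr <- run_extrusion(spec, extrusion_params(30, lifetime = 100,
                                               mode = mode, n_steps = 2000,
                                               seed = 11),
                        sample_every = 50)
    for (i in seq_along(tr$steps)) {
      l <- tr$left[i, ]; r <- tr$right[i, ]
      expect_true(all(l < r))
      expect_equal(anyDuplicated(c(l, r)), 0L)
      if (mode != "none") {
        expect_length(intersect(c(l, r), spec$centromere_positions), 0)
      }
    }
  }
})

test_that("empirical mean residence matches the lifetime within 5%", {
  spec <- chromosome_spec(2000)
  lifetime <- 100
  n_les <- 100
  n_steps <- 20000
  tr <- run_extrusion(spec, extrusion_params(n_les, lifetime = lifetime,
                                             n_steps = n_steps, seed = 42))
  # with per-step unbind probability 1/lifetime, expected events = L*T/lifetime
  expect_gt(tr$n_unbind, 1e4)
  observed_rate <- tr$n_unbind / (n_les * n_steps)
  expect_equal(observed_rate, 1 / lifetime, tolerance = 0.05)
})

test_that("engine states equal the rule-by-rule reference interpreter", {
  # small chains, all modes, several seeds: identical RNG stream usage makes
  # the optimized engine and the plain interpreter agree state-for-state
  cases <- expand.grid(mode = c("none", "blocking", "anchoring"),
                       n_les = c(1, 3), seed = c(1, 2, 3),
                       stringsAsFactors = FALSE)
  spec <- chromosome_spec(50, centromere_positions = c(12L, 30L))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    params <- extrusion_params(cs$n_les, lifetime = 20, mode = cs$mode,
                               n_steps = 200, seed = cs$seed)
    tr <- run_extrusion(spec, params, sample_every = 1)
    ref <- ref_extrusion(spec, params, sample_every = 1)
    expect_equal(unname(tr$left), unname(ref_states_matrix(ref, "left")),
                 info = paste(cs$mode, cs$n_les, cs$seed))
    expect_equal(unname(tr$right), unname(ref_states_matrix(ref, "right")),
                 info = paste(cs$mode, cs$n_les, cs$seed))
  }
})

test_that("runs are reproducible under a fixed seed", {
  spec <- holocentric_spec(300, 6, seed = 9)
  p <- extrusion_params(20, lifetime = 50, mode = "anchoring",
                        n_steps = 500, seed = 123)
  tr1 <- run_extrusion(spec, p)
  tr2 <- run_extrusion(spec, p)
  expect_identical(tr1$left, tr2$left)
  expect_identical(tr1$right, tr2$right)
})

test_that("bond traces round-trip through TSV", {
  spec <- holocentric_spec(200, 4, seed = 5)
  p <- extrusion_params(10, lifetime = 100, mode = "blocking",
                        n_steps = 300, seed = 8)
  tr <- run_extrusion(spec, p, sample_every = 100)
  path <- tempfile(fileext = ".tsv")
  write_bond_trace(tr, path)
  tr2 <- read_bond_trace(path)
  expect_equal(unname(tr2$left), unname(tr$left))
  expect_equal(unname(tr2$right), unname(tr$right))
  expect_equal(tr2$spec$centromere_positions, spec$centromere_positions)
  expect_equal(tr2$params$mode, "blocking")
  unlink(c(path, paste0(path, ".json")))
})
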