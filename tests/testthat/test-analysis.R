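# Structure analysis: spacing histograms, axial spacing estimators, contact
# maps, contact probability, ordering and groove statistics.

test_that("centromere spacing histogram measures consecutive 3D distances", {
  spec <- chromosome_spec(10, centromere_positions = c(0L, 4L, 9L))
  # 3-4-5 triangle: centromeres at known distances
  coords <- matrix(0, 10, 3)
  coords[5, ] <- c(3, 4, 0)   # site 4
  coords[10, ] <- c(3, 4, 12) # site 9
  h <- centromere_spacing_histogram(conformation(coords), spec)
  expect_equal(sort(h$distances), c(5, 12))

  # collinear uniform gaps give a degenerate histogram
  spec2 <- chromosome_spec(6, centromere_positions = as.integer(0:5))
  coords2 <- cbind(0, 0, seq(0, 35, by = 7))
  h2 <- centromere_spacing_histogram(conformation(coords2), spec2)
  expect_true(all(h2$distances == 7))
  expect_equal(sum(h2$counts > 0), 1L)

  expect_error(
    centromere_spacing_histogram(conformation(coords2),
                                 chromosome_spec(6, 2L)), "at least 2")
})

test_that("axial spacing estimators recover known geometries", {
  # straight axis, 40 axial sites with uniform 10 nm gaps -> 400 nm
  st <- extruder_state(seq(0L, 78L, by = 2L), seq(1L, 79L, by = 2L))
  coords <- cbind(0, 0, 10 * (seq_len(80) - 1))
  rep40 <- axial_spacing(conformation(coords), st)
  expect_equal(rep40$n_axial, 80L)
  expect_equal(rep40$median_distance, 10)
  expect_equal(rep40$chromosome_length_3d, 800)
  expect_equal(abs(rep40$peak_distance - 10) < 0.5, TRUE)

  # median and peak differ on a skewed bimodal distance set
  zpos <- cumsum(c(0, rep(2, 30), rep(10, 10)))
  stb <- extruder_state(seq(0L, 39L), seq(60L, 99L))
  coordsb <- cbind(0, 0, c(zpos, seq(500, by = 5, length.out = 59)))
  repb <- axial_spacing(conformation(coordsb), stb)
  expect_false(isTRUE(all.equal(repb$median_distance, repb$peak_distance)))

  expect_error(axial_spacing(conformation(coords),
                             structure(list(left = integer(),
                                            right = integer()),
                                       class = "extruder_state")), "axial")
})

test_that("contact maps match the brute-force pair count", {
  spec <- chromosome_spec(300, bp_per_nucleosome = 200)
  set.seed(31)
  for (rep in 1:3) {
    coords <- 40 * matrix(rnorm(300 * 3), ncol = 3)
    cm <- contact_map(conformation(coords), spec, region_bp = 300 * 200,
                      bin_bp = 4000, radius = 60)
    ref <- brute_contact_map(coords, 0L, 299L, 20L, 60)
    expect_equal(unname(cm$matrix), ref)
    # symmetry and non-negativity
    expect_true(all(cm$matrix >= 0))
    expect_equal(cm$matrix, t(cm$matrix))
  }

  # all beads at one point: every bin pair in contact
  coords1 <- matrix(0, 100, 3)
  spec1 <- chromosome_spec(100)
  cm1 <- contact_map(conformation(coords1), spec1, region_bp = 100 * 200)
  expect_true(all(cm1$matrix > 0))

  # straight fibre: banded matrix with half-width radius/bond per bin
  specs <- chromosome_spec(400)
  coordss <- cbind(10 * (seq_len(400) - 1), 0, 0)
  cms <- contact_map(conformation(coordss), specs, region_bp = 400 * 200,
                     bin_bp = 4000, radius = 200)
  M <- cms$matrix
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      if (abs(i - j) > 1) expect_equal(M[i, j], 0)
      if (i == j) expect_gt(M[i, j], 0)
    }
  }
})

test_that("contact probability is exact against brute force and bounded", {
  spec <- chromosome_spec(500)
  set.seed(32)
  coords <- 30 * matrix(rnorm(500 * 3), ncol = 3)
  ps <- contact_probability(conformation(coords), spec, s_min = 400,
                            s_max = 500 * 200, radius = 50,
                            bins_per_decade = 4)
  expect_true(all(ps$prob >= 0 & ps$prob <= 1))
  breaks_bp <- 10^seq(log10(400), log10(1e5),
                      length.out = ceiling(log10(250) * 4) + 1)
  ref <- brute_contact_probability(coords, 50, breaks_bp / 200)
  keep <- ref$possible > 0
  expect_equal(ps$contacts, ref$contacts[keep])
  expect_equal(ps$possible, ref$possible[keep])

  # collapsed globule: all probabilities 1
  psg <- contact_probability(conformation(matrix(0, 200, 3)),
                             chromosome_spec(200), s_min = 2 * 200,
                             s_max = 200 * 200, radius = 10)
  expect_true(all(psg$prob == 1))

  # straight fibre: 1 within radius worth of separation, 0 beyond
  coordsf <- cbind(10 * (seq_len(600) - 1), 0, 0)
  psf <- contact_probability(conformation(coordsf), chromosome_spec(600),
                             s_min = 2 * 200, s_max = 500 * 200,
                             radius = 200)
  expect_true(all(psf$prob[psf$s_bp <= 19 * 200] == 1))
  expect_true(all(psf$prob[psf$s_bp > 21 * 200] == 0))

  expect_error(contact_probability(conformation(coordsf),
                                   chromosome_spec(600), s_min = 10,
                                   s_max = 10), "smaller")
})

test_that("centromere ordering detects a linear arrangement", {
  spec <- chromosome_spec(100, centromere_positions = seq(0L, 99L, by = 10L))
  ordered <- cbind(0, 0, seq(0, 990, by = 10))
  expect_equal(centromere_order_fraction(conformation(ordered), spec), 1)
  set.seed(33)
  shuffled <- ordered[sample(100), ]
  expect_lt(centromere_order_fraction(conformation(shuffled), spec), 0.9)
})

test_that("groove statistic is flat on a cylinder and detects depletion", {
  n_beads <- 20000
  spec <- chromosome_spec(n_beads,
                          centromere_positions = seq(0L, n_beads - 1L,
                                                     by = n_beads %/% 10L))
  set.seed(34)
  # centromere line along z, chromatin filling a surrounding cylinder
  theta <- runif(n_beads, -pi, pi)
  zpos <- runif(n_beads, 0, 100)
  rad <- 60 * sqrt(runif(n_beads))
  coords <- cbind(rad * cos(theta), rad * sin(theta), zpos)
  coords[spec$centromere_positions + 1, ] <-
    cbind(0, 0, seq(0, 99, length.out = 10))
  kin <- cbind(c(-5, 5), 10, rep(seq(0, 99, length.out = 10), each = 2))
  confc <- conformation(coords, kinetochore = kin)
  g <- groove_profile(confc, spec)
  # uniform cylinder: no depletion on the kinetochore side
  expect_gt(g$depletion_ratio, 0.6)
  expect_true(all(g$density >= 0))

  # carve out the kinetochore-side (+y) half -> strong depletion
  coords2 <- coords
  chromatin <- setdiff(seq_len(n_beads), spec$centromere_positions + 1)
  coords2[chromatin, 2] <- -abs(coords2[chromatin, 2])
  conf2 <- conformation(coords2, kinetochore = kin)
  g2 <- groove_profile(conf2, spec)
  expect_lt(g2$depletion_ratio, 0.2)

  expect_error(groove_profile(conformation(coords), spec), "kinetochore")
})
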