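test_that("reference dimer geometry has the documented shape", {
  g <- dimer_geometry()
  expect_equal(nrow(g$coords), 7)
  mult <- table(g$roles)
  expect_equal(mult[["CSD"]], 1)
  expect_equal(mult[["CD"]], 2)
  expect_equal(mult[["hinge"]], 2)
  expect_equal(mult[["NTE"]], 2)
  # maximal extent: largest centre-centre distance (CD to opposite NTE) plus
  # one sphere diameter
  expect_equal(dimer_extent(g), sqrt(0.67^2 + 0.65^2) + 0.5, tolerance = 1e-10)
  expect_gte(dimer_extent(g), 1.0)
  expect_lte(dimer_extent(g), 1.5)
})

test_that("geometry is mirror-symmetric about the CSD", {
  g <- dimer_geometry()
  refl <- g$coords
  refl[, 1] <- -refl[, 1]
  # the reflected sphere set coincides with the original, role by role
  for (r in unique(g$roles)) {
    a <- g$coords[g$roles == r, , drop = FALSE]
    b <- refl[g$roles == r, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      d <- sqrt(colSums((t(b) - a[i, ])^2))
      expect_lt(min(d), 1e-12)
    }
  }
})

test_that("geometry validation rejects malformed dimers", {
  g <- dimer_geometry()
  expect_error(dimer_geometry(coords = g$coords[c(1:6, 5), ],
                              roles = g$roles[c(1:6, 5)]),
               "multiplicities")
  big <- g$coords * 3
  expect_error(dimer_geometry(coords = big, roles = g$roles), "extent")
  skew <- g$coords
  skew[2, ] <- skew[2, ] + c(0.05, 0, 0)  # break mirror symmetry
  expect_error(dimer_geometry(coords = skew, roles = g$roles), "symmetric")
})

test_that("principal-frame data reproduce the raw coordinates", {
  g <- dimer_geometry()
  # rotating the principal coordinates back must give the centred originals
  back <- g$pcoords %*% t(g$axes)
  expect_equal(back, unname(sweep(g$coords, 2, g$com)), tolerance = 1e-12)
  expect_true(all(g$inertia > 0))
})

test_that("genomic span maps beads to kbp", {
  expect_identical(genomic_span(1000), 1000)   # 1 Mbp fragment
  expect_identical(genomic_span(1), 1)
  expect_identical(genomic_span(250), 250)
  expect_equal(genomic_span(100, unit_system(kbp_per_bead = 2.5)), 250)
  expect_error(genomic_span(0), "bead count")
})

test_that("initial polymer is a unit-bond self-avoiding walk in the box", {
  st <- build_initial_configuration(system_composition(N = 0, L = 10, lx = 35))
  expect_equal(nrow(st$pol_x), 10)
  bonds <- sqrt(rowSums(diff(st$pol_x)^2))
  expect_true(all(abs(bonds - 1) < 1e-6))
  expect_true(all(st$pol_x > 0 & st$pol_x < 35))
})

test_that("initial configuration is reproducible by seed", {
  a <- build_initial_configuration(system_composition(N = 25, L = 20, lx = 12,
                                                      seed = 5))
  b <- build_initial_configuration(system_composition(N = 25, L = 20, lx = 12,
                                                      seed = 5))
  c <- build_initial_configuration(system_composition(N = 25, L = 20, lx = 12,
                                                      seed = 6))
  expect_identical(a$pol_x, b$pol_x)
  expect_identical(a$dim_x, b$dim_x)
  expect_identical(a$dim_q, b$dim_q)
  expect_false(identical(a$dim_x, c$dim_x))
})

test_that("no distinct-body sphere pair starts below 0.9 contact", {
  st <- build_initial_configuration(system_composition(N = 60, L = 60, lx = 14,
                                                       seed = 2))
  pos <- rbind(st$pol_x, sphere_positions(st))
  rad <- c(rep(0.5, 60), rep(0.25, 60 * 7))
  body <- c(rep(0, 60), rep(seq_len(60), each = 7))
  d <- as.matrix(dist(pos))
  for (i in seq_len(nrow(pos) - 1)) {
    js <- (i + 1):nrow(pos)
    same <- body[i] > 0 & body[js] == body[i]
    # consecutive beads sit at distance 1.0 = contact, allowed
    ratio <- d[i, js] / (rad[i] + rad[js])
    expect_true(all(ratio[!same] >= 0.9 - 1e-9))
  }
})

test_that("impossible packings raise an explicit error", {
  expect_error(
    build_initial_configuration(system_composition(N = 500, L = 0, lx = 4),
                                max_try = 50),
    "packing infeasible")
})

test_that("state invariants hold after construction", {
  st <- tiny_mixed_state()
  expect_true(validate_state(st))
  qn <- sqrt(rowSums(st$dim_q^2))
  expect_true(all(abs(qn - 1) < 1e-9))
})
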