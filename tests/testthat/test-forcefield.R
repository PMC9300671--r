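test_that("WCA potential matches its closed form", {
  w <- wca(2^(1 / 6), d = 1, eps = 1)
  expect_equal(w$energy, 0, tolerance = 1e-12)
  expect_equal(w$force, 0, tolerance = 1e-12)
  expect_equal(wca(1, d = 1, eps = 1)$energy, 1)
  expect_equal(wca(0.75, d = 0.75, eps = 2)$energy, 2)
  # force agrees with a central difference of the energy
  h <- 1e-6
  num <- -(wca(0.9 + h)$energy - wca(0.9 - h)$energy) / (2 * h)
  expect_equal(wca(0.9)$force, num, tolerance = 1e-6)
  expect_error(wca(0), "positive")
})

test_that("FENE bond matches closed form and harmonic limit", {
  expect_equal(fene(0)$energy, 0)
  # harmonic within 1% for small extensions
  for (r in c(0.05, 0.1, 0.16)) {
    expect_equal(fene(r, 30, 1.6)$energy, 0.5 * 30 * r^2,
                 tolerance = 0.01)
  }
  expect_gt(fene(0.999 * 1.6, 30, 1.6)$energy, 100)
  expect_error(fene(1.6), "overstretched")
  expect_error(fene(2), "overstretched")
})

test_that("Kratky-Porod bending matches closed form", {
  expect_equal(kratky_porod(0)$energy, 0)
  expect_equal(kratky_porod(pi, k = 3.7)$energy, 2 * 3.7)
  expect_equal(kratky_porod(pi / 2, k = 2)$energy, 2)
})

test_that("Morse-like attraction is shifted to zero at the cutoff", {
  for (p in list(c(a = 4, r0 = 0.5, rc = 1.0), c(a = 4, r0 = 0.75, rc = 1.1),
                 c(a = 10, r0 = 0.5, rc = 0.65))) {
    # the shift makes the energy vanish continuously at the cutoff: just
    # inside, only the linear slope term delta * |dU/dr| survives
    m <- morse_attraction(p[["rc"]] - 1e-6, 5, p[["a"]], p[["r0"]], p[["rc"]])
    slope <- abs(morse_attraction(p[["rc"]] - 1e-9, 5, p[["a"]], p[["r0"]],
                                  p[["rc"]])$force)
    expect_lt(abs(m$energy), 1e-6 * slope * 1.01 + 1e-10)
    expect_identical(
      unname(morse_attraction(p[["rc"]], 5, p[["a"]], p[["r0"]], p[["rc"]])$energy),
      0)
  }
  # minimum sits at r0, with the depth reduced by the cutoff shift
  f <- function(r) morse_attraction(r, 3, 4, 0.5, 1.0)$energy
  opt <- optimize(f, c(0.2, 0.99))
  expect_equal(opt$minimum, 0.5, tolerance = 1e-4)
  shift <- morse_attraction(0.6, 3, 4, 0.5, 1.0)$shift
  expect_equal(opt$objective, -3 * (1 + shift), tolerance = 1e-8)
  # zero scale gives a null interaction
  expect_equal(morse_attraction(c(0.4, 0.6, 0.9), 0, 4, 0.5, 1.0)$energy,
               rep(0, 3))
})

test_that("wall potential repels inward with the WCA contact value", {
  expect_equal(wall_potential(rbind(c(5, 5, 5)), 10, d = 1)$energy, 0)
  w <- wall_potential(rbind(c(0.5, 5, 5)), 10, d = 1, eps = 1)
  expect_equal(w$energy, 1)          # at distance d/2 from the face
  expect_gt(w$force[1, 1], 0)        # pushes away from the lower x face
  wup <- wall_potential(rbind(c(5, 5, 9.6)), 10, d = 1)
  expect_lt(wup$force[1, 3], 0)      # pushes down from the upper z face
  # inward everywhere near faces
  set.seed(1)
  for (k in 1:20) {
    p <- runif(3, 0.3, 0.55)
    f <- wall_potential(rbind(p), 10, d = 1)$force
    expect_true(all(f[p < 0.561] >= 0))
  }
})

test_that("limited-valence resolution is exclusive and distance-ordered", {
  # one hinge in range of two NTEs: only the nearest binds
  cand <- data.frame(hinge = c(1, 1), nte = c(10, 11), dist = c(0.50, 0.45))
  tab <- resolve_limited_valence(cand)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$nte, 11)
  # a fully bonded dimer (2 hinges + 2 NTEs engaged) admits no fifth partner
  tab4 <- data.frame(hinge = c(1, 2, 31, 41), nte = c(11, 21, 3, 4),
                     dist = rep(0.5, 4))
  cand5 <- data.frame(hinge = 51, nte = 3, dist = 0.4)  # NTE 3 already busy
  out <- resolve_limited_valence(cand5, tab4)
  expect_equal(nrow(out), 4)
  # empty in, empty out
  expect_equal(nrow(resolve_limited_valence(NULL, NULL)), 0)
  # bonds beyond r_off break
  old <- data.frame(hinge = 1, nte = 2, dist = 0.7)
  expect_equal(nrow(resolve_limited_valence(NULL, old)), 0)
})

test_that("isolated dimers beyond all cutoffs feel nothing", {
  st <- build_initial_configuration(system_composition(N = 0, L = 0, lx = 20))
  st$dim_x <- rbind(c(5, 5, 5), c(15, 15, 15))
  st$dim_q <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  st$dim_v <- matrix(0, 2, 3); st$dim_l <- matrix(0, 2, 3)
  spec <- interaction_spec("multivalent", eps_hh = 10, eps_hc = 10)
  f <- total_forces(st, spec)
  expect_equal(max(abs(f$f_dim)), 0)
  expect_equal(max(abs(f$torque_dim)), 0)
  expect_equal(f$u_total, 0)
})

test_that("cell-list forces equal the brute-force pure-R assembly", {
  for (variant in c("multivalent", "limited_valence")) {
    st <- tiny_mixed_state(N = 6, L = 8, lx = 7, seed = 9)
    spec <- interaction_spec(variant, eps_hh = 5, eps_hc = 8)
    # squeeze gently so many pairs interact at physical force magnitudes
    st$dim_x <- 3.5 + (st$dim_x - 3.5) * 0.8
    st$pol_x <- 3.5 + (st$pol_x - 3.5) * 0.8
    fc <- total_forces(st, spec, method = "cell")
    fb <- total_forces(st, spec, method = "brute")
    expect_equal(fc$f_pol, fb$f_pol, tolerance = 1e-12)
    expect_equal(fc$f_dim, fb$f_dim, tolerance = 1e-12)
    # R reference oracle (needs the same bond table for limited valence)
    st$bonds <- fc$bonds
    fr <- reference_forces(st, spec)
    scale <- max(1, max(abs(fr$f_pol)), max(abs(fr$f_dim)))
    expect_lt(max(abs(fc$f_pol - fr$f_pol)) / scale, 1e-10)
    expect_lt(max(abs(fc$f_dim - fr$f_dim)) / scale, 1e-10)
    expect_lt(max(abs(fc$torque_dim - fr$torque_dim)) / scale, 1e-10)
    expect_equal(fc$u_total, fr$u_total, tolerance = 1e-10)
  }
})

test_that("Newton's third law: interior forces sum to zero with PBC", {
  st <- tiny_mixed_state(N = 10, L = 12, lx = 8, seed = 4)
  st$boundary <- "periodic"
  spec <- interaction_spec("multivalent", eps_hh = 4, eps_hc = 4)
  f <- total_forces(st, spec)
  tot <- colSums(f$f_pol) + colSums(f$f_dim)
  expect_lt(max(abs(tot)), 1e-9)
})

test_that("doubling eps_hh exactly doubles the HH energy of a frozen state", {
  st <- tiny_mixed_state(N = 14, L = 0, lx = 7, seed = 8)
  s1 <- interaction_spec("multivalent", eps_hh = 3)
  s2 <- interaction_spec("multivalent", eps_hh = 6)
  u1 <- total_forces(st, s1)$u_terms[["hh"]]
  u2 <- total_forces(st, s2)$u_terms[["hh"]]
  expect_true(u1 < 0)  # some attraction present in a squeezed box
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
})
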