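test_that("composition scaling preserves both number densities", {
  comp <- system_composition()
  sc <- scale_composition(comp, 0.25)
  expect_equal(sc$N, 250L)
  expect_equal(sc$L, 250L)
  expect_equal(sc$lx, 35 * 0.25^(1 / 3))
  expect_lt(abs(sc$N / sc$lx^3 - comp$N / comp$lx^3) / (comp$N / comp$lx^3),
            0.01)
  expect_lt(abs(sc$L / sc$lx^3 - comp$L / comp$lx^3) / (comp$L / comp$lx^3),
            0.01)
  # the sub-box count rescales to keep the mean occupancy fixed
  expect_equal(sub_box_side(sc$N), 3L)
  expect_equal(sub_box_side(comp$N), 5L)
})

test_that("regime classification follows the threshold rules", {
  expect_equal(classify_regime(0.9, 0.8)$label, "absorbing_droplet")
  expect_equal(classify_regime(0.9, 0.1, phi_sep_small_hc = 0.9)$label,
               "dense_droplet")
  expect_equal(classify_regime(0.9, 0.1, phi_sep_small_hc = 0.2)$label,
               "BIPS_droplet")
  expect_equal(classify_regime(0.2, 0.1, baseline = c(0.18, 0.01))$label,
               "mixed")
  expect_equal(classify_regime(0.30, 0.4, baseline = c(0.18, 0.01))$label,
               "coating")
  expect_error(classify_regime(NA, 0.5), "missing")
  # pure function of stored observables: identical calls, identical labels
  a <- classify_regime(0.61, 0.7, baseline = c(0.15, 0.02),
                       phi_sep_small_hc = 0.2)
  b <- classify_regime(0.61, 0.7, baseline = c(0.15, 0.02),
                       phi_sep_small_hc = 0.2)
  expect_identical(a$label, b$label)
})

test_that("crossover interpolation is exact on synthetic logistic data", {
  x <- c(3, 4, 4.5, 5, 6)
  y <- 1 / (1 + exp(-(x - 4.5) / 0.4))
  expect_equal(interpolate_crossover(x, y, 0.5), 4.5, tolerance = 0.05)
  expect_true(is.na(interpolate_crossover(x, y + 10, 0.5)))
})

test_that("non-interacting point is stationary with a small separation depth", {
  ss <- scan_spec(0, 0, comp = system_composition(N = 64, L = 40, lx = 12),
                  run_tau = 16, seeds = c(1, 2), sample_tau = 1)
  pt <- equilibrate_and_measure(0, 0, ss)
  expect_lt(pt$means[["phi_sep_folded"]], 0.45)
  expect_lt(pt$means[["phi_sep"]], 0.35)
  expect_true(pt$stationary[["rg"]])
  expect_true(all(is.finite(pt$means[c("phi_sep", "rg", "f_tot")])))
  # mode fractions are a partition: bound fractions sum to f_tot exactly
  expect_equal(unname(pt$means[["frac_dangling"]] + pt$means[["frac_coating"]] +
                      pt$means[["frac_bridging"]]),
               unname(pt$means[["f_tot"]]), tolerance = 1e-9)
})

test_that("independent seed sets agree within joint errors", {
  comp <- system_composition(N = 64, L = 0, lx = 12)
  m <- lapply(list(c(11, 12), c(21, 22)), function(sds) {
    ss <- scan_spec(0, 0, comp = comp, run_tau = 12, seeds = sds,
                    sample_tau = 1)
    equilibrate_and_measure(0, 0, ss)
  })
  se <- sqrt(sum(vapply(m, function(p) max(p$se[["phi_sep"]], 0.01)^2, 0)))
  expect_lt(abs(m[[1]]$means[["phi_sep"]] - m[[2]]$means[["phi_sep"]]), 3 * se)
})

test_that("a quenched start with no equilibration trips the stationarity flag", {
  ss <- scan_spec(9, 0, comp = system_composition(N = 80, L = 0, lx = 13),
                  run_tau = 40, seeds = 1, sample_tau = 1, equil_frac = 0)
  pt <- equilibrate_and_measure(9, 0, ss)
  expect_false(pt$stationary[["phi_sep"]])
})

test_that("a zero-duration ramp is rejected", {
  expect_error(hysteresis_ramp(0, c(0, 2), ramp_tau = 0), "ramp too fast")
})

test_that("the hysteresis area vanishes in the reversible limit", {
  ss <- scan_spec(0, 0, comp = system_composition(N = 48, L = 32, lx = 11),
                  run_tau = 10, seeds = c(1, 2), sample_tau = 0.5)
  hr <- hysteresis_ramp(0, c(0, 2), ramp_tau = 15, ss = ss, equil_tau = 3)
  # no cooperativity: up and down traces coincide within noise
  expect_lt(abs(hr$area), 0.1 * diff(range(hr$eps_hc_range)))
  expect_true(all(c("up", "down") %in% hr$traces$leg))
})

test_that("condensed starts assemble a legal dense ball", {
  comp <- system_composition(N = 60, L = 40, lx = 14, seed = 5)
  st <- condensed_start(comp)
  d <- sqrt(rowSums(sweep(st$dim_x, 2, rep(7, 3))^2))
  r_expect <- (3 * 60 / (4 * pi * 0.4))^(1 / 3)
  expect_lte(max(d), r_expect + 0.5)
  # overlap-free against beads and other dimers
  sp <- sphere_positions(st)
  p <- bipsim:::cpp_pairs_within(sp, matrix(0, 0, 3), 0.9 * 0.5 - 1e-9, 14, FALSE)
  same <- (p$i - 1) %/% 7 == (p$j - 1) %/% 7
  expect_true(all(same))
  pb <- bipsim:::cpp_pairs_within(sp, st$pol_x, 0.9 * 0.75 - 1e-9, 14, FALSE)
  expect_equal(length(pb$i), 0)
})
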