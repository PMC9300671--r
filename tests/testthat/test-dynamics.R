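test_that("NVE dynamics of a single FENE bond conserves energy", {
  st <- build_initial_configuration(system_composition(N = 0, L = 2, lx = 20))
  st$pol_x <- rbind(c(10, 10, 10), c(10.98, 10, 10))  # slightly off-minimum
  st$pol_v <- matrix(0, 2, 3)
  spec <- interaction_spec("multivalent")
  res <- run_dynamics(st, spec, langevin_params(gamma = 0),
                      n_steps = 1e5, sample_every = 1000)
  e_tot <- res$series$u_total + res$series$ke_trans
  expect_lt(max(abs(e_tot - e_tot[1])), 1e-4)
})

test_that("rigid dimers stay rigid under strong forces", {
  st <- tiny_mixed_state(N = 8, L = 0, lx = 6, seed = 3)
  spec <- interaction_spec("multivalent", eps_hh = 10)
  res <- run_dynamics(st, spec, langevin_params(seed = 3), n_steps = 1e4)
  g <- dimer_geometry()
  ref <- as.matrix(dist(g$pcoords))
  sp <- sphere_positions(res$state, g)
  for (d in 1:8) {
    dd <- as.matrix(dist(sp[(d - 1) * 7 + 1:7, ]))
    expect_lt(max(abs(dd - ref)), 1e-6)
  }
  # quaternions stay normalised
  expect_lt(max(abs(sqrt(rowSums(res$state$dim_q^2)) - 1)), 1e-9)
})

test_that("thermostat satisfies equipartition for translation and rotation", {
  st <- build_initial_configuration(system_composition(N = 250, L = 0, lx = 30,
                                                       seed = 7))
  spec <- interaction_spec("multivalent")
  res <- run_dynamics(st, spec, langevin_params(seed = 7), n_steps = 2e4,
                      sample_every = 200)
  s <- res$series[res$series$time > 4, ]
  ke_tr <- mean(s$ke_trans) / (3 * 250)
  ke_rot <- mean(s$ke_rot) / (3 * 250)
  expect_equal(ke_tr, 0.5, tolerance = 0.02)
  expect_equal(ke_rot, 0.5, tolerance = 0.02)
  # total per particle = 3 kT (6 dof)
  expect_equal(mean(s$ke_trans + s$ke_rot) / 250, 3, tolerance = 0.02)
})

test_that("free-particle diffusion obeys the Einstein relation", {
  # dilute dimers, gamma = 1 => D = kT/gamma = 1 for centre-of-mass motion;
  # the MSD slope is measured beyond the inertial crossover (m/gamma = 1 tau)
  st <- build_initial_configuration(system_composition(N = 50, L = 0, lx = 90,
                                                       seed = 11))
  spec <- interaction_spec("multivalent")
  res <- run_dynamics(st, spec, langevin_params(seed = 11), n_steps = 2.5e5,
                      sample_every = 1000)
  pos <- lapply(res$frames, function(f) f$dim_x)
  times <- vapply(res$frames, function(f) f$time, 0)
  dt_f <- times[2] - times[1]                 # 1 tau per frame
  lags <- 4:12                                # 4..12 tau
  msd <- sapply(lags, function(lag) {
    o <- seq(1, length(pos) - lag, by = 3)
    mean(vapply(o, function(k) {
      keep <- rowSums(pos[[k]] > 10 & pos[[k]] < 80) == 3
      mean(rowSums((pos[[k + lag]][keep, , drop = FALSE] -
                    pos[[k]][keep, , drop = FALSE])^2))
    }, 0))
  })
  slope <- unname(coef(lm(msd ~ I(lags * dt_f)))[2])
  expect_equal(slope, 6, tolerance = 0.05)    # 6 D with D = kT/gamma = 1
})

test_that("neighbour search equals brute force and handles empty systems", {
  st <- tiny_mixed_state(N = 10, L = 15, lx = 8, seed = 6)
  np <- neighbor_pairs(st, cutoff = 1.2)
  pos <- rbind(st$pol_x, sphere_positions(st))
  d <- as.matrix(dist(pos))
  body <- c(rep(0, 15), rep(seq_len(10), each = 7))
  want <- 0L
  for (i in seq_len(nrow(pos) - 1))
    for (j in (i + 1):nrow(pos)) {
      if (body[i] > 0 && body[i] == body[j]) next
      if (d[i, j] <= 1.2) {
        want <- want + 1L
        expect_true(any(np$i == i & np$j == j))
      }
    }
  expect_equal(nrow(np), want)
  empty <- build_initial_configuration(system_composition(N = 0, L = 0, lx = 5))
  expect_equal(nrow(neighbor_pairs(empty, 1.2)), 0)
})

test_that("skin = 0 and skin = 0.3 produce bitwise-identical trajectories", {
  st <- tiny_mixed_state(N = 8, L = 10, lx = 7, seed = 2)
  spec <- interaction_spec("multivalent", eps_hh = 4, eps_hc = 4)
  a <- run_dynamics(st, spec, langevin_params(skin = 0, seed = 2), n_steps = 100)
  b <- run_dynamics(st, spec, langevin_params(skin = 0.3, seed = 2), n_steps = 100)
  expect_identical(a$state$pol_x, b$state$pol_x)
  expect_identical(a$state$dim_x, b$state$dim_x)
  expect_identical(a$state$dim_q, b$state$dim_q)
})

test_that("checkpoint restart continues the trajectory exactly", {
  st <- tiny_mixed_state(N = 8, L = 10, lx = 7, seed = 12)
  spec <- interaction_spec("limited_valence", eps_hh = 8, eps_hc = 6)
  p <- langevin_params(seed = 12)
  full <- run_dynamics(st, spec, p, n_steps = 400)
  half <- run_dynamics(st, spec, p, n_steps = 200)
  ck <- file.path(tempdir(), "restart.chk")
  write_checkpoint(half$state, ck, rng_state = half$rng_state)
  re <- read_checkpoint(ck)
  cont <- run_dynamics(re, spec, p, n_steps = 200,
                       rng_state = attr(re, "rng_state"))
  expect_identical(full$state$pol_x, cont$state$pol_x)
  expect_identical(full$state$dim_x, cont$state$dim_x)
  expect_identical(full$state$dim_q, cont$state$dim_q)
  expect_identical(full$state$bonds, cont$state$bonds)
})

test_that("deterministic dynamics retrace after velocity reversal", {
  st <- build_initial_configuration(system_composition(N = 0, L = 20, lx = 12,
                                                       seed = 5))
  spec <- interaction_spec("multivalent")
  fwd <- run_dynamics(st, spec, langevin_params(gamma = 0), n_steps = 100)
  flip <- fwd$state
  flip$pol_v <- -flip$pol_v
  back <- run_dynamics(flip, spec, langevin_params(gamma = 0), n_steps = 100)
  expect_lt(max(abs(back$state$pol_x - st$pol_x)), 1e-6)
})

test_that("zero steps leave the state unchanged", {
  st <- tiny_mixed_state(N = 5, L = 5, lx = 7)
  spec <- interaction_spec("multivalent")
  res <- run_dynamics(st, spec, langevin_params(), n_steps = 0)
  expect_identical(res$state$pol_x, st$pol_x)
  expect_identical(res$state$dim_x, st$dim_x)
})

test_that("a reckless timestep aborts with an explicit diagnosis", {
  st <- build_initial_configuration(system_composition(N = 0, L = 30, lx = 10,
                                                       seed = 1))
  spec <- interaction_spec("multivalent")
  expect_error(
    run_dynamics(st, spec, langevin_params(dt = 0.1, seed = 1), n_steps = 5000),
    "overstretched|blow-up")
})

test_that("a free chain shows the worm-like-chain persistence length", {
  # K_bend = 3.7 kT gives a tangent decorrelation length of about 3.7 sigma;
  # estimated from the per-bond angle statistics, which equilibrate within a
  # few tau (the discrete-chain relation is l_p = -1 / log<cos theta>)
  st <- build_initial_configuration(system_composition(N = 0, L = 100, lx = 60,
                                                       seed = 13))
  spec <- interaction_spec("multivalent")
  res <- run_dynamics(st, spec, langevin_params(seed = 13), n_steps = 1.2e5,
                      sample_every = 2000)
  frames <- res$frames[vapply(res$frames, function(f) f$time, 0) > 20]
  cth <- vapply(frames, function(f) {
    b <- diff(f$pol_x)
    b <- b / sqrt(rowSums(b^2))
    mean(rowSums(b[-nrow(b), ] * b[-1, ]))
  }, 0)
  lp <- -1 / log(mean(cth))
  expect_equal(lp, 3.7, tolerance = 0.15)
  # and the per-angle average agrees with the Boltzmann prediction for the
  # Kratky-Porod energy: <cos> = coth(K) - 1/K
  expect_equal(mean(cth), 1 / tanh(3.7) - 1 / 3.7, tolerance = 0.02)
})
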