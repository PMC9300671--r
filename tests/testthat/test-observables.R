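test_that("separation depth is exact in the fully separated and uniform limits", {
  v_sb <- 10
  # half the boxes at the dense reference, half empty; rho = mean density
  counts <- c(rep(5, 4), rep(0, 4))           # rho_i = 0.5 or 0
  rho <- sum(counts) / (8 * v_sb)
  for (conv in c("split", "folded", "signed"))
    expect_equal(separation_depth(counts, conv, v_sb = v_sb, rho = rho), 1)
  # perfectly uniform
  uni <- rep(3, 27)
  for (conv in c("split", "folded", "signed"))
    expect_equal(separation_depth(uni, conv, v_sb = v_sb,
                                  rho = 3 / v_sb), 0)
})

test_that("separation depth baselines match the Poisson oracle", {
  # Monte-Carlo oracle: independent Poisson(8) counts per sub-box at the
  # production geometry (v_sb = (35/5)^3, rho+ = 0.5)
  set.seed(42)
  v_sb <- 343
  m <- matrix(rpois(1e4 * 125, 8), 1e4, 125)
  phi_folded <- apply(m, 1, function(x)
    separation_depth(x, "folded", v_sb = v_sb, rho = mean(x) / v_sb))
  expect_equal(mean(phi_folded), sqrt(2 / (pi * 8)), tolerance = 0.02 / 0.28)
  # the split convention gives the ideal-mixture baseline near 0.15
  phi_split <- apply(m[1:2000, ], 1, function(x)
    separation_depth(x, "split", v_sb = v_sb, rho = mean(x) / v_sb))
  expect_equal(mean(phi_split), 0.148, tolerance = 0.01 / 0.148)
  # signed terms cancel in a uniform phase
  phi_signed <- apply(m[1:2000, ], 1, function(x)
    separation_depth(x, "signed", v_sb = v_sb, rho = mean(x) / v_sb))
  expect_lt(abs(mean(phi_signed)), 1e-10)
})

test_that("sub-box grid counts every dimer once by its CSD centre", {
  st <- generate_fixture("uniform_gas", n = 200, lx = 20, seed = 3)
  g <- sub_box_grid(st, n_side = 4)
  expect_equal(sum(g$n_i), 200)
  expect_equal(length(g$n_i), 64)
  expect_equal(g$rho, 200 / 20^3)
  # translation by one sub-box edge (with wrap) leaves folded phi unchanged
  st2 <- st
  st2$dim_x <- (st2$dim_x + 5) %% 20
  expect_equal(separation_depth(sub_box_grid(st2, n_side = 4), "folded"),
               separation_depth(g, "folded"), tolerance = 1e-10)
  expect_equal(sub_box_side(1000), 5L)
  expect_equal(sub_box_side(250), 3L)
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(2, 5, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  chain <- generate_fixture("straight_chain", n = 1000)
  expect_equal(radius_of_gyration(chain), sqrt((1000^2 - 1) / 12),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(chain), sqrt(999999 / 12), tolerance = 1e-9)
})

test_that("binding modes follow the bead-separation rules", {
  spec <- interaction_spec("multivalent", eps_hc = 4)
  coated <- generate_fixture("coated_polymer", n = 40)
  bm <- classify_binding_modes(coated, spec)
  expect_equal(unname(bm$fractions[["coating"]]), 1)
  expect_equal(bm$f_tot, 1)
  expect_equal(bm$f_c, 1)
  expect_equal(sum(bm$fractions), 1)

  # dangling: one CD in contact, the other far away.  With the body frame
  # aligned to the world axes the CDs sit 0.45 sigma either side of the CSD,
  # so shifting the dimer 1.3 sigma along x leaves only the near CD in range
  st <- coated
  st$pol_x <- rbind(c(5, 10, 10))
  st$polymer <- polymer_spec(L = 1)
  g <- dimer_geometry()
  csd <- g$coords[which(g$role_code == 1)[1], ]
  st$dim_x <- rbind(c(5, 10, 10) + c(1.3, 0, 0) + (g$com - csd))
  st$dim_q <- rbind(bipsim:::identity_quaternion(g))
  cd <- sphere_positions(st, g)[which(g$role_code == 2), ]
  d <- sqrt(rowSums(sweep(cd, 2, c(5, 10, 10))^2))
  expect_true(xor(d[1] <= spec$rc_hc, d[2] <= spec$rc_hc))
  bm1 <- classify_binding_modes(st, spec)
  expect_equal(unname(bm1$counts[["dangling"]]), 1)

  # bridging: CDs contact beads 5 and 9 of a folded chain
  st2 <- coated
  st2$pol_x <- matrix(c(seq(2, 11), rep(10, 10), rep(10, 10)), 10, 3)
  st2$pol_x[9, ] <- st2$pol_x[5, ] + c(0.9, 0, 0)  # bead 9 folded next to 5
  st2$polymer <- polymer_spec(L = 10)
  ctr <- (st2$pol_x[5, ] + st2$pol_x[9, ]) / 2
  st2$dim_x <- rbind(ctr + c(0, 0.8, 0) + (g$com - g$coords[1, ]))
  st2$dim_q <- rbind(bipsim:::identity_quaternion(g))
  bm2 <- classify_binding_modes(st2, spec)
  expect_equal(unname(bm2$counts[["bridging"]]), 1)

  # coating is |i - j| < 2, bridging |i - j| >= 2: adjacent beads coat
  st3 <- st2
  st3$pol_x[9, ] <- c(50, 50, 50)
  st3$pol_x[6, ] <- st3$pol_x[5, ] + c(0.9, 0, 0)
  bm3 <- classify_binding_modes(st3, spec)
  expect_equal(unname(bm3$counts[["coating"]]), 1)
})

test_that("binding modes are invariant to CD relabelling", {
  spec <- interaction_spec("multivalent", eps_hc = 4)
  g <- dimer_geometry()
  swap <- order(c(1, 2, 3, 5, 4, 6, 7))  # exchange the two CD rows
  g2 <- dimer_geometry(coords = g$coords[swap, ], roles = g$roles[swap])
  st <- generate_fixture("coated_polymer", n = 25)
  a <- classify_binding_modes(st, spec, geom = g)
  b <- classify_binding_modes(st, spec, geom = g2)
  expect_equal(a$counts, b$counts)
})

test_that("bond correlation normalises to 1 and handles degenerate input", {
  tg <- generate_fixture("telegraph_bonds", n = 200, frames = 400, seed = 2)
  nu <- bond_correlation(tg, lags = 0:20)
  expect_equal(nu$nu[1], 1, tolerance = 1e-12)
  # frozen mixed pattern: some pairs always on, others always off
  frozen <- bond_event_series(matrix(rep(c(TRUE, FALSE), each = 50 * 10), 10),
                              interval = 1, n_dimers = 100)
  nuf <- bond_correlation(frozen, lags = 0:5)
  expect_true(all(abs(nuf$nu - 1) < 1e-12))
  # all-off series has zero variance
  dead <- bond_event_series(matrix(FALSE, 10, 4), interval = 1)
  expect_error(bond_correlation(dead), "degenerate")
})

test_that("telegraph bonds decay as the two-state Markov autocovariance", {
  k <- 0.01
  tg <- generate_fixture("telegraph_bonds", n = 1000, frames = 10000,
                         k_on = k, k_off = k, interval = 1, seed = 7)
  lags <- c(0, 10, 25, 50, 100)
  nu <- bond_correlation(tg, lags = lags)
  expect_true(all(abs(nu$nu - exp(-2 * k * nu$dt)) < 0.03))
})

test_that("pair-centred pooling equals the variance-weighted average", {
  set.seed(9)
  y <- matrix(runif(50 * 8) < rep(runif(8, 0.2, 0.8), each = 50), 50, 8)
  s <- bond_event_series(y, interval = 1)
  lags <- 0:10
  nu <- bond_correlation(s, lags = lags, center = "pair")
  manual <- sapply(lags, function(lag) {
    cps <- sapply(seq_len(ncol(y)), function(p) {
      v <- y[, p]
      mu <- mean(v)
      idx <- seq_len(length(v) - lag)
      mean(v[idx] & v[idx + lag]) - mu^2
    })
    vars <- apply(y, 2, function(v) mean(v) - mean(v)^2)
    sum(cps) / sum(vars)
  })
  expect_equal(nu$nu, manual, tolerance = 1e-12)
})

test_that("decorrelation-time fits recover known timescales", {
  dt_grid <- seq(0, 250, by = 2)
  nu <- data.frame(lag = dt_grid, dt = dt_grid, nu = exp(-dt_grid / 50))
  fit <- fit_decorrelation_time(nu)
  expect_equal(fit$tau_hh, 50, tolerance = 0.01)
  expect_equal(fit$beta, 1, tolerance = 0.05)
  # telegraph oracle: tau = 1/(2k)
  tg <- generate_fixture("telegraph_bonds", n = 800, frames = 8000,
                         k_on = 0.01, k_off = 0.01, seed = 3)
  nutg <- bond_correlation(tg, lags = seq(0, 250, by = 5))
  ftg <- fit_decorrelation_time(nutg)
  expect_equal(ftg$tau_hh, 50, tolerance = 0.10)
  expect_true(ftg$reliable)
  flat <- data.frame(lag = 0:20, dt = 0:20, nu = rep(1, 21))
  expect_error(fit_decorrelation_time(flat), "no decorrelation")
})

test_that("cluster detection matches a union-find oracle", {
  spec <- interaction_spec("multivalent", eps_hh = 4)
  # far-apart dimers are all singletons
  gas <- generate_fixture("uniform_gas", n = 40, lx = 60, seed = 5)
  cl <- detect_clusters(gas, spec)
  if (length(cl$sizes) == 40) expect_true(all(cl$sizes == 1))
  # hand-built chain A-B-C: A and C linked only through B
  st <- gas
  st$dim_x <- rbind(c(10, 10, 10), c(10.9, 10, 10), c(11.8, 10, 10),
                    c(40, 40, 40))
  st$dim_q <- matrix(rep(c(1, 0, 0, 0), 4), 4, 4, byrow = TRUE)
  cl3 <- detect_clusters(st, spec)
  expect_equal(sort(cl3$sizes, decreasing = TRUE), c(3, 1))
  # random configuration versus pure-R union-find over the same link set
  st2 <- generate_fixture("uniform_gas", n = 60, lx = 12, seed = 8)
  cl2 <- detect_clusters(st2, spec)
  g <- dimer_geometry()
  sp <- sphere_positions(st2, g)
  edges <- matrix(0L, 0, 2)
  link_cut <- max(spec$rc_hh, 1.05 * 0.5)
  d <- as.matrix(dist(sp))
  role <- rep(g$role_code, 60)
  dimer <- rep(1:60, each = 7)
  for (i in seq_len(nrow(sp) - 1)) for (j in (i + 1):nrow(sp)) {
    if (dimer[i] == dimer[j]) next
    hn <- (role[i] == 3 && role[j] == 4) || (role[i] == 4 && role[j] == 3)
    if (d[i, j] <= 1.05 * 0.5 || (hn && d[i, j] <= spec$rc_hh))
      edges <- rbind(edges, c(dimer[i], dimer[j]))
  }
  oracle <- uf_components(60, edges)
  expect_equal(canon_partition(cl2$membership), canon_partition(oracle))
})

test_that("droplet statistics recover synthetic constructions", {
  spec <- interaction_spec("multivalent", eps_hh = 4)
  ball <- generate_fixture("dense_ball", n = 500, radius = 5, lx = 35, seed = 1)
  ds <- droplet_stats(ball, spec = spec)
  expect_gte(ds$droplet_size, 495)  # a surface straggler may sit unlinked
  expect_equal(ds$r_d, 5, tolerance = 0.02)
  expect_equal(ds$rho_hd, sum(ds$inside) / (4 / 3 * pi * ds$r_d^3),
               tolerance = 1e-9)
  expect_equal(ds$rho_hd, 500 / (4 / 3 * pi * 125), tolerance = 0.05)
  expect_gt(ds$rho_hd, ds$rho_ld)

  two <- generate_fixture("two_balls", n = 400, n2 = 100, radius = 5,
                          sep = 18, lx = 35, seed = 2)
  ds2 <- droplet_stats(two, spec = spec)
  expect_gte(ds2$droplet_size, 390)
  expect_lte(ds2$droplet_size, 400)
  expect_lt(abs(ds2$centroid[1] - (35 / 2 - 9)), 1)

  # no-droplet limit: whole uniform box designated as one cluster
  gas <- generate_fixture("uniform_gas", n = 400, lx = 20, seed = 3)
  fake <- structure(list(membership = rep(1L, 400), sizes = 400L,
                         largest = 1L, n = 400L), class = "cluster_set")
  ds3 <- droplet_stats(gas, clusters = fake, spec = spec)
  rho <- 400 / 20^3
  expect_equal(ds3$rho_hd, rho, tolerance = 0.35)
  expect_equal(ds3$rho_ld, rho, tolerance = 0.35)
  expect_error(droplet_stats(generate_fixture("uniform_gas", n = 0)), "empty|no dimers")
})

test_that("droplet radius scales as N^(1/3) at fixed density", {
  ns <- c(100, 200, 400, 800, 1600, 3200)
  rho0 <- 0.5
  rd <- vapply(seq_along(ns), function(k) {
    r <- (3 * ns[k] / (4 * pi * rho0))^(1 / 3)
    ball <- generate_fixture("dense_ball", n = ns[k], radius = r, lx = 40,
                             seed = k)
    droplet_stats(ball, clusters = structure(
      list(membership = rep(1L, ns[k]), sizes = ns[k], largest = 1L,
           n = ns[k]), class = "cluster_set"))$r_d
  }, 0)
  fit <- lm(log(rd) ~ log(ns))
  expect_equal(unname(coef(fit)[2]), 1 / 3, tolerance = 0.01 / (1 / 3))
})

test_that("fractal dimension distinguishes solids, discs and lines", {
  ball <- generate_fixture("dense_ball", n = 4000, radius = 8, lx = 40, seed = 4)
  expect_equal(fractal_dimension(ball$dim_x)$d_f, 3, tolerance = 0.15 / 3)
  line <- cbind(seq(0, 120, by = 0.5), 0, 0)
  expect_equal(fractal_dimension(line)$d_f, 1, tolerance = 0.15)
  set.seed(6)
  th <- 2 * pi * runif(3000); rr <- 10 * sqrt(runif(3000))
  disc <- cbind(rr * cos(th), rr * sin(th), 0)
  expect_equal(fractal_dimension(disc)$d_f, 2, tolerance = 0.2 / 2)
  expect_error(fractal_dimension(matrix(0, 10, 3)), "insufficient mass")
})

test_that("mixing index runs from demixed to fully mixed", {
  spec <- interaction_spec("multivalent", eps_hh = 4)
  ball <- generate_fixture("dense_ball", n = 400, radius = 5, lx = 35, seed = 5)
  ds <- droplet_stats(ball, spec = spec)
  halves <- assign_droplet_halves(ds, ball)
  # at t0 the index vanishes up to plane-edge reassignments when the
  # centroid is recomputed from the labelled subset
  expect_lt(mixing_index(ball, halves, spec), 0.02)
  # swap exactly 25% of each half: index 0.5 by the combinatorial count
  lab <- halves$labels
  a <- which(lab == "A"); b <- which(lab == "B")
  na <- length(a); nb <- length(b)
  swapped <- halves
  swapped$labels[a[seq_len(round(na / 4))]] <- "B"
  swapped$labels[b[seq_len(round(nb / 4))]] <- "A"
  expect_equal(mixing_index(ball, swapped, spec), 0.5, tolerance = 0.05)
  # random labels: fully mixed
  set.seed(8)
  shuf <- halves
  shuf$labels[!is.na(lab)] <- sample(lab[!is.na(lab)])
  expect_gt(mixing_index(ball, shuf, spec), 0.85)
  none <- halves; none$labels[] <- NA
  expect_error(mixing_index(ball, none, spec), "droplet absent")
})

test_that("residence times are censored run-length means", {
  y <- as.logical(as.integer(strsplit("00111001110", "")[[1]]))
  expect_equal(residence_time(y, interval = 1), 3)
  expect_equal(residence_time(y, interval = 0.5), 1.5)
  expect_error(residence_time(rep(FALSE, 20)), "no binding")
  # events touching the window edges are censored away
  expect_error(residence_time(rep(TRUE, 20)), "no binding")
  # two-state Markov oracle: mean on-time 1/k_off = 20 tau
  tg <- generate_fixture("telegraph_bonds", n = 300, frames = 4000,
                         k_on = 0.02, k_off = 0.05, interval = 1, seed = 4)
  expect_equal(residence_time(tg), 1 / 0.05, tolerance = 0.10)
})
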