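# Experiment protocols: seeded, reproducible pipelines over the simulator,
# with regime classification in the (eps_hh, eps_hc) plane.

#' Scan specification
#'
#' @param eps_hh,eps_hc numeric vectors: the interaction-energy grid (k_B T).
#' @param variant interaction variant for all points.
#' @param comp a [system_composition()] template (per-seed compositions get
#'   distinct seeds).
#' @param run_tau production run length per point (tau).  The publication
#'   convention is at least 5000 tau; scaled-down values are accepted for
#'   desk-scale work.
#' @param equil_frac fraction of the run discarded as equilibration.
#' @param seeds integer vector of independent replicate seeds (>= 4 for
#'   production).
#' @param sample_tau sampling interval (tau).
#' @param dt integrator timestep.
#' @return an object of class `scan_spec`.
#' @export
scan_spec <- function(eps_hh, eps_hc, variant = "multivalent",
                      comp = system_composition(), run_tau = 5000,
                      equil_frac = 0.5, seeds = 1:4, sample_tau = 5,
                      dt = 0.001) {
  stopifnot(run_tau > 0, equil_frac >= 0, equil_frac < 1, length(seeds) >= 1)
  structure(list(eps_hh = eps_hh, eps_hc = eps_hc, variant = variant,
                 comp = comp, run_tau = run_tau, equil_frac = equil_frac,
                 seeds = seeds, sample_tau = sample_tau, dt = dt),
            class = "scan_spec")
}

#' Scale a system composition preserving densities
#'
#' Scales protein and bead counts by `factor` and the box volume by the same
#' factor, so both number densities are preserved; the sub-box count for the
#' separation depth is rescaled via [sub_box_side()] to keep the mean
#' occupancy fixed.
#'
#' @param comp a [system_composition()].
#' @param factor scale factor (e.g. 0.25).
#' @param tol relative density mismatch tolerated after integer rounding.
#' @return a scaled `system_composition`.
#' @export
scale_composition <- function(comp, factor, tol = 0.02) {
  n2 <- as.integer(round(comp$N * factor))
  l2 <- as.integer(round(comp$L * factor))
  lx2 <- comp$lx * factor^(1 / 3)
  out <- system_composition(N = n2, L = l2, lx = lx2,
                            boundary = comp$boundary, seed = comp$seed)
  for (nm in c("N", "L")) {
    if (comp[[nm]] > 0) {
      rel <- abs(out[[nm]] / lx2^3 - comp[[nm]] / comp$lx^3) /
        (comp[[nm]] / comp$lx^3)
      if (rel > tol)
        stop(sprintf("scaled composition changes the %s density by %.1f%%",
                     nm, 100 * rel))
    }
  }
  out
}

#' Condensed (phase-separated) initial configuration
#'
#' Builds an initial state whose proteins are pre-assembled into a single
#' dense ball at the box centre, with the polymer grown around it as usual.
#' Used to measure points deep inside a two-phase region: relaxing from the
#' separated configuration converges to the coexistence state far faster
#' than coarsening from a gas, and if the droplet phase is not stable at the
#' chosen energies the ball simply evaporates.
#'
#' @param comp a [system_composition()].
#' @param geom a `dimer_geometry`.
#' @param rho_ball target protein number density of the ball (dimers /
#'   sigma^3; default 0.4).
#' @param max_try rejection-sampling budget per dimer.
#' @return a `system_state`.
#' @export
condensed_start <- function(comp, geom = dimer_geometry(), rho_ball = 0.4,
                            max_try = 4000) {
  st <- build_initial_configuration(comp, geom = geom)
  n <- comp$N
  if (n == 0) return(st)
  radius <- (3 * n / (4 * pi * rho_ball))^(1 / 3)
  if (2 * radius > comp$lx - 2)
    stop("packing infeasible: condensed ball larger than the box")
  ctr <- rep(comp$lx / 2, 3)
  with_seed(comp$seed + 104729L, {
    placed <- matrix(NA_real_, 0, 3)    # accepted sphere centres
    beads <- st$pol_x
    for (d in seq_len(n)) {
      ok <- FALSE
      for (t in seq_len(max_try)) {
        u <- runif(1)^(1 / 3) * radius
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        com <- ctr + u * v
        q <- random_quaternion(1)
        sph <- cpp_sphere_positions(rbind(com), q, geom$pcoords)
        if (nrow(placed) > 0) {
          p <- cpp_pairs_within(sph, placed, 0.9 * geom$sphere_diameter,
                                comp$lx, FALSE)
          if (length(p$i) > 0) next
        }
        if (nrow(beads) > 0) {
          pb <- cpp_pairs_within(sph, beads,
                                 0.9 * (0.5 + geom$sphere_diameter / 2),
                                 comp$lx, FALSE)
          if (length(pb$i) > 0) next
        }
        st$dim_x[d, ] <- com
        st$dim_q[d, ] <- q
        placed <- rbind(placed, sph)
        ok <- TRUE
        break
      }
      if (!ok) stop("packing infeasible: could not assemble the condensed ball")
    }
  })
  st
}

# per-frame observable rows shared by all protocols
measure_frames <- function(frames, spec, geom, n_side = NULL) {
  rows <- lapply(frames, function(fr) {
    grid <- sub_box_grid(fr, n_side = n_side, geom = geom)
    bm <- if (nrow(fr$pol_x) > 0 && nrow(fr$dim_x) > 0)
      classify_binding_modes(fr, spec, geom) else NULL
    data.frame(
      time = fr$time,
      phi_sep = separation_depth(grid, "split"),
      phi_sep_folded = separation_depth(grid, "folded"),
      phi_sep_signed = separation_depth(grid, "signed"),
      rg = if (nrow(fr$pol_x) > 0) radius_of_gyration(fr) else NA_real_,
      f_tot = if (!is.null(bm)) bm$f_tot else NA_real_,
      f_c = if (!is.null(bm)) bm$f_c else NA_real_,
      frac_dangling = if (!is.null(bm)) unname(bm$fractions["dangling"]) else NA_real_,
      frac_coating = if (!is.null(bm)) unname(bm$fractions["coating"]) else NA_real_,
      frac_bridging = if (!is.null(bm)) unname(bm$fractions["bridging"]) else NA_real_)
  })
  do.call(rbind, rows)
}

# Mann-Kendall trend guard: TRUE when no monotone trend at the 5% level
is_stationary <- function(x, t) {
  x <- x[is.finite(x)]
  if (length(x) < 8 || sd(x) == 0) return(TRUE)
  ct <- suppressWarnings(cor.test(t[seq_along(x)], x, method = "kendall"))
  is.na(ct$p.value) || ct$p.value >= 0.05
}

#' Equilibrate and measure one parameter point
#'
#' Runs independent seeded replicates at fixed interaction energies, discards
#' the equilibration window, checks stationarity of the separation depth and
#' polymer radius of gyration over the analysis window (Mann-Kendall at the
#' 5% level) and returns means with standard errors over seeds.
#'
#' @param eps_hh,eps_hc interaction energies (k_B T).
#' @param ss a [scan_spec()] carrying composition, run length, seeds.
#' @param geom a `dimer_geometry`.
#' @param init optional list of pre-built initial states (one per seed).
#' @return list of class `point_measurement`: `means`, `se` (named vectors
#'   over the frame observables), `stationary` (named logical), `series`
#'   (per-seed frame rows), `final_states`.
#' @export
equilibrate_and_measure <- function(eps_hh, eps_hc, ss, geom = dimer_geometry(),
                                    init = NULL) {
  spec <- interaction_spec(ss$variant, eps_hh = eps_hh, eps_hc = eps_hc)
  n_steps <- round(ss$run_tau / ss$dt)
  sample_every <- max(1, round(ss$sample_tau / ss$dt))
  n_side <- sub_box_side(ss$comp$N)
  all_rows <- list()
  finals <- list()
  for (k in seq_along(ss$seeds)) {
    sd_k <- ss$seeds[k]
    comp_k <- ss$comp; comp_k$seed <- sd_k
    st <- if (!is.null(init)) init[[k]]
          else build_initial_configuration(comp_k, geom = geom)
    res <- run_dynamics(st, spec, langevin_params(dt = ss$dt, seed = sd_k),
                        n_steps = n_steps, sample_every = sample_every,
                        geom = geom)
    rows <- measure_frames(res$frames, spec, geom, n_side)
    rows$seed <- sd_k
    all_rows[[k]] <- rows
    finals[[k]] <- res$state
  }
  series <- do.call(rbind, all_rows)
  t0 <- min(series$time) + ss$equil_frac * (max(series$time) - min(series$time))
  win <- series[series$time >= t0, , drop = FALSE]
  obs <- c("phi_sep", "phi_sep_folded", "phi_sep_signed", "rg", "f_tot", "f_c",
           "frac_dangling", "frac_coating", "frac_bridging")
  per_seed <- sapply(obs, function(o)
    unname(tapply(win[[o]], win$seed, mean, na.rm = TRUE)))
  if (is.null(dim(per_seed)))
    per_seed <- matrix(per_seed, nrow = 1, dimnames = list(NULL, obs))
  means <- colMeans(per_seed, na.rm = TRUE)
  se <- apply(per_seed, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  stationary <- c(
    phi_sep = all(vapply(split(win, win$seed),
                         function(w) is_stationary(w$phi_sep, w$time), TRUE)),
    rg = all(vapply(split(win, win$seed),
                    function(w) is_stationary(w$rg, w$time), TRUE)))
  structure(list(eps_hh = eps_hh, eps_hc = eps_hc, means = means, se = se,
                 stationary = stationary, series = series,
                 final_states = finals),
            class = "point_measurement")
}

#' @export
print.point_measurement <- function(x, ...) {
  cat(sprintf("point (eps_hh=%g, eps_hc=%g): phi_sep = %.3f +- %.3f, f_tot = %.3f\n",
              x$eps_hh, x$eps_hc, x$means["phi_sep"], x$se["phi_sep"],
              x$means["f_tot"]))
  if (!all(x$stationary)) cat("  [non-stationary flag raised]\n")
  invisible(x)
}

#' Classify the phase-behaviour regime of one point
#'
#' Rules: a droplet is present when phi_sep >= 0.5; an `absorbing_droplet`
#' additionally has f_tot >= 0.5; `coating` is a non-droplet point whose
#' phi_sep exceeds its weak-interaction baseline by more than 3 combined
#' standard errors; a `BIPS_droplet` is a droplet at a point whose
#' small-eps_hc counterpart is not a droplet (the droplet exists only through
#' the chromatin); otherwise `mixed`.
#'
#' @param phi_sep,f_tot point observables (means over seeds).
#' @param baseline optional `c(mean, se)` of phi_sep over weak-interaction
#'   points (for the coating call).
#' @param phi_sep_small_hc optional phi_sep of the same eps_hh at small
#'   eps_hc (for the BIPS call).
#' @param phi_threshold droplet threshold (0.5).
#' @return an object of class `regime_call` with `label` and `supporting`.
#' @export
classify_regime <- function(phi_sep, f_tot, baseline = NULL,
                            phi_sep_small_hc = NA, phi_threshold = 0.5) {
  if (!is.finite(phi_sep)) stop("missing observables: phi_sep")
  droplet <- phi_sep >= phi_threshold
  label <- if (droplet) {
    if (is.finite(f_tot) && f_tot >= 0.5) "absorbing_droplet"
    else if (is.finite(phi_sep_small_hc) && phi_sep_small_hc < phi_threshold)
      "BIPS_droplet"
    else "dense_droplet"
  } else {
    if (!is.null(baseline) &&
        phi_sep > baseline[1] + 3 * max(baseline[2], 1e-12)) "coating"
    else "mixed"
  }
  structure(list(label = label,
                 supporting = c(phi_sep = phi_sep, f_tot = f_tot,
                                phi_sep_small_hc = phi_sep_small_hc)),
            class = "regime_call")
}

#' @export
print.regime_call <- function(x, ...) {
  cat("regime:", x$label, sprintf("(phi_sep = %.3f, f_tot = %.3f)\n",
                                  x$supporting["phi_sep"], x$supporting["f_tot"]))
  invisible(x)
}

#' Linear interpolation of a threshold crossing
#'
#' @param x ordered abscissa (e.g. eps_hh grid).
#' @param y observable values.
#' @param threshold crossing level (default 0.5).
#' @return interpolated x of the first upward crossing, or NA.
#' @export
interpolate_crossover <- function(x, y, threshold = 0.5) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  for (k in seq_len(length(x) - 1)) {
    if ((y[k] < threshold && y[k + 1] >= threshold) ||
        (y[k] > threshold && y[k + 1] <= threshold)) {
      return(x[k] + (threshold - y[k]) * (x[k + 1] - x[k]) / (y[k + 1] - y[k]))
    }
  }
  NA_real_
}

#' Phase scan over an interaction-energy grid
#'
#' Measures every (eps_hh, eps_hc) grid point with
#' [equilibrate_and_measure()], classifies regimes (using the smallest
#' eps_hh row as the coating baseline and the smallest eps_hc column as the
#' BIPS reference) and reports threshold crossovers by linear interpolation.
#'
#' @param ss a [scan_spec()].
#' @param geom a `dimer_geometry`.
#' @return list of class `phase_scan`: `table` (one row per point with
#'   observables and regime label), `points` (the measurements) and
#'   `crossover` (phi_sep = 0.5 crossing along eps_hh for each eps_hc).
#' @export
phase_scan <- function(ss, geom = dimer_geometry()) {
  grid <- expand.grid(eps_hh = ss$eps_hh, eps_hc = ss$eps_hc)
  pts <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    pts[[i]] <- equilibrate_and_measure(grid$eps_hh[i], grid$eps_hc[i], ss, geom)
  tab <- do.call(rbind, lapply(pts, function(p)
    data.frame(eps_hh = p$eps_hh, eps_hc = p$eps_hc,
               phi_sep = unname(p$means["phi_sep"]),
               phi_sep_se = unname(p$se["phi_sep"]),
               f_tot = unname(p$means["f_tot"]),
               stationary = all(p$stationary))))
  min_hh <- min(tab$eps_hh); min_hc <- min(tab$eps_hc)
  base_rows <- tab[tab$eps_hh == min_hh, , drop = FALSE]
  baseline <- c(mean(base_rows$phi_sep),
                max(mean(base_rows$phi_sep_se, na.rm = TRUE),
                    sd(base_rows$phi_sep) / sqrt(nrow(base_rows)), na.rm = TRUE))
  tab$regime <- NA_character_
  for (i in seq_len(nrow(tab))) {
    ref <- tab$phi_sep[tab$eps_hh == tab$eps_hh[i] & tab$eps_hc == min_hc]
    tab$regime[i] <- classify_regime(tab$phi_sep[i], tab$f_tot[i],
                                     baseline = baseline,
                                     phi_sep_small_hc = ref[1])$label
  }
  crossover <- vapply(unique(tab$eps_hc), function(ec) {
    sub <- tab[tab$eps_hc == ec, ]
    interpolate_crossover(sub$eps_hh, sub$phi_sep, 0.5)
  }, 0)
  names(crossover) <- unique(tab$eps_hc)
  structure(list(table = tab, points = pts, crossover = crossover,
                 baseline = baseline),
            class = "phase_scan")
}

#' @export
print.phase_scan <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Protein-density scan
#'
#' Repeats one interaction-energy point for several protein counts and
#' reports droplet densities, droplet radius, polymer radius of gyration and
#' binding-mode fractions, plus the log-log slope of R_d against N.
#'
#' @param n_values protein counts.
#' @param eps_hh,eps_hc interaction energies.
#' @param ss a [scan_spec()] template (its composition supplies L, lx).
#' @param geom a `dimer_geometry`.
#' @return list of class `density_scan`: `table`, `slope` (fit with CI) over
#'   points with a detected droplet.
#' @export
density_scan <- function(n_values, eps_hh, eps_hc, ss, geom = dimer_geometry()) {
  rows <- list()
  for (nv in n_values) {
    ssn <- ss
    ssn$comp$N <- nv
    pt <- equilibrate_and_measure(eps_hh, eps_hc, ssn, geom)
    spec <- interaction_spec(ss$variant, eps_hh = eps_hh, eps_hc = eps_hc)
    ds <- lapply(pt$final_states, function(st)
      droplet_stats(st, spec = spec, geom = geom))
    rows[[length(rows) + 1]] <- data.frame(
      N = nv,
      rho_hd = mean(vapply(ds, function(d) d$rho_hd, 0)),
      rho_ld = mean(vapply(ds, function(d) d$rho_ld, 0)),
      r_d = mean(vapply(ds, function(d) d$r_d, 0)),
      droplet_size = mean(vapply(ds, function(d) d$droplet_size, 0)),
      rg = unname(pt$means["rg"]),
      f_tot = unname(pt$means["f_tot"]),
      frac_bridging = unname(pt$means["frac_bridging"]))
  }
  tab <- do.call(rbind, rows)
  slope <- NULL
  if (nrow(tab) >= 3) {
    fit <- lm(log(r_d) ~ log(N), data = tab)
    ci <- tryCatch(confint(fit)[2, ], error = function(e) c(NA, NA))
    slope <- list(estimate = unname(coef(fit)[2]), ci = ci)
  }
  structure(list(table = tab, slope = slope, eps_hh = eps_hh,
                 eps_hc = eps_hc), class = "density_scan")
}

#' Interaction-energy hysteresis ramp
#'
#' Ramps the protein-chromatin energy linearly from `eps_hc_range[1]` to
#' `eps_hc_range[2]` over `ramp_tau` during integration, then back down over
#' the same interval, sampling the bound fraction continuously.  Reports the
#' up and down traces and the enclosed hysteresis area
#' integral(f_up - f_down) d eps_hc.
#'
#' @param eps_hh fixed protein-protein energy.
#' @param eps_hc_range `c(low, high)` ramp endpoints.
#' @param ramp_tau duration of each ramp leg (tau); must be positive.
#' @param ss a [scan_spec()] (composition, seeds, dt, sampling).
#' @param equil_tau equilibration at the starting point before ramping.
#' @param geom a `dimer_geometry`.
#' @return list of class `hysteresis_ramp`: `traces` (seed, leg, eps_hc,
#'   f_tot, modes) and `area` (mean over seeds).
#' @export
hysteresis_ramp <- function(eps_hh, eps_hc_range = c(8, 14), ramp_tau = 2e4,
                            ss = scan_spec(eps_hh, eps_hc_range[1]),
                            equil_tau = ramp_tau / 10,
                            geom = dimer_geometry()) {
  if (ramp_tau <= 0) stop("ramp too fast: ramp_tau must be positive")
  dt <- ss$dt
  sample_every <- max(1, round(ss$sample_tau / dt))
  n_ramp <- round(ramp_tau / dt)
  traces <- list()
  areas <- numeric()
  for (sd_k in ss$seeds) {
    comp_k <- ss$comp; comp_k$seed <- sd_k
    spec0 <- interaction_spec(ss$variant, eps_hh = eps_hh,
                              eps_hc = eps_hc_range[1])
    st <- build_initial_configuration(comp_k, geom = geom)
    pre <- run_dynamics(st, spec0, langevin_params(dt = dt, seed = sd_k),
                        n_steps = round(equil_tau / dt), sample_every = 0,
                        geom = geom)
    legs <- list(up = eps_hc_range, down = rev(eps_hc_range))
    rng <- pre$rng_state
    st_cur <- pre$state
    for (leg in names(legs)) {
      res <- run_dynamics(st_cur, spec0,
                          langevin_params(dt = dt, seed = sd_k),
                          n_steps = n_ramp, sample_every = sample_every,
                          geom = geom,
                          ramp = list(eps_hc = legs[[leg]]),
                          rng_state = rng)
      tvals <- vapply(res$frames, function(f) f$time, 0)
      frac <- (tvals - tvals[1]) / (tvals[length(tvals)] - tvals[1])
      eps_now <- legs[[leg]][1] + frac * diff(legs[[leg]])
      spec_now <- spec0
      ft <- vapply(seq_along(res$frames), function(i) {
        classify_binding_modes(res$frames[[i]], spec_now, geom)$f_tot
      }, 0)
      traces[[length(traces) + 1]] <-
        data.frame(seed = sd_k, leg = leg, time = tvals, eps_hc = eps_now,
                   f_tot = ft)
      rng <- res$rng_state
      st_cur <- res$state
    }
    tr <- do.call(rbind, tail(traces, 2))
    grid_e <- seq(min(eps_hc_range), max(eps_hc_range), length.out = 51)
    up <- approx(tr$eps_hc[tr$leg == "up"], tr$f_tot[tr$leg == "up"], grid_e,
                 rule = 2, ties = mean)$y
    dn <- approx(tr$eps_hc[tr$leg == "down"], tr$f_tot[tr$leg == "down"], grid_e,
                 rule = 2, ties = mean)$y
    areas <- c(areas, sum(diff(grid_e) * (head(up - dn, -1) + tail(up - dn, -1)) / 2))
  }
  structure(list(traces = do.call(rbind, traces), area = mean(areas),
                 area_by_seed = areas, eps_hh = eps_hh,
                 eps_hc_range = eps_hc_range),
            class = "hysteresis_ramp")
}

#' Quench protocol (limited-valence metastable states)
#'
#' Starts from an equilibrium configuration with all attractive interactions
#' off, switches the interactions on instantaneously, relaxes for
#' `relax_tau`, then measures over a further `measure_tau`, checking that the
#' measured quantities have stopped systematically varying (Mann-Kendall at
#' the 5% level).
#'
#' @param eps_hh,eps_hc energies switched on at the quench.
#' @param ss a [scan_spec()] (variant defaults to limited_valence).
#' @param relax_tau,measure_tau the two phases of the run (tau).
#' @param pre_tau equilibration with interactions off before the quench.
#' @param geom a `dimer_geometry`.
#' @return list of class `quench_result`: `means`, `se`, `stationary`,
#'   `cluster_count` (per seed, final frame), `series`, `final_states`.
#' @export
quench_protocol <- function(eps_hh, eps_hc,
                            ss = scan_spec(eps_hh, eps_hc,
                                           variant = "limited_valence"),
                            relax_tau = 1e4, measure_tau = 1e4,
                            pre_tau = 50, geom = dimer_geometry()) {
  dt <- ss$dt
  sample_every <- max(1, round(ss$sample_tau / dt))
  n_side <- sub_box_side(ss$comp$N)
  spec_off <- interaction_spec(ss$variant, eps_hh = 0, eps_hc = 0)
  spec_on <- interaction_spec(ss$variant, eps_hh = eps_hh, eps_hc = eps_hc)
  all_rows <- list(); finals <- list(); nclust <- integer()
  for (k in seq_along(ss$seeds)) {
    sd_k <- ss$seeds[k]
    comp_k <- ss$comp; comp_k$seed <- sd_k
    st <- build_initial_configuration(comp_k, geom = geom)
    pre <- run_dynamics(st, spec_off, langevin_params(dt = dt, seed = sd_k),
                        n_steps = round(pre_tau / dt), sample_every = 0,
                        geom = geom)
    rel <- run_dynamics(pre$state, spec_on,
                        langevin_params(dt = dt, seed = sd_k),
                        n_steps = round(relax_tau / dt), sample_every = 0,
                        geom = geom, rng_state = pre$rng_state)
    mea <- run_dynamics(rel$state, spec_on,
                        langevin_params(dt = dt, seed = sd_k),
                        n_steps = round(measure_tau / dt),
                        sample_every = sample_every,
                        geom = geom, rng_state = rel$rng_state)
    rows <- measure_frames(mea$frames, spec_on, geom, n_side)
    rows$seed <- sd_k
    all_rows[[k]] <- rows
    finals[[k]] <- mea$state
    nclust <- c(nclust, length(detect_clusters(mea$state, spec_on, geom)$sizes))
  }
  series <- do.call(rbind, all_rows)
  obs <- c("phi_sep", "phi_sep_folded", "phi_sep_signed", "rg", "f_tot", "f_c")
  per_seed <- sapply(obs, function(o)
    unname(tapply(series[[o]], series$seed, mean, na.rm = TRUE)))
  if (is.null(dim(per_seed)))
    per_seed <- matrix(per_seed, nrow = 1, dimnames = list(NULL, obs))
  means <- colMeans(per_seed, na.rm = TRUE)
  se <- apply(per_seed, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  stationary <- all(vapply(split(series, series$seed),
                           function(w) is_stationary(w$phi_sep, w$time), TRUE))
  structure(list(eps_hh = eps_hh, eps_hc = eps_hc, means = means, se = se,
                 stationary = stationary, cluster_count = nclust,
                 series = series, final_states = finals),
            class = "quench_result")
}
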