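#' Langevin integration parameters
#'
#' @param dt timestep in tau (default 0.001).
#' @param gamma friction per unit mass (1/tau); `gamma = 0` gives
#'   deterministic NVE dynamics (the thermal noise is switched off with it,
#'   per the fluctuation-dissipation relation).
#' @param kT temperature (k_B T, default 1).
#' @param skin neighbour-list skin (sigma); the pair list is rebuilt when any
#'   site has moved more than `skin/2` since the last build.  `skin = 0`
#'   forces a rebuild every step and yields bitwise-identical trajectories.
#' @param seed integer seed for the simulation noise stream.
#' @return an object of class `langevin_params`.
#' @export
langevin_params <- function(dt = 0.001, gamma = 1, kT = 1, skin = 0.3,
                            seed = 1) {
  stopifnot(dt > 0, gamma >= 0, kT >= 0, skin >= 0)
  structure(list(dt = dt, gamma = gamma, kT = kT, skin = skin,
                 seed = as.integer(seed)),
            class = "langevin_params")
}

#' Run Langevin dynamics
#'
#' Integrates the system forward by `n_steps` timesteps with a velocity-Verlet
#' Langevin scheme: point beads translate; rigid dimers translate and rotate
#' (quaternion orientation, lab-frame angular momentum, exponential-map
#' rotation update with renormalisation every step).  The thermal noise obeys
#' the fluctuation-dissipation relation per degree of freedom, with the
#' rotational friction tensor derived from the same per-sphere friction as
#' the translation.  The run is bit-reproducible for a given seed; the noise
#' stream state is returned so a checkpointed run continues identically.
#'
#' @param state a `system_state`.
#' @param spec an [interaction_spec()].
#' @param params a [langevin_params()].
#' @param n_steps number of timesteps (>= 0).
#' @param sample_every sample interval in steps (0 = no frames).
#' @param geom a `dimer_geometry` (defaults to the state's).
#' @param ramp optional named list `list(eps_hh = c(from, to), eps_hc =
#'   c(from, to))` applied as a piecewise-linear energy ramp across the run;
#'   defaults to constant energies from `spec`.
#' @param rng_state optional 64-character hex string continuing a previous
#'   noise stream (as returned in `$rng_state`); overrides `params$seed`.
#' @return a list of class `sim_result` with elements `state` (final
#'   `system_state`), `frames` (list of sampled states), `series`
#'   (data.frame of time, energy decomposition, kinetic energies, active
#'   valence bonds) and `rng_state`.
#' @export
run_dynamics <- function(state, spec, params = langevin_params(),
                         n_steps, sample_every = 0, geom = state$geom,
                         ramp = NULL, rng_state = NULL) {
  if (is.null(geom)) geom <- dimer_geometry()
  stopifnot(n_steps >= 0)
  eps_ramp <- c(spec$eps_hh, spec$eps_hh, spec$eps_hc, spec$eps_hc)
  if (!is.null(ramp)) {
    if (!is.null(ramp$eps_hh)) eps_ramp[1:2] <- ramp$eps_hh
    if (!is.null(ramp$eps_hc)) eps_ramp[3:4] <- ramp$eps_hc
    if (n_steps == 0) stop("ramp too fast: a ramp needs n_steps > 0")
  }
  rs <- if (is.null(rng_state)) "" else rng_state
  out <- cpp_run(unclass(state), geom, spec, params$dt, params$gamma,
                 params$kT, params$skin, as.integer(n_steps),
                 as.integer(sample_every), eps_ramp, rs, params$seed)
  wrap_state <- function(s) {
    s$geom <- geom
    s$polymer <- state$polymer
    class(s) <- "system_state"
    s
  }
  out$state <- wrap_state(out$state)
  out$frames <- lapply(out$frames, wrap_state)
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result:", length(x$frames), "sampled frames, final time",
      sprintf("%.3f tau\n", x$state$time))
  invisible(x)
}

#' Neighbour pairs within a cutoff
#'
#' Grid-accelerated search for all site pairs within `cutoff`, excluding
#' intra-dimer pairs.  Site order: polymer beads first, then 7 spheres per
#' dimer in geometry order.
#'
#' @param state a `system_state`.
#' @param cutoff search radius (sigma).
#' @param geom a `dimer_geometry`.
#' @return data.frame with 1-based site indices `i < j` and `dist`.
#' @export
neighbor_pairs <- function(state, cutoff, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  L <- nrow(state$pol_x); N <- nrow(state$dim_x)
  pos <- rbind(state$pol_x, if (N > 0) sphere_positions(state, geom))
  if (is.null(pos) || nrow(pos) == 0)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  p <- cpp_pairs_within(pos, matrix(0, 0, 3), cutoff, state$lx,
                        identical(state$boundary, "periodic"))
  out <- data.frame(i = p$i, j = p$j, dist = p$dist)
  if (N > 0 && nrow(out) > 0) {
    dim_of <- function(s) ifelse(s <= L, -1L, (s - L - 1L) %/% 7L)
    keep <- !(dim_of(out$i) >= 0 & dim_of(out$i) == dim_of(out$j))
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Mean kinetic energy per degree of freedom
#'
#' @param state a `system_state`.
#' @param geom geometry (for the dimer moments of inertia).
#' @return list with `trans`, `rot` and `per_dof` (all in k_B T).
#' @export
kinetic_energy <- function(state, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  ke_tr <- 0.5 * sum(state$pol_v^2) + 0.5 * sum(state$dim_v^2)
  ke_rot <- 0
  N <- nrow(state$dim_x)
  for (d in seq_len(N)) {
    R <- quat_to_matrix(state$dim_q[d, ])
    lb <- drop(t(R) %*% state$dim_l[d, ])
    ke_rot <- ke_rot + 0.5 * sum(lb^2 / geom$inertia)
  }
  ndof <- 3 * nrow(state$pol_x) + 6 * N
  list(trans = ke_tr, rot = ke_rot,
       per_dof = if (ndof > 0) (ke_tr + ke_rot) / ndof else NA_real_)
}

# body->lab rotation matrix from a unit quaternion (w, x, y, z)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
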