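#' bipsim: coarse-grained simulation of chromatin-mediated protein phase
#' separation
#'
#' Langevin-dynamics simulation of rigid seven-sphere protein dimers (inspired
#' by the domain structure of HP1) in solution with a bead-spring chromatin
#' polymer, plus the observables and experiment protocols used to map the
#' liquid-liquid / bridging-induced phase behaviour of such systems.
#'
#' All internal computation uses reduced units: the polymer bead diameter
#' sigma is the unit of length, the thermal energy k_B*T the unit of energy,
#' and tau the unit of time. One bead covers roughly 1 kbp of chromatin and
#' sigma corresponds to about 10 nm.
#'
#' @useDynLib bipsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor.test coef nls lm dist approx confint
#' @importFrom utils head tail write.csv read.csv read.table
#' @keywords internal
"_PACKAGE"

role_levels <- c("CSD", "CD", "hinge", "NTE")

#' Unit system of the model
#'
#' The model works in reduced units; this object records how they map onto
#' physical chromatin scales: one polymer bead has diameter `sigma_nm`
#' nanometres and covers `kbp_per_bead` kilobases.
#'
#' @param sigma_nm bead diameter in nanometres (default 10).
#' @param kbp_per_bead genomic coverage of one bead in kbp (default 1).
#' @return an object of class `unit_system`.
#' @export
unit_system <- function(sigma_nm = 10, kbp_per_bead = 1) {
  stopifnot(sigma_nm > 0, kbp_per_bead > 0)
  structure(list(sigma_nm = sigma_nm, kbp_per_bead = kbp_per_bead,
                 tau = 1, kT = 1),
            class = "unit_system")
}

#' Genomic span of a polymer
#'
#' @param L number of beads (>= 1).
#' @param units a [unit_system()].
#' @return genomic length in kbp.
#' @export
genomic_span <- function(L, units = unit_system()) {
  if (!is.numeric(L) || length(L) != 1 || L < 1)
    stop("L must be a bead count >= 1")
  L * units$kbp_per_bead
}

#' Rigid dimer geometry
#'
#' Builds the body-frame geometry of one rigid protein dimer: seven spheres of
#' diameter 0.5 sigma representing the dimerised chromoshadow domain (CSD, one
#' sphere), the two chromodomains (CD), the two hinges and the two N-terminal
#' extensions (NTE).  The reference coordinates put both CDs on one exterior
#' face (so both can simultaneously contact a polymer bead, which makes the
#' coating binding mode geometrically easy) and the hinge/NTE spheres on the
#' opposite face, where protein-protein contacts form.  The geometry is
#' mirror-symmetric about the CSD.
#'
#' @param coords optional 7x3 matrix of body-frame sphere centres (sigma);
#'   rows must be ordered to match `roles`.
#' @param roles character vector of sphere roles, with multiplicities
#'   CSD:1, CD:2, hinge:2, NTE:2.
#' @param sphere_diameter sphere diameter in sigma (default 0.5).
#' @return an object of class `dimer_geometry` with the raw coordinates, the
#'   centre-of-mass-centred principal-frame coordinates used by the
#'   integrator, and the principal moments of inertia (total dimer mass 1,
#'   equal point masses on the sphere centres).
#' @export
dimer_geometry <- function(coords = NULL, roles = NULL, sphere_diameter = 0.5) {
  if (is.null(coords)) {
    coords <- rbind(
      CSD   = c(0.00,  0.00, 0),
      hinge = c(0.22,  0.22, 0),
      hinge2 = c(-0.22, 0.22, 0),
      CD    = c(0.45, -0.15, 0),
      CD2   = c(-0.45, -0.15, 0),
      NTE   = c(0.22,  0.50, 0),
      NTE2  = c(-0.22, 0.50, 0))
    roles <- c("CSD", "hinge", "hinge", "CD", "CD", "NTE", "NTE")
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != 7 || ncol(coords) != 3)
    stop("a dimer geometry needs exactly 7 spheres with x, y, z coordinates")
  if (is.null(roles) || length(roles) != 7)
    stop("roles must label all 7 spheres")
  if (!all(roles %in% role_levels))
    stop("roles must be drawn from: ", paste(role_levels, collapse = ", "))
  mult <- table(factor(roles, levels = role_levels))
  if (!all(mult == c(CSD = 1, CD = 2, hinge = 2, NTE = 2)))
    stop("role multiplicities must be CSD:1, CD:2, hinge:2, NTE:2")
  dimnames(coords) <- NULL

  # equal point masses, total mass 1
  m <- rep(1 / 7, 7)
  com <- colSums(coords * m)
  centred <- sweep(coords, 2, com)
  inert <- matrix(0, 3, 3)
  for (k in 1:7) {
    r <- centred[k, ]
    inert <- inert + m[k] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  ev <- eigen(inert, symmetric = TRUE)
  # principal axes, deterministic sign convention
  axes <- ev$vectors
  for (c in 1:3) if (axes[which.max(abs(axes[, c])), c] < 0) axes[, c] <- -axes[, c]
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  pcoords <- centred %*% axes

  geom <- structure(list(
    coords = coords, roles = roles,
    role_code = match(roles, role_levels),  # 1 CSD, 2 CD, 3 hinge, 4 NTE
    sphere_diameter = sphere_diameter,
    mass = 1, masses = m,
    pcoords = pcoords, inertia = ev$values, axes = axes,
    com = com), class = "dimer_geometry")
  validate_dimer_geometry(geom)
  geom
}

#' @rdname dimer_geometry
#' @param geom a `dimer_geometry`.
#' @export
validate_dimer_geometry <- function(geom) {
  ext <- dimer_extent(geom)
  if (ext < 1.0 || ext > 1.5)
    stop(sprintf("dimer maximal extent %.4f sigma outside [1.0, 1.5] sigma", ext))
  # mirror symmetry about the CSD plane: reflect through x = x_CSD
  csd <- geom$coords[geom$roles == "CSD", , drop = FALSE]
  refl <- geom$coords
  refl[, 1] <- 2 * csd[1, 1] - refl[, 1]
  for (r in role_levels) {
    a <- geom$coords[geom$roles == r, , drop = FALSE]
    b <- refl[geom$roles == r, , drop = FALSE]
    # every reflected sphere must coincide with a sphere of the same role
    d <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b)), drop = FALSE]
    if (any(apply(d, 1, min) > 1e-8))
      stop("geometry is not mirror-symmetric about the CSD")
  }
  # both CDs must be able to touch one polymer bead at the same time
  cds <- geom$coords[geom$roles == "CD", , drop = FALSE]
  reach <- 0.5 + geom$sphere_diameter / 2  # bead radius + CD radius
  if (sqrt(sum((cds[1, ] - cds[2, ])^2)) > 2 * reach)
    stop("CD spheres too far apart to contact a single polymer bead")
  invisible(geom)
}

#' @rdname dimer_geometry
#' @export
dimer_extent <- function(geom) {
  max(dist(geom$coords)) + geom$sphere_diameter
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat("Rigid dimer geometry: 7 spheres (diameter",
      x$sphere_diameter, "sigma)\n")
  cat("  roles:", paste(x$roles, collapse = " "), "\n")
  cat(sprintf("  maximal extent: %.4f sigma\n", dimer_extent(x)))
  cat(sprintf("  principal inertia: %.5f %.5f %.5f (mass 1)\n",
              x$inertia[1], x$inertia[2], x$inertia[3]))
  invisible(x)
}

#' Polymer specification
#'
#' Bead-spring chromatin fibre: beads of diameter 1 sigma joined by FENE
#' springs, with Kratky-Porod bending rigidity.
#'
#' @param L number of beads (>= 2 for a chain; 0 allowed for protein-only
#'   systems).
#' @param fene_k FENE spring constant (k_B T / sigma^2).
#' @param fene_r0 FENE maximum extension (sigma, > 1).
#' @param k_bend bending constant (k_B T); the default 3.7 makes the box edge
#'   of the standard composition comparable to the worm-like-chain radius of
#'   gyration of the polymer.
#' @return an object of class `polymer_spec`.
#' @export
polymer_spec <- function(L = 1000, fene_k = 30, fene_r0 = 1.6, k_bend = 3.7) {
  stopifnot(L >= 0, fene_r0 > 1, k_bend >= 0, fene_k > 0)
  structure(list(L = L, bead_diameter = 1, fene_k = fene_k,
                 fene_r0 = fene_r0, k_bend = k_bend),
            class = "polymer_spec")
}

#' System composition
#'
#' @param N number of protein dimers.
#' @param L number of polymer beads.
#' @param lx cubic box edge (sigma).
#' @param boundary `"walls"` (confining repulsive walls, the production
#'   default) or `"periodic"`.
#' @param seed integer random seed for the initial configuration.
#' @return an object of class `system_composition`.
#' @export
system_composition <- function(N = 1000, L = 1000, lx = 35,
                               boundary = c("walls", "periodic"), seed = 1) {
  boundary <- match.arg(boundary)
  stopifnot(N >= 0, L >= 0, lx > 0)
  structure(list(N = N, L = L, lx = lx, boundary = boundary,
                 seed = as.integer(seed)),
            class = "system_composition")
}

#' Build an initial configuration
#'
#' Places the polymer as a self-avoiding random walk with bond length 1 sigma
#' folded into the box, then inserts dimers with random positions and
#' orientations rejecting overlaps (centre distances below `min_sep_frac`
#' times the contact distance), and draws Maxwell-Boltzmann velocities at
#' k_B T = 1.  Deterministic for a given seed.
#'
#' @param comp a [system_composition()].
#' @param spec a [polymer_spec()] (bead count taken from `comp`).
#' @param geom a [dimer_geometry()].
#' @param min_sep_frac overlap rejection threshold as a fraction of the
#'   contact distance (default 0.9).
#' @param max_try bounded retry budget per particle before a
#'   "packing infeasible" error.
#' @return a `system_state`.
#' @export
build_initial_configuration <- function(comp, spec = polymer_spec(L = comp$L),
                                        geom = dimer_geometry(),
                                        min_sep_frac = 0.9, max_try = 20000) {
  st <- cpp_build_initial(comp$L, comp$N, comp$lx, geom, comp$seed, 1.0,
                          1.0, min_sep_frac, as.integer(max_try))
  st$boundary <- comp$boundary
  st$geom <- geom
  st$polymer <- spec
  class(st) <- "system_state"
  st
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state:", nrow(x$pol_x), "polymer beads,", nrow(x$dim_x),
      "dimers, box", x$lx, "sigma (", x$boundary, ")\n")
  cat(sprintf("  time: %.3f tau, active valence bonds: %d\n",
              x$time, nrow(x$bonds)))
  invisible(x)
}

#' World-frame sphere positions of all dimers
#'
#' @param state a `system_state`.
#' @param geom a `dimer_geometry` (defaults to the one stored in the state).
#' @return a (7N) x 3 matrix, 7 consecutive rows per dimer in geometry order.
#' @export
sphere_positions <- function(state, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  cpp_sphere_positions(state$dim_x, state$dim_q, geom$pcoords)
}

#' Validate state invariants
#'
#' Checks quaternion normalisation, rigid-body distance preservation and (in
#' walls mode) confinement.
#'
#' @param state a `system_state`.
#' @param geom geometry used for the rigidity check.
#' @param tol tolerance on quaternion norm and intra-dimer distances.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_state <- function(state, geom = state$geom, tol = 1e-9) {
  if (is.null(geom)) geom <- dimer_geometry()
  qn <- sqrt(rowSums(state$dim_q^2))
  if (length(qn) && max(abs(qn - 1)) > tol)
    stop("quaternions are not normalised")
  if (nrow(state$dim_x) > 0) {
    sp <- sphere_positions(state, geom)
    ref <- as.matrix(dist(geom$pcoords))
    for (d in seq_len(min(nrow(state$dim_x), 25))) {
      rows <- (d - 1) * 7 + 1:7
      dd <- as.matrix(dist(sp[rows, ]))
      if (max(abs(dd - ref)) > max(tol, 1e-9))
        stop("intra-dimer distances deviate from the body frame")
    }
  }
  if (identical(state$boundary, "walls")) {
    allpos <- rbind(state$pol_x, if (nrow(state$dim_x)) sphere_positions(state, geom))
    if (length(allpos) && (min(allpos) < 0 || max(allpos) > state$lx))
      stop("coordinates outside the box in walls mode")
  }
  invisible(TRUE)
}
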