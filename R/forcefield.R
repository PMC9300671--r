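#' Interaction specification
#'
#' Collects every potential parameter of the model.  Two protein-protein
#' interaction variants are supported:
#' \describe{
#'   \item{multivalent}{a truncated-and-shifted Morse-like attraction between
#'     every hinge/NTE sphere pair of different dimers within `rc_hh`; several
#'     NTEs can engage one hinge at once, limited only by sterics.}
#'   \item{limited_valence}{a shorter-ranged attraction applied only to
#'     explicitly bookkept exclusive hinge-NTE bonds: each hinge and each NTE
#'     site holds at most one bond (so a dimer binds at most four partners).
#'     Bonds form when a free pair comes within `r_on` (nearest pairs first)
#'     and break beyond `r_off`; the hysteresis gap avoids force chattering.}
#' }
#' The chromodomain-chromatin (HC) attraction is identical for both variants.
#' Quoted `eps_hh`/`eps_hc` values scale the Morse-like form; because the
#' potential is shifted to vanish at its cutoff, they are not the true well
#' depths.
#'
#' @param variant `"multivalent"` or `"limited_valence"`.
#' @param eps_hh hinge-NTE attraction scale (k_B T).
#' @param eps_hc CD-polymer attraction scale (k_B T).
#' @param eps_wca steric (WCA) energy scale, default 1 k_B T.
#' @param a_hh,r0_hh,rc_hh Morse width (1/sigma), equilibrium distance and
#'   cutoff for the hinge-NTE class.  Defaults: multivalent a = 4, r0 = 0.5,
#'   rc = 1.0; limited valence a = 10, r0 = 0.5, rc = 0.65.
#' @param a_hc,r0_hc,rc_hc same for the CD-bead class (a = 4, r0 = 0.75,
#'   rc = 1.1 for both variants).
#' @param r_on,r_off limited-valence bond formation/break distances.
#' @param fene_k,fene_r0 FENE bond parameters.
#' @param k_bend Kratky-Porod bending constant (k_B T).
#' @return an object of class `interaction_spec`.
#' @export
interaction_spec <- function(variant = c("multivalent", "limited_valence"),
                             eps_hh = 0, eps_hc = 0, eps_wca = 1,
                             a_hh = NULL, r0_hh = 0.5, rc_hh = NULL,
                             a_hc = 4, r0_hc = 0.75, rc_hc = 1.1,
                             r_on = 0.55, r_off = 0.62,
                             fene_k = 30, fene_r0 = 1.6, k_bend = 3.7) {
  variant <- match.arg(variant)
  if (is.null(a_hh)) a_hh <- if (variant == "multivalent") 4 else 10
  if (is.null(rc_hh)) rc_hh <- if (variant == "multivalent") 1.0 else 0.65
  stopifnot(eps_hh >= 0, eps_hc >= 0, eps_wca > 0,
            r0_hh < rc_hh, r0_hc < rc_hc, fene_r0 > 1, k_bend >= 0)
  if (variant == "limited_valence" && !(r_on <= r_off && r_off < rc_hh))
    stop("limited valence requires r_on <= r_off < rc_hh")
  structure(list(variant = variant, eps_hh = eps_hh, eps_hc = eps_hc,
                 eps_wca = eps_wca,
                 a_hh = a_hh, r0_hh = r0_hh, rc_hh = rc_hh,
                 a_hc = a_hc, r0_hc = r0_hc, rc_hc = rc_hc,
                 r_on = r_on, r_off = r_off,
                 fene_k = fene_k, fene_r0 = fene_r0, k_bend = k_bend),
            class = "interaction_spec")
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat("interaction_spec (", x$variant, ")\n", sep = "")
  cat(sprintf("  eps_hh = %g, eps_hc = %g (k_B T); WCA eps = %g\n",
              x$eps_hh, x$eps_hc, x$eps_wca))
  cat(sprintf("  HH: a = %g, r0 = %g, rc = %g", x$a_hh, x$r0_hh, x$rc_hh))
  if (x$variant == "limited_valence")
    cat(sprintf(" (bond on/off: %g/%g)", x$r_on, x$r_off))
  cat(sprintf("\n  HC: a = %g, r0 = %g, rc = %g\n", x$a_hc, x$r0_hc, x$rc_hc))
  cat(sprintf("  FENE K = %g, R0 = %g; bending K = %g\n",
              x$fene_k, x$fene_r0, x$k_bend))
  invisible(x)
}

#' Weeks-Chandler-Andersen potential
#'
#' Purely repulsive truncated-shifted Lennard-Jones:
#' U = 4 eps ((d/r)^12 - (d/r)^6) + eps for r < 2^(1/6) d, 0 beyond.
#'
#' @param r centre-centre distance(s), > 0.
#' @param d contact diameter (mixing rule: (d_i + d_j)/2 applied by caller).
#' @param eps energy scale.
#' @return list with `energy` and `force` (radial scalar, positive = repulsive).
#' @export
wca <- function(r, d = 1, eps = 1) {
  if (any(r <= 0)) stop("wca: distance must be positive")
  rc <- 2^(1 / 6) * d
  s6 <- (d / r)^6
  inside <- r < rc
  u <- ifelse(inside, 4 * eps * (s6^2 - s6) + eps, 0)
  f <- ifelse(inside, 24 * eps * (2 * s6^2 - s6) / r, 0)
  list(energy = u, force = f)
}

#' FENE bond potential
#'
#' U = -0.5 K R0^2 log(1 - (r/R0)^2); diverges as r approaches R0.
#'
#' @param r bond length(s), 0 <= r < R0.
#' @param k spring constant.
#' @param r0 maximum extension.
#' @return list with `energy` and `force` (positive = attractive pull back).
#' @export
fene <- function(r, k = 30, r0 = 1.6) {
  if (any(r < 0)) stop("fene: negative distance")
  if (any(r >= r0)) stop("bond overstretched: r >= R0")
  fr <- 1 - (r / r0)^2
  list(energy = -0.5 * k * r0^2 * log(fr), force = -k * r / fr)
}

#' Kratky-Porod bending potential
#'
#' U = K (1 - cos theta) on the angle between consecutive bond vectors.
#'
#' @param theta angle(s) in radians, in `[0, pi]`.
#' @param k bending constant.
#' @return list with `energy` and `dU_dtheta`.
#' @export
kratky_porod <- function(theta, k = 3.7) {
  stopifnot(all(theta >= -1e-12), all(theta <= pi + 1e-12))
  list(energy = k * (1 - cos(theta)), dU_dtheta = k * sin(theta))
}

#' Morse-like attraction, truncated and shifted
#'
#' U(r) = eps ((1 - exp(-a (r - r0)))^2 - 1) - U_shift for r < rc, 0 beyond,
#' with U_shift chosen so U(rc) = 0 and the force continuous at the cutoff.
#'
#' @param r distance(s), > 0.
#' @param eps quoted energy scale (the true well depth is `eps (1 + shift)`
#'   where shift < 0 is the cutoff correction).
#' @param a well width parameter (1/sigma).
#' @param r0 equilibrium distance.
#' @param rc cutoff.
#' @return list with `energy`, `force` (radial scalar, positive = repulsive)
#'   and the `shift` value.
#' @export
morse_attraction <- function(r, eps, a, r0, rc) {
  if (any(r <= 0)) stop("morse_attraction: distance must be positive")
  shift <- (1 - exp(-a * (rc - r0)))^2 - 1
  e <- exp(-a * (r - r0))
  inside <- r < rc
  u <- ifelse(inside, eps * ((1 - e)^2 - 1 - shift), 0)
  f <- ifelse(inside, -2 * eps * a * e * (1 - e), 0)  # -dU/dr
  list(energy = u, force = f, shift = shift)
}

#' Confining wall potential
#'
#' WCA-form repulsion from each box face acting on a sphere centre, with
#' contact parameter equal to the sphere radius, so the range is
#' 2^(1/6) d/2 from the face and the energy at distance d/2 equals eps.
#'
#' @param pos n x 3 matrix of centre positions.
#' @param lx box edge.
#' @param d sphere diameter(s) (length 1 or n).
#' @param eps energy scale.
#' @return list with total `energy` and n x 3 `force` matrix (directed inward).
#' @export
wall_potential <- function(pos, lx, d = 1, eps = 1) {
  pos <- rbind(pos)
  n <- nrow(pos)
  d <- rep(d, length.out = n)
  u <- 0
  f <- matrix(0, n, 3)
  for (dim in 1:3) {
    for (side in c(0, 1)) {
      s <- if (side == 0) pos[, dim] else lx - pos[, dim]
      s <- pmax(s, 1e-9)
      w <- wca(s, d / 2, eps)
      u <- u + sum(w$energy)
      f[, dim] <- f[, dim] + if (side == 0) w$force else -w$force
    }
  }
  list(energy = u, force = f)
}

#' Resolve the limited-valence bond table
#'
#' Pure bookkeeping: existing bonds persist while their pair distance is at
#' most `r_off`; broken bonds free both sites; remaining candidate pairs (a
#' free hinge and a free NTE within `r_on`) are admitted in ascending-distance
#' order.  Each hinge and each NTE site can hold at most one bond.
#'
#' @param candidates data.frame with columns `hinge`, `nte` (site ids) and
#'   `dist`; current pair distances for candidate formation.
#' @param table data.frame with columns `hinge`, `nte`, `dist` for currently
#'   active bonds (`dist` = current distance).
#' @param r_on,r_off formation / break distances.
#' @return updated bond table (data.frame with columns `hinge`, `nte`).
#' @export
resolve_limited_valence <- function(candidates, table = NULL,
                                    r_on = 0.55, r_off = 0.62) {
  if (is.null(table) || nrow(table) == 0)
    table <- data.frame(hinge = integer(), nte = integer(), dist = numeric())
  keep <- table$dist <= r_off
  table <- table[keep, , drop = FALSE]
  busy_h <- table$hinge
  busy_n <- table$nte
  if (!is.null(candidates) && nrow(candidates) > 0) {
    cand <- candidates[candidates$dist <= r_on, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$hinge, cand$nte), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      h <- cand$hinge[k]; n <- cand$nte[k]
      if (h %in% busy_h || n %in% busy_n) next
      table <- rbind(table, data.frame(hinge = h, nte = n, dist = cand$dist[k]))
      busy_h <- c(busy_h, h); busy_n <- c(busy_n, n)
    }
  }
  rownames(table) <- NULL
  table[, c("hinge", "nte")]
}

#' Total forces and potential energy
#'
#' Evaluates the full force field on a state: WCA sterics between all
#' distinct-body sphere pairs, FENE + bending along the polymer, hinge-NTE
#' attraction per variant, CD-bead attraction and wall repulsion.  Returns
#' per-bead forces, per-dimer net force and torque (about the centre of
#' mass) and the potential energy decomposition.
#'
#' @param state a `system_state`.
#' @param spec an [interaction_spec()].
#' @param geom a `dimer_geometry`.
#' @param method `"cell"` (cell-list accelerated, the production path) or
#'   `"brute"` (all-pairs, for cross-checks).
#' @return list with `f_pol`, `f_dim`, `torque_dim`, `f_site`, `u_total`,
#'   `u_terms` and the active `bonds` table.
#' @export
total_forces <- function(state, spec, geom = state$geom,
                         method = c("cell", "brute")) {
  method <- match.arg(method)
  if (is.null(geom)) geom <- dimer_geometry()
  cpp_forces(unclass(state), geom, spec, 0.3, method == "brute")
}

# ---------------------------------------------------------------------------
# Pure-R brute-force reference: assembles the same force field from the
# closed-form potentials above.  O(M^2); used as the independent oracle in
# tests, never in production paths.

#' Brute-force reference forces (pure R)
#'
#' Independent all-pairs assembly of the force field from the closed-form
#' potential functions.  Slow; intended for small systems and cross-checks
#' against [total_forces()].
#'
#' @inheritParams total_forces
#' @return same shape as [total_forces()] (without `f_site`).
#' @export
reference_forces <- function(state, spec, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  L <- nrow(state$pol_x); N <- nrow(state$dim_x)
  sp <- if (N > 0) sphere_positions(state, geom) else matrix(0, 0, 3)
  pos <- rbind(state$pol_x, sp)
  M <- nrow(pos)
  type <- c(rep(0L, L), rep(geom$role_code, N))       # 0 bead, 1 CSD, 2 CD, 3 hinge, 4 NTE
  body <- c(rep(-seq_len(max(L, 1)), length.out = L), rep(seq_len(N), each = 7))
  rad <- c(rep(0.5, L), rep(geom$sphere_diameter / 2, 7 * N))
  periodic <- identical(state$boundary, "periodic")
  lx <- state$lx

  f <- matrix(0, M, 3)
  u <- c(steric = 0, fene = 0, bend = 0, hh = 0, hc = 0, wall = 0)

  # limited-valence bond set from the state table (site ids)
  bonded <- matrix(FALSE, 0, 0)
  partner <- rep(NA_integer_, M)
  if (spec$variant == "limited_valence" && nrow(state$bonds) > 0) {
    partner[state$bonds[, 1]] <- state$bonds[, 2]
    partner[state$bonds[, 2]] <- state$bonds[, 1]
  }

  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (body[i] > 0 && body[i] == body[j]) next
      dv <- pos[i, ] - pos[j, ]
      if (periodic) dv <- dv - lx * round(dv / lx)
      r <- sqrt(sum(dv^2))
      fr <- 0
      d <- rad[i] + rad[j]
      if (r < 2^(1 / 6) * d) {
        w <- wca(r, d, spec$eps_wca)
        u["steric"] <- u["steric"] + w$energy
        fr <- fr + w$force
      }
      hc <- (type[i] == 0 && type[j] == 2) || (type[i] == 2 && type[j] == 0)
      hh <- (type[i] == 3 && type[j] == 4) || (type[i] == 4 && type[j] == 3)
      if (hc && r < spec$rc_hc) {
        m <- morse_attraction(r, spec$eps_hc, spec$a_hc, spec$r0_hc, spec$rc_hc)
        u["hc"] <- u["hc"] + m$energy
        fr <- fr + m$force
      } else if (hh && r < spec$rc_hh) {
        act <- if (spec$variant == "multivalent") TRUE
               else isTRUE(partner[i] == j)
        if (act) {
          m <- morse_attraction(r, spec$eps_hh, spec$a_hh, spec$r0_hh, spec$rc_hh)
          u["hh"] <- u["hh"] + m$energy
          fr <- fr + m$force
        }
      }
      if (fr != 0) {
        fv <- fr * dv / r
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
  }

  # FENE + bending along the chain
  if (L >= 2) {
    for (i in seq_len(L - 1)) {
      dv <- pos[i, ] - pos[i + 1, ]
      if (periodic) dv <- dv - lx * round(dv / lx)
      r <- sqrt(sum(dv^2))
      fb <- fene(r, spec$fene_k, spec$fene_r0)
      u["fene"] <- u["fene"] + fb$energy
      fv <- fb$force * dv / r
      f[i, ] <- f[i, ] + fv
      f[i + 1, ] <- f[i + 1, ] - fv
    }
  }
  if (L >= 3 && spec$k_bend > 0) {
    for (i in 2:(L - 1)) {
      b1 <- pos[i, ] - pos[i - 1, ]
      b2 <- pos[i + 1, ] - pos[i, ]
      if (periodic) { b1 <- b1 - lx * round(b1 / lx); b2 <- b2 - lx * round(b2 / lx) }
      n1 <- sqrt(sum(b1^2)); n2 <- sqrt(sum(b2^2))
      uv <- b1 / n1; vv <- b2 / n2
      cth <- sum(uv * vv)
      u["bend"] <- u["bend"] + spec$k_bend * (1 - cth)
      fprev <- -spec$k_bend / n1 * (vv - cth * uv)
      fnext <- spec$k_bend / n2 * (uv - cth * vv)
      f[i - 1, ] <- f[i - 1, ] + fprev
      f[i + 1, ] <- f[i + 1, ] + fnext
      f[i, ] <- f[i, ] - fprev - fnext
    }
  }

  if (!periodic) {
    w <- wall_potential(pos, lx, 2 * rad, spec$eps_wca)
    u["wall"] <- w$energy
    f <- f + w$force
  }

  f_pol <- f[seq_len(L), , drop = FALSE]
  f_dim <- matrix(0, N, 3); torque <- matrix(0, N, 3)
  for (d in seq_len(N)) {
    rows <- L + (d - 1) * 7 + 1:7
    f_dim[d, ] <- colSums(f[rows, , drop = FALSE])
    off <- sweep(pos[rows, , drop = FALSE], 2, state$dim_x[d, ])
    torque[d, ] <- colSums(cbind(
      off[, 2] * f[rows, 3] - off[, 3] * f[rows, 2],
      off[, 3] * f[rows, 1] - off[, 1] * f[rows, 3],
      off[, 1] * f[rows, 2] - off[, 2] * f[rows, 1]))
  }
  list(f_pol = f_pol, f_dim = f_dim, torque_dim = torque,
       u_total = sum(u), u_terms = u)
}
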