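#' Sub-box density grid
#'
#' Splits the cubic box into `n_side^3` equal sub-boxes and counts the protein
#' dimers in each, locating every dimer by the centre of its CSD sphere (one
#' unambiguous point per dimer).
#'
#' @param state a `system_state`.
#' @param n_side sub-boxes per edge; the default keeps the production
#'   convention of 125 sub-boxes for the standard composition and rescales
#'   for other protein counts so the mean occupancy stays fixed (about 8
#'   dimers per sub-box); see [sub_box_side()].
#' @param geom a `dimer_geometry`.
#' @return an object of class `sub_box_grid`: counts `n_i`, sub-box volume
#'   `v_sb`, overall density `rho` and box size.
#' @export
sub_box_grid <- function(state, n_side = NULL, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  if (is.null(n_side)) n_side <- sub_box_side(N)
  lx <- state$lx
  csd_row <- which(geom$role_code == 1)[1]
  pos <- if (N > 0) {
    sp <- sphere_positions(state, geom)
    sp[(seq_len(N) - 1) * 7 + csd_row, , drop = FALSE]
  } else matrix(0, 0, 3)
  w <- lx / n_side
  idx <- pmin(pmax(floor(pos / w), 0), n_side - 1)
  lin <- idx[, 1] * n_side^2 + idx[, 2] * n_side + idx[, 3] + 1
  n_i <- tabulate(lin, nbins = n_side^3)
  structure(list(n_i = n_i, n_side = n_side, v_sb = w^3,
                 rho = N / lx^3, N = N, lx = lx),
            class = "sub_box_grid")
}

#' Sub-box count per edge for a given protein number
#'
#' Keeps the mean sub-box occupancy at the production value (1000 dimers over
#' 125 sub-boxes = 8 per box) when the system is scaled.
#'
#' @param N number of dimers.
#' @param target_occupancy mean dimers per sub-box (default 8).
#' @return integer sub-boxes per edge (>= 2).
#' @export
sub_box_side <- function(N, target_occupancy = 8) {
  max(2L, as.integer(round((max(N, 1) / target_occupancy)^(1 / 3))))
}

#' Separation depth
#'
#' Order parameter for phase separation from sub-box densities: each sub-box
#' contributes its deviation from the overall density rho, normalised by the
#' deviation expected for a strongly phase-separated system, with reference
#' densities rho_plus (dense phase) and rho_minus = 0 (dilute phase).
#' Three conventions are implemented:
#' \describe{
#'   \item{split (default)}{|rho_i - rho| normalised by (rho_plus - rho) for
#'     sub-boxes denser than the mean and by (rho - rho_minus) for sub-boxes
#'     rarer than the mean.  For an ideal uniform mixture at the production
#'     composition this gives a baseline of about 0.15, and it tends to 1 on
#'     strong separation.}
#'   \item{folded}{|rho_i - rho| / |rho* - rho| with rho* = rho_plus when
#'     rho_i > rho_plus / 2, else rho_minus.  Baseline about 0.28 for
#'     Poisson-distributed counts of mean 8; tends to 1 on separation.}
#'   \item{signed}{the signed terms (rho_i - rho) / (rho* - rho) with the
#'     same rho* rule; identically ~0 in a uniform phase, retained for
#'     audit.}
#' }
#'
#' @param grid a [sub_box_grid()], or a numeric vector of sub-box counts (in
#'   which case `v_sb` and `rho` must be given).
#' @param convention `"split"`, `"folded"` or `"signed"`.
#' @param rho_plus reference dense-phase density (dimers / sigma^3).
#' @param v_sb,rho sub-box volume and overall density when `grid` is a raw
#'   count vector.
#' @return the separation depth (dimensionless scalar).
#' @export
separation_depth <- function(grid, convention = c("split", "folded", "signed"),
                             rho_plus = 0.5, v_sb = NULL, rho = NULL) {
  convention <- match.arg(convention)
  if (inherits(grid, "sub_box_grid")) {
    counts <- grid$n_i; v_sb <- grid$v_sb; rho <- grid$rho
  } else {
    counts <- grid
    if (is.null(v_sb) || is.null(rho))
      stop("raw counts need v_sb and rho")
  }
  rho_i <- counts / v_sb
  t_i <- switch(convention,
    split = {
      denom <- ifelse(rho_i > rho, rho_plus - rho, rho)
      abs(rho_i - rho) / denom
    },
    folded = {
      rho_star <- ifelse(rho_i > rho_plus / 2, rho_plus, 0)
      abs(rho_i - rho) / abs(rho_star - rho)
    },
    signed = {
      rho_star <- ifelse(rho_i > rho_plus / 2, rho_plus, 0)
      (rho_i - rho) / (rho_star - rho)
    })
  mean(t_i)
}

#' Radius of gyration
#'
#' Root mean squared distance of a set of positions from their centroid.
#'
#' @param pos n x 3 position matrix (or a `system_state`, in which case the
#'   polymer beads are used).
#' @return R_g in sigma.
#' @export
radius_of_gyration <- function(pos) {
  if (inherits(pos, "system_state")) pos <- pos$pol_x
  pos <- rbind(pos)
  if (nrow(pos) < 1) stop("radius_of_gyration needs at least one position")
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

# CD-bead contact table: one row per CD sphere, with its nearest in-contact
# bead (NA when unbound).  Contact = CD centre within rc_hc of a bead centre.
cd_contact_table <- function(state, spec, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x); L <- nrow(state$pol_x)
  cd_rows <- which(geom$role_code == 2)
  ncd <- length(cd_rows)
  out <- data.frame(dimer = rep(seq_len(N), each = ncd),
                    cd = rep(seq_len(ncd), times = N),
                    bead = NA_integer_)
  if (N == 0 || L == 0) return(out)
  sp <- sphere_positions(state, geom)
  cd_pos <- sp[rep((seq_len(N) - 1) * 7, each = ncd) + cd_rows, , drop = FALSE]
  p <- cpp_pairs_within(cd_pos, state$pol_x, spec$rc_hc, state$lx,
                        identical(state$boundary, "periodic"))
  if (length(p$i)) {
    # nearest contacting bead per CD
    ord <- order(p$i, p$dist)
    first <- !duplicated(p$i[ord])
    out$bead[p$i[ord][first]] <- p$j[ord][first]
  }
  out
}

#' Classify chromatin binding modes
#'
#' Each dimer has two chromodomains (CDs).  A CD is bound when its centre
#' lies within the CD-bead attraction cutoff of a bead centre; its bound bead
#' is the nearest such bead.  Modes: no CD bound = `unbound`; one CD bound =
#' `dangling`; both bound to beads i, j with |i - j| < 2 = `coating`; with
#' |i - j| >= 2 = `bridging`.
#'
#' @param state a `system_state`.
#' @param spec an [interaction_spec()] (for the contact cutoff).
#' @param geom a `dimer_geometry`.
#' @return an object of class `binding_mode_counts`: per-mode counts and
#'   fractions, `f_tot` (fraction bound in any mode) and `f_c` (fraction of
#'   beads contacted by at least one CD).
#' @export
classify_binding_modes <- function(state, spec, geom = state$geom) {
  N <- nrow(state$dim_x); L <- nrow(state$pol_x)
  tab <- cd_contact_table(state, spec, geom)
  b1 <- tab$bead[tab$cd == 1]
  b2 <- tab$bead[tab$cd == 2]
  nb <- (!is.na(b1)) + (!is.na(b2))
  per_dimer <- rep("unbound", N)
  per_dimer[nb == 1] <- "dangling"
  both <- which(nb == 2)
  per_dimer[both] <- ifelse(abs(b1[both] - b2[both]) < 2, "coating", "bridging")
  modes <- vapply(c("unbound", "dangling", "coating", "bridging"),
                  function(m) sum(per_dimer == m), 0L)
  fractions <- if (N > 0) modes / N else modes * NA_real_
  f_c <- if (L > 0) length(unique(tab$bead[!is.na(tab$bead)])) / L else NA_real_
  structure(list(counts = modes, fractions = fractions,
                 f_tot = unname(1 - fractions["unbound"]),
                 f_c = f_c, per_dimer = per_dimer),
            class = "binding_mode_counts")
}

#' @export
print.binding_mode_counts <- function(x, ...) {
  cat("binding modes:\n")
  print(x$counts)
  cat(sprintf("f_tot = %.3f, f_c = %.3f\n", x$f_tot, x$f_c))
  invisible(x)
}

#' Protein-protein contact pairs of one frame
#'
#' Two dimers interact when a hinge sphere of one and an NTE sphere of the
#' other are within the hinge-NTE attraction cutoff (multivalent variant) or
#' hold an active exclusive bond (limited-valence variant).
#'
#' @param state a `system_state`.
#' @param spec an [interaction_spec()].
#' @param geom a `dimer_geometry`.
#' @return two-column matrix of dimer index pairs (i < j), one row per
#'   interacting pair.
#' @export
protein_contacts <- function(state, spec, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  if (N < 2) return(matrix(integer(), 0, 2))
  if (spec$variant == "limited_valence") {
    if (nrow(state$bonds) == 0) return(matrix(integer(), 0, 2))
    L <- nrow(state$pol_x)
    d_of <- (pmax(state$bonds, L + 1) - L - 1) %/% 7 + 1
    pr <- cbind(pmin(d_of[, 1], d_of[, 2]), pmax(d_of[, 1], d_of[, 2]))
    return(unique(pr, MARGIN = 1))
  }
  sp <- sphere_positions(state, geom)
  hr <- which(geom$role_code == 3); nr <- which(geom$role_code == 4)
  hid <- rep((seq_len(N) - 1) * 7, each = length(hr)) + hr
  nid <- rep((seq_len(N) - 1) * 7, each = length(nr)) + nr
  p <- cpp_pairs_within(sp[hid, , drop = FALSE], sp[nid, , drop = FALSE],
                        spec$rc_hh, state$lx,
                        identical(state$boundary, "periodic"))
  if (!length(p$i)) return(matrix(integer(), 0, 2))
  di <- (hid[p$i] - 1) %/% 7 + 1
  dj <- (nid[p$j] - 1) %/% 7 + 1
  keep <- di != dj
  pr <- cbind(pmin(di[keep], dj[keep]), pmax(di[keep], dj[keep]))
  unique(pr, MARGIN = 1)
}

#' Bond event series
#'
#' Builds the indicator time series y_ij(t) of protein-protein interactions
#' from the sampled frames of one or more runs.  Only pairs that interact at
#' least once are stored; pairs that never interact have zero variance and
#' drop out of every statistic.
#'
#' @param x a `sim_result` (frames sampled at a fixed interval), a list of
#'   per-frame pair matrices, or a logical matrix (frames x pairs).
#' @param spec an [interaction_spec()] (needed when `x` is a `sim_result`).
#' @param interval sampling interval in tau (derived from frame times when
#'   `x` is a `sim_result`).
#' @param n_dimers total number of dimers (for bookkeeping).
#' @return an object of class `bond_event_series` with the indicator matrix
#'   `y` (frames x tracked pairs), `pair_ids`, `interval` and `n_dimers`.
#' @export
bond_event_series <- function(x, spec = NULL, interval = NULL,
                              n_dimers = NULL) {
  if (inherits(x, "sim_result")) {
    if (is.null(spec)) stop("spec needed to extract contacts from frames")
    frames <- x$frames
    if (length(frames) < 2) stop("need at least two sampled frames")
    times <- vapply(frames, function(f) f$time, 0)
    interval <- times[2] - times[1]
    n_dimers <- nrow(frames[[1]]$dim_x)
    x <- lapply(frames, protein_contacts, spec = spec)
  }
  if (is.matrix(x) && is.logical(x)) {
    return(structure(list(y = x, pair_ids = NULL,
                          interval = interval %||% 1,
                          n_dimers = n_dimers %||% NA_integer_),
                     class = "bond_event_series"))
  }
  stopifnot(is.list(x))
  keys <- lapply(x, function(m) if (nrow(m)) m[, 1] * 1e6 + m[, 2] else numeric())
  all_keys <- sort(unique(unlist(keys)))
  tt <- length(x)
  y <- matrix(FALSE, tt, length(all_keys))
  for (f in seq_len(tt))
    y[f, match(keys[[f]], all_keys)] <- TRUE
  pair_ids <- cbind(floor(all_keys / 1e6), all_keys %% 1e6)
  structure(list(y = y, pair_ids = pair_ids, interval = interval %||% 1,
                 n_dimers = n_dimers %||% NA_integer_),
            class = "bond_event_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bond_event_series <- function(x, ...) {
  cat("bond_event_series:", nrow(x$y), "frames x", ncol(x$y),
      "tracked pairs, interval", x$interval, "tau\n")
  invisible(x)
}

#' Bond-bond correlation function
#'
#' Normalised autocovariance of the pair-interaction indicator process
#' y_ij(t), pooled over time, pairs and repeat runs:
#' nu(dt) = (<y(t+dt) y(t)> - <y>^2) / (<y> - <y>^2).  With the default
#' `center = "global"` the angle-bracket average runs over all times and all
#' possible pairs (pairs that never interact contribute zeros), matching the
#' pooled definition; nu(0) = 1 and a frozen (time-constant) bond pattern
#' stays at 1 for all lags.  `center = "pair"` subtracts per-pair means
#' instead, which equals the variance-weighted average of the per-pair
#' normalised autocovariances.
#'
#' @param series a `bond_event_series` or list of them (repeat runs).
#' @param lags integer vector of lags in frames (default 0 .. nframes/2).
#' @param center `"global"` or `"pair"` mean subtraction.
#' @return data.frame with `lag` (frames), `dt` (tau) and `nu`.
#' @export
bond_correlation <- function(series, lags = NULL,
                             center = c("global", "pair")) {
  center <- match.arg(center)
  if (inherits(series, "bond_event_series")) series <- list(series)
  tt <- min(vapply(series, function(s) nrow(s$y), 0L))
  if (is.null(lags)) lags <- 0:(tt %/% 2)
  interval <- series[[1]]$interval
  num <- rep(0, length(lags)); den <- 0
  for (s in series) {
    y <- s$y
    n <- nrow(y)
    # all possible pairs, including the never-interacting ones
    p_tot <- if (is.finite(s$n_dimers) && !is.null(s$pair_ids))
      s$n_dimers * (s$n_dimers - 1) / 2 else ncol(y)
    p_tot <- max(p_tot, ncol(y))
    if (ncol(y) == 0) next
    mu <- colMeans(y)
    if (center == "global") {
      mu_g <- sum(mu) / p_tot
      den <- den + p_tot * (mu_g - mu_g^2)
    } else {
      den <- den + sum(mu - mu^2)
    }
    for (k in seq_along(lags)) {
      lag <- lags[k]
      if (lag >= n) { num[k] <- NA; next }
      idx <- seq_len(n - lag)
      cp <- colSums(y[idx, , drop = FALSE] & y[idx + lag, , drop = FALSE]) / (n - lag)
      num[k] <- num[k] +
        if (center == "global") sum(cp) - p_tot * (sum(mu) / p_tot)^2
        else sum(cp - mu^2)
    }
  }
  if (den <= 0)
    stop("degenerate series: the indicator process has zero variance")
  data.frame(lag = lags, dt = lags * interval, nu = num / den)
}

#' Fit an overall bond decorrelation time
#'
#' Least-squares fit of a stretched exponential nu(dt) =
#' exp(-(dt / tau_hh)^beta), beta in (0, 2], to a bond correlation curve.
#' Fits with large relative standard error are flagged unreliable.
#'
#' @param nu data.frame from [bond_correlation()] (needs >= 10 lag points).
#' @param beta_fixed optionally fix the stretching exponent.
#' @param max_rel_err relative error above which the fit is flagged.
#' @return list with `tau_hh`, `beta`, `tau_se`, `reliable`.
#' @export
fit_decorrelation_time <- function(nu, beta_fixed = NULL, max_rel_err = 0.5) {
  nu <- nu[is.finite(nu$nu), , drop = FALSE]
  if (nrow(nu) < 10) stop("need at least 10 lag points spanning the decay")
  if (min(nu$nu) > 0.9)
    stop("no decorrelation within window")
  d <- nu[nu$dt > 0, , drop = FALSE]
  pos <- d$nu > 0.01
  # initial guess from the 1/e crossing
  below <- which(d$nu < exp(-1))
  tau0 <- if (length(below)) d$dt[below[1]] else max(d$dt)
  fit <- tryCatch({
    if (is.null(beta_fixed)) {
      minpack.lm::nlsLM(nu ~ exp(-(dt / tau)^beta), data = d,
                        start = list(tau = tau0, beta = 1),
                        lower = c(tau = 1e-6, beta = 0.05),
                        upper = c(tau = Inf, beta = 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(nu ~ exp(-(dt / tau)^b), data = cbind(d, b = beta_fixed),
                        start = list(tau = tau0),
                        lower = c(tau = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) stop("no decorrelation within window: ", conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  tau <- unname(est["tau"])
  list(tau_hh = tau,
       beta = unname(if (is.null(beta_fixed)) est["beta"] else beta_fixed),
       tau_se = se,
       reliable = is.finite(se) && se / tau <= max_rel_err)
}

#' Detect protein clusters
#'
#' Two dimers are linked when any inter-dimer sphere pair is within its
#' attraction cutoff (hinge-NTE pairs) or touching sterically (within
#' `steric_slack` times the contact distance).  Clusters are the connected
#' components of the link graph.
#'
#' @param state a `system_state`.
#' @param spec an [interaction_spec()].
#' @param geom a `dimer_geometry`.
#' @param steric_slack multiplier on the steric contact distance (1.05).
#' @return an object of class `cluster_set`: `membership` (dimer -> cluster),
#'   `sizes` (decreasing), and the index of the largest cluster.
#' @export
detect_clusters <- function(state, spec, geom = state$geom,
                            steric_slack = 1.05) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  if (N == 0) stop("no dimers in the system")
  sp <- sphere_positions(state, geom)
  link_cut <- max(spec$rc_hh, steric_slack * geom$sphere_diameter)
  p <- cpp_pairs_within(sp, matrix(0, 0, 3), link_cut, state$lx,
                        identical(state$boundary, "periodic"))
  di <- (p$i - 1) %/% 7 + 1
  dj <- (p$j - 1) %/% 7 + 1
  ti <- geom$role_code[(p$i - 1) %% 7 + 1]
  tj <- geom$role_code[(p$j - 1) %% 7 + 1]
  hn <- (ti == 3 & tj == 4) | (ti == 4 & tj == 3)
  linked <- di != dj &
    (p$dist <= steric_slack * geom$sphere_diameter |
       (hn & p$dist <= spec$rc_hh))
  edges <- unique(cbind(pmin(di[linked], dj[linked]),
                        pmax(di[linked], dj[linked])), MARGIN = 1)
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, as.vector(t(edges)))
  memb <- igraph::components(g)$membership
  # relabel clusters by decreasing size
  sz <- table(memb)
  ord <- order(-as.integer(sz))
  relab <- match(memb, as.integer(names(sz))[ord])
  sizes <- as.integer(sz[ord])
  structure(list(membership = relab, sizes = sizes, largest = 1L, n = N),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$sizes), "clusters; largest:",
      x$sizes[1], "of", x$n, "dimers\n")
  invisible(x)
}

#' Droplet statistics
#'
#' Designates the largest cluster as the droplet and reports its radius
#' R_d = sqrt(5/3) R_g,cluster (the radius of the uniform ball with the same
#' radius of gyration), the protein density inside the sphere of radius R_d
#' about the cluster centroid (`rho_hd`) and the density of the remaining
#' proteins in the remaining box volume (`rho_ld`).
#'
#' @param state a `system_state`.
#' @param clusters a [detect_clusters()] result.
#' @param spec an [interaction_spec()] used when clusters must be detected.
#' @param geom a `dimer_geometry`.
#' @return an object of class `droplet_stats` with `r_d`, `rho_hd`, `rho_ld`,
#'   `centroid` and `droplet_size`.
#' @export
droplet_stats <- function(state, clusters = NULL,
                          spec = interaction_spec(), geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  if (N == 0) stop("empty system: no dimers")
  if (is.null(clusters)) clusters <- detect_clusters(state, spec, geom)
  csd_row <- which(geom$role_code == 1)[1]
  sp <- sphere_positions(state, geom)
  pos <- sp[(seq_len(N) - 1) * 7 + csd_row, , drop = FALSE]
  members <- which(clusters$membership == clusters$largest)
  ctr <- colMeans(pos[members, , drop = FALSE])
  rg <- radius_of_gyration(pos[members, , drop = FALSE])
  r_d <- sqrt(5 / 3) * rg
  dists <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  inside <- dists <= r_d
  v_d <- 4 / 3 * pi * r_d^3
  v_out <- max(state$lx^3 - v_d, .Machine$double.eps)
  structure(list(r_d = r_d, rho_hd = sum(inside) / v_d,
                 rho_ld = sum(!inside) / v_out,
                 centroid = ctr, droplet_size = length(members),
                 inside = inside),
            class = "droplet_stats")
}

#' @export
print.droplet_stats <- function(x, ...) {
  cat(sprintf("droplet: %d dimers, R_d = %.2f sigma, rho_HD = %.3f, rho_LD = %.4f\n",
              x$droplet_size, x$r_d, x$rho_hd, x$rho_ld))
  invisible(x)
}

#' Mass-radius fractal dimension of a cluster
#'
#' Least-squares slope of log(mass within r of the cluster centroid) against
#' log r over r in [1 sigma, cluster R_g].  About 3 for a compact droplet,
#' below 3 for gel-like aggregates.
#'
#' @param pos n x 3 member positions (n >= 30).
#' @param r_grid optional radii; default 12 log-spaced points.
#' @return list with `d_f` and the fitted points.
#' @export
fractal_dimension <- function(pos, r_grid = NULL) {
  pos <- rbind(pos)
  if (nrow(pos) < 30) stop("insufficient mass: cluster smaller than 30")
  ctr <- colMeans(pos)
  d <- sqrt(rowSums(sweep(pos, 2, ctr)^2))
  rg <- sqrt(mean(d^2))
  if (rg <= 1) stop("insufficient mass: cluster radius of gyration <= 1 sigma")
  if (is.null(r_grid)) r_grid <- exp(seq(log(1), log(rg), length.out = 12))
  mass <- vapply(r_grid, function(r) sum(d <= r), 0)
  keep <- mass > 0
  fit <- lm(log(mass[keep]) ~ log(r_grid[keep]))
  list(d_f = unname(coef(fit)[2]),
       r = r_grid[keep], mass = mass[keep])
}

#' Label droplet halves
#'
#' Splits the droplet through its centroid by a plane (normal along the
#' droplet's first principal axis by default) and labels the member dimers
#' `"A"`/`"B"` by side.  Used as the t = 0 reference for [mixing_index()].
#'
#' @param stats a [droplet_stats()] result.
#' @param state the `system_state` the stats came from.
#' @param geom a `dimer_geometry`.
#' @param normal optional 3-vector plane normal.
#' @return list with `labels` (per dimer, NA outside the droplet), `normal`,
#'   `members`.
#' @export
assign_droplet_halves <- function(stats, state, geom = state$geom,
                                  normal = NULL) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  csd_row <- which(geom$role_code == 1)[1]
  sp <- sphere_positions(state, geom)
  pos <- sp[(seq_len(N) - 1) * 7 + csd_row, , drop = FALSE]
  members <- which(stats$inside)
  rel <- sweep(pos[members, , drop = FALSE], 2, stats$centroid)
  if (is.null(normal)) {
    normal <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE)$vectors[, 1]
  }
  normal <- normal / sqrt(sum(normal^2))
  side <- drop(rel %*% normal)
  labels <- rep(NA_character_, N)
  labels[members] <- ifelse(side >= 0, "A", "B")
  list(labels = labels, normal = normal, members = members)
}

#' Mixing index of droplet halves
#'
#' Quantifies how much two initially separated droplet halves have mixed: for
#' each of the two half-volumes (split through the current droplet centroid
#' by the stored plane normal), the imbalance between the labels is
#' 1 - |n_A - n_B| / (n_A + n_B); the index is the average over the two
#' halves.  0 = fully demixed (the t = 0 configuration), 1 = fully mixed.
#'
#' @param state a `system_state` at the later time.
#' @param halves the [assign_droplet_halves()] labelling from t = 0.
#' @param spec,geom forwarded to droplet detection at the later time.
#' @return mixing index in `[0, 1]`.
#' @export
mixing_index <- function(state, halves, spec = interaction_spec(),
                         geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  N <- nrow(state$dim_x)
  labelled <- which(!is.na(halves$labels))
  if (length(labelled) == 0) stop("droplet absent: no labelled dimers")
  csd_row <- which(geom$role_code == 1)[1]
  sp <- sphere_positions(state, geom)
  pos <- sp[(seq_len(N) - 1) * 7 + csd_row, , drop = FALSE]
  ctr <- colMeans(pos[labelled, , drop = FALSE])
  side <- drop(sweep(pos[labelled, , drop = FALSE], 2, ctr) %*% halves$normal)
  lab <- halves$labels[labelled]
  per_half <- vapply(c(1, -1), function(sgn) {
    sel <- if (sgn > 0) side >= 0 else side < 0
    na <- sum(lab[sel] == "A"); nb <- sum(lab[sel] == "B")
    if (na + nb == 0) return(NA_real_)
    1 - abs(na - nb) / (na + nb)
  }, 0)
  mean(per_half, na.rm = TRUE)
}

#' Mean single-bond residence time
#'
#' Mean duration of contiguous interaction events in a bond indicator series,
#' with censoring of events that touch either end of the observation window.
#'
#' @param series a `bond_event_series`, a logical/0-1 vector, or a logical
#'   matrix (frames x pairs).
#' @param interval sampling interval in tau (taken from the series object
#'   when available).
#' @return mean residence time in tau.
#' @export
residence_time <- function(series, interval = NULL) {
  if (inherits(series, "bond_event_series")) {
    interval <- interval %||% series$interval
    y <- series$y
  } else if (is.matrix(series)) {
    y <- series
  } else {
    y <- matrix(as.logical(series), ncol = 1)
  }
  interval <- interval %||% 1
  durs <- numeric()
  for (p in seq_len(ncol(y))) {
    r <- rle(as.logical(y[, p]))
    if (length(r$lengths) == 0) next
    on <- which(r$values)
    if (length(on) == 0) next
    # censor events touching the window boundaries
    on <- setdiff(on, c(if (r$values[1]) 1, if (r$values[length(r$values)]) length(r$values)))
    durs <- c(durs, r$lengths[on])
  }
  if (length(durs) == 0) stop("no binding observed")
  mean(durs) * interval
}
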