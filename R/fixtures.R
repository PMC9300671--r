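# Synthetic fixtures: configurations and bond series with known properties,
# so every observable is testable without running any physics.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# quaternion (w,x,y,z) from a proper rotation matrix
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

random_quaternion <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# orientation whose world frame coincides with the geometry's raw body frame:
# world offsets equal the COM-centred raw coordinates when R(q) equals the
# principal-axis matrix stored at geometry construction
identity_quaternion <- function(geom) {
  quat_from_matrix(geom$axes)
}

empty_state <- function(L, N, lx, boundary = "walls", geom = dimer_geometry()) {
  structure(list(
    time = 0, lx = lx, boundary = boundary,
    pol_x = matrix(0, L, 3), pol_v = matrix(0, L, 3),
    dim_x = matrix(0, N, 3), dim_q = matrix(rep(c(1, 0, 0, 0), each = N), N, 4),
    dim_v = matrix(0, N, 3), dim_l = matrix(0, N, 3),
    bonds = matrix(integer(), 0, 2), geom = geom,
    polymer = if (L > 0) polymer_spec(L = L) else polymer_spec(L = 0)),
    class = "system_state")
}

uniform_ball <- function(n, radius, centre) {
  u <- runif(n)^(1 / 3) * radius
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  sweep(v * u, 2, centre, `+`)
}

#' Generate a synthetic fixture
#'
#' Deterministic (seeded) construction of configurations and bond series with
#' known properties:
#' \describe{
#'   \item{uniform_gas}{`n` dimers uniform in the box (Poisson-like sub-box
#'     counts).}
#'   \item{dense_ball}{`n` dimers uniform in a ball of radius `radius` at the
#'     box centre.}
#'   \item{two_balls}{two dense balls of `n` and `n2` dimers separated by
#'     `sep` along x.}
#'   \item{straight_chain}{a straight polymer of `n` beads with spacing
#'     `spacing` through the box centre.}
#'   \item{ring_chain}{a circular polymer of `n` beads.}
#'   \item{coated_polymer}{a straight chain with one dimer per bead posed so
#'     that both CDs contact that bead (pure coating, every bead covered).}
#'   \item{telegraph_bonds}{a `bond_event_series` of `n` independent
#'     two-state Markov (telegraph) processes with switching rates `k_on`,
#'     `k_off`, sampled every `interval` tau for `frames` frames using the
#'     exact discrete-time transition probabilities.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param n primary count (dimers, beads or pairs).
#' @param lx box edge.
#' @param seed RNG seed.
#' @param radius,n2,radius2,sep,spacing,k_on,k_off,interval,frames
#'   kind-specific parameters.
#' @param geom a `dimer_geometry`.
#' @return a `system_state` or a `bond_event_series`.
#' @export
generate_fixture <- function(kind = c("uniform_gas", "dense_ball", "two_balls",
                                      "straight_chain", "ring_chain",
                                      "coated_polymer", "telegraph_bonds"),
                             n = 100, lx = 35, seed = 1,
                             radius = 5, n2 = 100, radius2 = radius, sep = 15,
                             spacing = 1, k_on = 0.01, k_off = 0.01,
                             interval = 1, frames = 1000,
                             geom = dimer_geometry()) {
  kind <- match.arg(kind)
  with_seed(seed, {
    switch(kind,
      uniform_gas = {
        st <- empty_state(0, n, lx, geom = geom)
        st$dim_x <- matrix(runif(3 * n, 1, lx - 1), n, 3)
        st$dim_q <- random_quaternion(n)
        st
      },
      dense_ball = {
        if (2 * radius > lx) stop("infeasible: ball larger than box")
        st <- empty_state(0, n, lx, geom = geom)
        st$dim_x <- uniform_ball(n, radius, rep(lx / 2, 3))
        st$dim_q <- random_quaternion(n)
        st
      },
      two_balls = {
        if (sep + radius + radius2 > lx) stop("infeasible: balls do not fit")
        st <- empty_state(0, n + n2, lx, geom = geom)
        c1 <- c(lx / 2 - sep / 2, lx / 2, lx / 2)
        c2 <- c(lx / 2 + sep / 2, lx / 2, lx / 2)
        st$dim_x <- rbind(uniform_ball(n, radius, c1),
                          uniform_ball(n2, radius2, c2))
        st$dim_q <- random_quaternion(n + n2)
        st
      },
      straight_chain = {
        st <- empty_state(n, 0, max(lx, (n + 1) * spacing), geom = geom)
        st$pol_x <- cbind(seq_len(n) * spacing, st$lx / 2, st$lx / 2)
        st
      },
      ring_chain = {
        r <- n * spacing / (2 * pi)
        st <- empty_state(n, 0, max(lx, 3 * r), geom = geom)
        th <- 2 * pi * (seq_len(n) - 1) / n
        st$pol_x <- cbind(st$lx / 2 + r * cos(th), st$lx / 2 + r * sin(th),
                          st$lx / 2)
        st
      },
      coated_polymer = {
        st <- empty_state(n, n, max(lx, n + 2), geom = geom)
        st$pol_x <- cbind(seq_len(n), st$lx / 2, st$lx / 2)
        # dimer posed with its raw body frame aligned to the world axes and
        # the CSD "above" the bead, so both CDs contact the same bead
        q0 <- identity_quaternion(geom)
        h <- 0.8
        csd <- geom$coords[which(geom$role_code == 1)[1], ]
        for (d in seq_len(n)) {
          st$dim_x[d, ] <- st$pol_x[d, ] + c(0, h, 0) + (geom$com - csd)
          st$dim_q[d, ] <- q0
        }
        st
      },
      telegraph_bonds = {
        K <- k_on + k_off
        p_on <- k_on / K
        # exact sampled-chain transition probabilities over one interval
        decay <- exp(-K * interval)
        p01 <- p_on * (1 - decay)        # off -> on
        p10 <- (1 - p_on) * (1 - decay)  # on -> off
        y <- matrix(FALSE, frames, n)
        y[1, ] <- runif(n) < p_on
        for (f in 2:frames) {
          u <- runif(n)
          y[f, ] <- ifelse(y[f - 1, ], u >= p10, u < p01)
        }
        bond_event_series(y, interval = interval, n_dimers = n)
      })
  })
}
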