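# File formats: TOML-subset configuration, extended XYZ and LAMMPS-dump
# trajectories, exact-restart text checkpoints, tidy CSV observables.

#' Read a TOML-subset configuration file
#'
#' Supports the subset needed for run configuration: `[section]` headers,
#' `key = value` pairs with string, number, boolean and flat-array values,
#' `#` comments.
#'
#' @param path file path.
#' @return nested named list (one element per section).
#' @export
read_config_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok %in% c("true", "false")) return(tok == "true")
    num <- suppressWarnings(as.numeric(tok))
    if (!is.na(num)) return(num)
    tok
  }
  for (k in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[k])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("parse error at line %d of %s: expected key = value", k, path))
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      toks <- strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]
      vals <- lapply(toks, parse_scalar)
      if (all(vapply(vals, is.numeric, TRUE))) unlist(vals) else vals
    } else parse_scalar(val)
    if (is.null(section)) out[[key]] <- parsed else out[[section]][[key]] <- parsed
  }
  out
}

#' Build run objects from a configuration
#'
#' Maps a configuration list (from [read_config_toml()]) onto the package's
#' constructor objects.  Recognised sections: `[system]` (N, L, lx, boundary,
#' seed), `[forcefield]` (variant, eps_hh, eps_hc and any potential
#' parameter), `[dynamics]` (dt, gamma, kT, skin, seed), `[geometry]`
#' (`file` = whitespace-separated table `role x y z`).
#'
#' @param cfg list from [read_config_toml()] or a path to a TOML file.
#' @return list with `composition`, `polymer`, `spec`, `params`, `geom`.
#' @export
configure_run <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config_toml(cfg)
  sys <- cfg$system %||% list()
  comp <- system_composition(
    N = sys$N %||% 1000, L = sys$L %||% 1000, lx = sys$lx %||% 35,
    boundary = sys$boundary %||% "walls", seed = sys$seed %||% 1)
  ffc <- cfg$forcefield %||% list()
  args <- ffc[names(ffc) %in% names(formals(interaction_spec))]
  spec <- do.call(interaction_spec, args)
  pol <- polymer_spec(L = comp$L, fene_k = spec$fene_k,
                      fene_r0 = spec$fene_r0, k_bend = spec$k_bend)
  dyn <- cfg$dynamics %||% list()
  params <- langevin_params(dt = dyn$dt %||% 0.001, gamma = dyn$gamma %||% 1,
                            kT = dyn$kT %||% 1, skin = dyn$skin %||% 0.3,
                            seed = dyn$seed %||% comp$seed)
  geom <- if (!is.null(cfg$geometry$file))
    read_geometry_table(cfg$geometry$file) else dimer_geometry()
  list(composition = comp, polymer = pol, spec = spec, params = params,
       geom = geom)
}

#' Read a dimer geometry from a coordinate table
#'
#' Whitespace-separated text with one sphere per line: `role x y z`.
#'
#' @param path file path.
#' @return a [dimer_geometry()].
#' @export
read_geometry_table <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 4) stop("geometry table must have columns: role x y z")
  coords <- unname(as.matrix(tab[, 2:4]))
  dimer_geometry(coords = coords, roles = tab[, 1])
}

role_letter <- c(P = 0, S = 1, C = 2, H = 3, N = 4)

frame_atoms <- function(state, geom = state$geom) {
  if (is.null(geom)) geom <- dimer_geometry()
  L <- nrow(state$pol_x); N <- nrow(state$dim_x)
  pos <- rbind(state$pol_x, if (N > 0) sphere_positions(state, geom))
  type <- c(rep(0L, L), rep(geom$role_code, N))
  data.frame(id = seq_len(nrow(pos)), type = type,
             role = names(role_letter)[type + 1],
             x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Write a trajectory
#'
#' `"xyz"` writes extended XYZ (atom count; comment line with `time=`,
#' `lx=`; then `role x y z` per sphere).  `"lammps"` writes a LAMMPS-dump
#' dialect readable by standard MD analysis tools (`ITEM: ATOMS id type x y
#' z qw qx qy qz`, quaternion columns populated for dimer CSD rows and zero
#' otherwise).
#'
#' @param frames a list of `system_state` frames (or a `sim_result`).
#' @param path output file.
#' @param format `"xyz"` or `"lammps"`.
#' @return `path` invisibly.
#' @export
write_trajectory <- function(frames, path, format = c("xyz", "lammps")) {
  format <- match.arg(format)
  if (inherits(frames, "sim_result")) frames <- frames$frames
  times <- vapply(frames, function(f) f$time, 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    at <- frame_atoms(fr)
    if (format == "xyz") {
      writeLines(as.character(nrow(at)), con)
      writeLines(sprintf("time=%.10f lx=%.10f boundary=%s", fr$time, fr$lx,
                         fr$boundary), con)
      writeLines(sprintf("%s %.10f %.10f %.10f", at$role, at$x, at$y, at$z), con)
    } else {
      writeLines("ITEM: TIMESTEP", con)
      writeLines(as.character(round(fr$time * 1000)), con)
      writeLines("ITEM: NUMBER OF ATOMS", con)
      writeLines(as.character(nrow(at)), con)
      writeLines("ITEM: BOX BOUNDS ff ff ff", con)
      writeLines(rep(sprintf("%.10f %.10f", 0, fr$lx), 3), con)
      writeLines("ITEM: ATOMS id type x y z qw qx qy qz", con)
      q <- matrix(0, nrow(at), 4)
      L <- nrow(fr$pol_x); N <- nrow(fr$dim_x)
      if (N > 0) {
        csd_row <- which((fr$geom %||% dimer_geometry())$role_code == 1)[1]
        q[L + (seq_len(N) - 1) * 7 + csd_row, ] <- fr$dim_q
      }
      writeLines(sprintf("%d %d %.10f %.10f %.10f %.10f %.10f %.10f %.10f",
                         at$id, at$type + 1L, at$x, at$y, at$z,
                         q[, 1], q[, 2], q[, 3], q[, 4]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory
#'
#' @param path file path.
#' @param format `"xyz"` or `"lammps"`.
#' @return list of frames; each has `time`, and an `atoms` data.frame with
#'   `role`/`type`, `x`, `y`, `z` (plus quaternions for the LAMMPS dialect).
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1
  fail <- function(msg, ln) stop(sprintf("parse error at line %d of %s: %s", ln, path, msg))
  if (format == "xyz") {
    while (i <= length(lines)) {
      if (trimws(lines[i]) == "") { i <- i + 1; next }
      n <- suppressWarnings(as.integer(lines[i]))
      if (is.na(n)) fail("expected atom count", i)
      if (i + 1 > length(lines)) fail("missing comment line", i + 1)
      hdr <- lines[i + 1]
      tm <- as.numeric(sub(".*time=([0-9eE.+-]+).*", "\\1", hdr))
      if (i + 1 + n > length(lines)) fail("truncated frame", length(lines))
      rows <- lines[(i + 2):(i + 1 + n)]
      toks <- strsplit(trimws(rows), "\\s+")
      bad <- which(vapply(toks, length, 0L) != 4)
      if (length(bad)) fail("expected 'role x y z'", i + 1 + bad[1])
      at <- data.frame(role = vapply(toks, `[`, "", 1),
                       x = as.numeric(vapply(toks, `[`, "", 2)),
                       y = as.numeric(vapply(toks, `[`, "", 3)),
                       z = as.numeric(vapply(toks, `[`, "", 4)))
      frames[[length(frames) + 1]] <- list(time = tm, atoms = at)
      i <- i + 2 + n
    }
  } else {
    at_line <- function(k) if (k >= 1 && k <= length(lines)) lines[k] else ""
    while (i <= length(lines)) {
      if (trimws(lines[i]) == "") { i <- i + 1; next }
      if (!startsWith(lines[i], "ITEM: TIMESTEP")) fail("expected ITEM: TIMESTEP", i)
      step <- as.numeric(at_line(i + 1))
      if (!startsWith(at_line(i + 2), "ITEM: NUMBER OF ATOMS"))
        fail("expected ITEM: NUMBER OF ATOMS", i + 2)
      n <- as.integer(at_line(i + 3))
      if (is.na(n)) fail("expected atom count", i + 3)
      i2 <- i + 4
      if (!startsWith(at_line(i2), "ITEM: BOX BOUNDS")) fail("expected ITEM: BOX BOUNDS", i2)
      i2 <- i2 + 4
      if (!startsWith(at_line(i2), "ITEM: ATOMS")) fail("expected ITEM: ATOMS", i2)
      if (i2 + n > length(lines)) fail("truncated frame", length(lines))
      toks <- strsplit(trimws(lines[(i2 + 1):(i2 + n)]), "\\s+")
      ncol <- length(strsplit(trimws(sub("ITEM: ATOMS", "", lines[i2])), "\\s+")[[1]])
      bad <- which(vapply(toks, length, 0L) != ncol)
      if (length(bad)) fail("wrong column count in ATOMS row", i2 + bad[1])
      m <- do.call(rbind, lapply(toks, as.numeric))
      at <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4], z = m[, 5])
      if (ncol >= 9) { at$qw <- m[, 6]; at$qx <- m[, 7]; at$qy <- m[, 8]; at$qz <- m[, 9] }
      frames[[length(frames) + 1]] <- list(time = step / 1000, atoms = at)
      i <- i2 + n + 1
    }
  }
  frames
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write an exact-restart checkpoint
#'
#' Plain-text key/value format with 17-significant-digit doubles (exact IEEE
#' round trip) and the hex-encoded noise-stream state, so a restarted run
#' continues the original trajectory bitwise.
#'
#' @param state a `system_state`.
#' @param path output file.
#' @param rng_state optional 64-char hex RNG state (from [run_dynamics()]).
#' @return `path` invisibly.
#' @export
write_checkpoint <- function(state, path, rng_state = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bipsim checkpoint v1", con)
  writeLines(paste("time", fmt17(state$time)), con)
  writeLines(paste("lx", fmt17(state$lx)), con)
  writeLines(paste("boundary", state$boundary), con)
  if (!is.null(rng_state)) writeLines(paste("rng_state", rng_state), con)
  wmat <- function(name, m) {
    writeLines(paste(name, nrow(m)), con)
    if (nrow(m)) writeLines(apply(m, 1, function(r) paste(fmt17(r), collapse = " ")), con)
  }
  wmat("pol_x", state$pol_x); wmat("pol_v", state$pol_v)
  wmat("dim_x", state$dim_x); wmat("dim_q", state$dim_q)
  wmat("dim_v", state$dim_v); wmat("dim_l", state$dim_l)
  writeLines(paste("bonds", nrow(state$bonds)), con)
  if (nrow(state$bonds))
    writeLines(apply(state$bonds, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an exact-restart checkpoint
#'
#' @param path checkpoint file.
#' @param geom geometry to attach to the state.
#' @return a `system_state`; the RNG state (if present) is in
#'   `attr(, "rng_state")`.
#' @export
read_checkpoint <- function(path, geom = dimer_geometry()) {
  lines <- readLines(path, warn = FALSE)
  i <- 2
  kv <- function() strsplit(lines[i], " ", fixed = TRUE)[[1]]
  st <- list()
  rng <- NULL
  while (i <= length(lines)) {
    p <- kv()
    key <- p[1]
    if (key %in% c("pol_x", "pol_v", "dim_x", "dim_q", "dim_v", "dim_l", "bonds")) {
      n <- as.integer(p[2])
      m <- if (n > 0) {
        do.call(rbind, lapply(lines[(i + 1):(i + n)],
                              function(l) as.numeric(strsplit(l, " ")[[1]])))
      } else matrix(numeric(), 0, if (key == "dim_q") 4 else if (key == "bonds") 2 else 3)
      if (key == "bonds") m <- matrix(as.integer(m), ncol = 2)
      st[[key]] <- m
      i <- i + n + 1
    } else {
      val <- p[2]
      if (key == "time") st$time <- as.numeric(val)
      else if (key == "lx") st$lx <- as.numeric(val)
      else if (key == "boundary") st$boundary <- val
      else if (key == "rng_state") rng <- val
      i <- i + 1
    }
  }
  st$geom <- geom
  st$polymer <- polymer_spec(L = nrow(st$pol_x))
  class(st) <- "system_state"
  if (!is.null(rng)) attr(st, "rng_state") <- rng
  st
}

#' Write tidy observable rows
#'
#' One row per measurement: run metadata columns (seed, energies, N),
#' observable name, value and standard error.
#'
#' @param df data.frame in the tidy layout.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_observables_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
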