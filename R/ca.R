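#' Per-sweep event probabilities for the cellular automaton
#'
#' @param a A valid `click_assembly`.
#' @param kill Named numeric: per-kill-edge kill probability per contact per
#'   sweep, names `"killer-|victim"`.
#' @param reproduction Named numeric: per-population probability of copying
#'   into an empty neighbor.
#' @param maturation Named numeric: per-maturation-edge probability per
#'   sweep, names by source population.
#' @param death Named numeric: per-population spontaneous death probability.
#' @param help_level Help level h; reproduction of help-sensitive
#'   populations is scaled to `min(1, p * (1 + beta * h))`.
#' @return A list of class `ca_rates`; all probabilities verified in
#'   \[0, 1\] after the help modifier.
#' @seealso [map_ode_rates_to_ca()] for the documented ODE-to-CA mapping.
#' @export
ca_rates <- function(a, kill, reproduction, maturation, death,
                     help_level = NULL) {
  ids <- a$populations$id
  beta <- stats::setNames(a$populations$help_coefficient, ids)
  h <- help_vector(a, help_level)
  reproduction <- pmin(1, reproduction[ids] * (1 + beta * h))
  ek <- paste0(a$kill_edges$killer, "-|", a$kill_edges$victim)
  kill <- if (length(ek)) kill[ek] else numeric(0)
  maturation <- if (nrow(a$maturation_edges))
    maturation[a$maturation_edges$source] else numeric(0)
  death <- death[ids]
  all_p <- c(kill, reproduction, maturation, death)
  if (any(!is.finite(all_p)) || any(all_p < 0) || any(all_p > 1))
    stop("all CA probabilities must lie in [0, 1] after the help modifier")
  structure(list(kill = stats::setNames(as.numeric(kill), ek),
                 reproduction = stats::setNames(as.numeric(reproduction), ids),
                 maturation = stats::setNames(as.numeric(maturation),
                                              a$maturation_edges$source),
                 death = stats::setNames(as.numeric(death), ids)),
            class = "ca_rates")
}

#' Map mean-field ODE rates to CA per-sweep probabilities
#'
#' One sweep corresponds to a time step `dt`; each rate becomes the
#' probability `rate * dt`. By default `dt` is chosen so the largest
#' resulting probability is 0.5, keeping the discretization well inside
#' \[0, 1\]. In the well-mixed limit the automaton's expected per-sweep
#' dynamics then match [build_rhs()] with time measured in sweeps of
#' length `dt`.
#'
#' @param a A valid `click_assembly`.
#' @param help_level Optional help level override (applied through the
#'   growth term, as in the ODE backend).
#' @param dt Optional explicit time step per sweep.
#' @return A `ca_rates` list; the chosen `dt` is attached as attribute
#'   `"dt"`.
#' @export
map_ode_rates_to_ca <- function(a, help_level = NULL, dt = NULL) {
  ids <- a$populations$id
  beta <- stats::setNames(a$populations$help_coefficient, ids)
  h <- help_vector(a, help_level)
  growth <- a$populations$growth_rate * (1 + beta * h)
  rates <- c(growth, a$populations$death_rate, a$kill_edges$kill_rate,
             a$maturation_edges$rate)
  if (is.null(dt)) {
    mx <- max(rates, 0)
    dt <- if (mx > 0) 0.5 / mx else 1
  }
  r <- ca_rates(a,
    kill = stats::setNames(a$kill_edges$kill_rate * dt,
                           paste0(a$kill_edges$killer, "-|",
                                  a$kill_edges$victim)),
    reproduction = stats::setNames(a$populations$growth_rate * dt, ids),
    maturation = stats::setNames(a$maturation_edges$rate * dt,
                                 a$maturation_edges$source),
    death = stats::setNames(a$populations$death_rate * dt, ids),
    help_level = help_level)
  attr(r, "dt") <- dt
  r
}

#' Initialize a lattice for the spatial backend
#'
#' Places cells i.i.d. per site according to `densities` (remaining mass is
#' empty). The same seed always yields the identical lattice.
#'
#' @param a A valid `click_assembly`.
#' @param width,height Lattice dimensions (>= 4).
#' @param densities Named fractions per population id, summing to <= 1.
#' @param seed Integer RNG seed, recorded on the lattice.
#' @return A `click_lattice`: list with `states` (height x width integer
#'   matrix of codes, 0 = empty, k = k-th population), `ids`, `rng_seed`,
#'   `generation`.
#' @export
init_lattice <- function(a, width, height, densities, seed = 0L) {
  stopifnot(width >= 4L, height >= 4L)
  ids <- a$populations$id
  dens <- stats::setNames(numeric(length(ids)), ids)
  dens[names(densities)] <- unlist(densities)
  if (any(dens < 0) || sum(dens) > 1 + 1e-12)
    stop("densities must be non-negative and sum to <= 1")
  draws <- with_preserved_rng({
    set.seed(seed)
    sample.int(length(ids) + 1L, width * height, replace = TRUE,
               prob = c(pmin(dens, 1), max(0, 1 - sum(dens))))
  })
  codes <- ifelse(draws == length(ids) + 1L, 0L, draws)  # last slot = empty
  structure(list(states = matrix(codes, nrow = height, ncol = width),
                 ids = ids, rng_seed = as.integer(seed), generation = 0L),
            class = "click_lattice")
}

#' @export
print.click_lattice <- function(x, ...) {
  n <- length(x$states)
  occ <- tabulate(x$states, nbins = length(x$ids))
  cat(sprintf("click lattice %dx%d (generation %d, seed %d)\n",
              nrow(x$states), ncol(x$states), x$generation, x$rng_seed))
  cat("  occupied fractions:",
      paste(sprintf("%s=%.3f", x$ids, occ / n), collapse = ", "),
      sprintf("empty=%.3f\n", 1 - sum(occ) / n))
  invisible(x)
}

ca_rate_tables <- function(a, r) {
  ids <- a$populations$id
  n <- length(ids)
  kill_edge_m <- matrix(0L, n, n); kill_prob_m <- matrix(0, n, n)
  ke <- a$kill_edges
  for (i in seq_len(nrow(ke))) {
    ki <- match(ke$killer[i], ids); vi <- match(ke$victim[i], ids)
    kill_edge_m[ki, vi] <- 1L
    kill_prob_m[ki, vi] <- r$kill[paste0(ke$killer[i], "-|", ke$victim[i])]
  }
  mat_prob <- numeric(n); mat_target <- integer(n)
  me <- a$maturation_edges
  for (i in seq_len(nrow(me))) {
    si <- match(me$source[i], ids)
    mat_prob[si] <- r$maturation[me$source[i]]
    mat_target[si] <- match(me$target[i], ids)
  }
  list(kill_edge = kill_edge_m, kill_prob = kill_prob_m,
       rep_prob = as.numeric(r$reproduction[ids]),
       mat_prob = mat_prob, mat_target = mat_target,
       death_prob = as.numeric(r$death[ids]))
}

#' Advance the lattice by one sweep
#'
#' One sweep is `width * height` random-sequential single-site contact
#' updates (focal site uniform with replacement; uniform von Neumann
#' neighbor on the torus; kill, else reproduction into an empty neighbor),
#' followed by an independent per-site demographic pass (maturation, then
#' spontaneous death). In every kill resolution exactly one site changes:
#' the victim empties, the killer survives.
#'
#' @param l A `click_lattice`.
#' @param a The `click_assembly` the lattice belongs to.
#' @param r A `ca_rates` list.
#' @param sweeps Number of sweeps to advance (default 1).
#' @return The advanced `click_lattice` (generation counter incremented).
#' @export
step_ca <- function(l, a, r, sweeps = 1L) {
  if (any(!(l$states %in% c(0L, seq_along(l$ids)))))
    stop("lattice contains unknown state codes")
  tabs <- ca_rate_tables(a, r)
  out <- with_preserved_rng({
    set.seed(l$rng_seed + l$generation)
    ca_run_cpp(l$states, as.integer(sweeps), tabs$kill_edge, tabs$kill_prob,
               tabs$rep_prob, tabs$mat_prob, tabs$mat_target, tabs$death_prob)
  })
  l$states <- out$grid
  l$generation <- l$generation + as.integer(sweeps)
  l
}

#' Run the spatial stochastic backend
#'
#' Advances the lattice `sweeps` sweeps and records the occupied fraction of
#' every population after each sweep. The run is fully reproducible from
#' (assembly, rates, initial lattice, its seed).
#'
#' @param a A valid `click_assembly`.
#' @param r A `ca_rates` list.
#' @param l0 Initial `click_lattice` from [init_lattice()].
#' @param sweeps Number of sweeps (>= 1).
#' @return A `click_trajectory` with backend tag `"ca"`; times are sweep
#'   indices `0:sweeps` (row 0 is the initial lattice) and abundances are
#'   occupied fractions. The final lattice is attached as attribute
#'   `"lattice"`.
#' @export
run_ca <- function(a, r, l0, sweeps) {
  stopifnot(sweeps >= 1L)
  if (any(!(l0$states %in% c(0L, seq_along(l0$ids)))))
    stop("lattice contains unknown state codes")
  tabs <- ca_rate_tables(a, r)
  n_sites <- length(l0$states)
  out <- with_preserved_rng({
    set.seed(l0$rng_seed + l0$generation)
    ca_run_cpp(l0$states, as.integer(sweeps), tabs$kill_edge, tabs$kill_prob,
               tabs$rep_prob, tabs$mat_prob, tabs$mat_target, tabs$death_prob)
  })
  counts0 <- tabulate(l0$states, nbins = length(l0$ids))
  ab <- rbind(counts0, out$counts) / n_sites
  colnames(ab) <- l0$ids
  rownames(ab) <- NULL
  lat <- l0
  lat$states <- out$grid
  lat$generation <- l0$generation + as.integer(sweeps)
  traj <- new_trajectory(times = 0:sweeps, abundances = ab,
    metadata = list(backend = "ca", assembly = fingerprint(unclass(a)),
                    seed = l0$rng_seed, sweeps = sweeps,
                    width = ncol(l0$states), height = nrow(l0$states),
                    rates = unclass(r)))
  attr(traj, "lattice") <- lat
  traj
}

#' Write a lattice snapshot
#'
#' Two plain-text formats: `"grid"` writes one character per site (`.` for
#' empty, the first letter of each population id otherwise, falling back to
#' population indices when first letters collide) under a `#` header with
#' dimensions, codes, seed and generation; `"rle"` writes a JSON record with
#' the same metadata and the column-major state sequence run-length encoded
#' as `[code, length]` pairs.
#'
#' @param l A `click_lattice`.
#' @param path Output path.
#' @param format `"grid"` (default) or `"rle"`.
#' @return `path`, invisibly.
#' @seealso [read_lattice()]
#' @export
write_lattice <- function(l, path, format = c("grid", "rle")) {
  format <- match.arg(format)
  if (format == "rle") {
    codes <- as.integer(l$states)
    ends <- c(which(diff(codes) != 0L), length(codes))
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    runs <- mapply(function(s, e) c(codes[s], e - s + 1L), starts, ends,
                   SIMPLIFY = FALSE)
    jsonlite::write_json(list(height = nrow(l$states), width = ncol(l$states),
                              ids = l$ids, rng_seed = l$rng_seed,
                              generation = l$generation, runs = runs),
                         path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  chars <- substr(l$ids, 1L, 1L)
  if (anyDuplicated(chars)) chars <- as.character(seq_along(l$ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lattice %dx%d seed %d generation %d codes %s",
                     nrow(l$states), ncol(l$states), l$rng_seed,
                     l$generation,
                     paste(sprintf("%s=%s", chars, l$ids), collapse = ",")),
             con)
  sym <- c(".", chars)
  for (i in seq_len(nrow(l$states)))
    writeLines(paste(sym[l$states[i, ] + 1L], collapse = ""), con)
  invisible(path)
}

#' Read a run-length-encoded lattice snapshot
#'
#' @param path Path to a file written by `write_lattice(format = "rle")`.
#' @return A `click_lattice`.
#' @export
read_lattice <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  runs <- if (is.matrix(x$runs)) x$runs else do.call(rbind, x$runs)
  codes <- rep(as.integer(runs[, 1L]), times = as.integer(runs[, 2L]))
  if (length(codes) != x$height * x$width)
    stop("run-length data does not match the recorded dimensions")
  structure(list(states = matrix(codes, nrow = x$height, ncol = x$width),
                 ids = x$ids, rng_seed = as.integer(x$rng_seed),
                 generation = as.integer(x$generation)),
            class = "click_lattice")
}

#' Minimum separation between non-adjacent polyline segments
#'
#' Utility behind the return-map overlap statistic: the smallest distance
#' between any two non-adjacent, non-degenerate segments of the path
#' `(x[i], y[i]) -> (x[i+1], y[i+1])`; zero if any two such segments cross.
#'
#' @param x,y Coordinate vectors of equal length (>= 4 points).
#' @return Minimum separation, or `NA` if fewer than two usable segments.
#' @export
min_segment_separation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  min_segment_separation_cpp(as.numeric(x), as.numeric(y))
}
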