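#' Classify the attractor reached by a trajectory
#'
#' Labels the long-run regime from the tail of a trajectory:
#' \describe{
#'   \item{`extinct`}{every population's tail mean is below the extinction
#'     threshold;}
#'   \item{`non_stationary`}{the tail coefficient of variation of any
#'     non-negligible population exceeds `cv_threshold` (the trajectory has
#'     not settled);}
#'   \item{`<id>_dominant`}{the most abundant population exceeds the
#'     runner-up by at least `dominance_margin` (for the canonical 4-click
#'     these are `Tr1_dominant` and `Tc_dominant`);}
#'   \item{`coexistence`}{otherwise.}
#' }
#'
#' @param traj A `click_trajectory`.
#' @param tail_fraction Fraction of the trajectory (from the end) used for
#'   the tail statistics, in (0, 1\].
#' @param dominance_margin Dominance requires top >= margin * runner-up
#'   (default 2).
#' @param cv_threshold Tail coefficient-of-variation threshold for the
#'   non-stationary label (default 0.1); applied to populations whose tail
#'   mean exceeds 1e-4 so that noise around extinct populations is ignored.
#' @param extinction_threshold Abundance below which a population counts as
#'   lost (default 1e-8).
#' @return List of class `attractor_label` with `label`, `dominant_id`
#'   (or `NA`), `final_state` and `tail_mean`.
#' @export
classify_attractor <- function(traj, tail_fraction = 0.2,
                               dominance_margin = 2, cv_threshold = 0.1,
                               extinction_threshold = 1e-8) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  ab <- traj$abundances
  if (is.null(dim(ab)) || nrow(ab) == 0L) stop("empty trajectory")
  n_tail <- max(2L, ceiling(nrow(ab) * tail_fraction))
  tail_ab <- ab[seq(nrow(ab) - n_tail + 1L, nrow(ab)), , drop = FALSE]
  mu <- colMeans(tail_ab)
  final <- ab[nrow(ab), ]
  lab <- function(label, dom = NA_character_)
    structure(list(label = label, dominant_id = dom, final_state = final,
                   tail_mean = mu), class = "attractor_label")
  if (all(mu < extinction_threshold)) return(lab("extinct"))
  live <- mu > 1e-4
  if (any(live)) {
    cv <- apply(tail_ab[, live, drop = FALSE], 2L, stats::sd) / mu[live]
    if (any(cv > cv_threshold)) return(lab("non_stationary"))
  }
  ord <- order(mu, decreasing = TRUE)
  top <- names(mu)[ord[1L]]
  runner <- if (length(mu) > 1L) mu[ord[2L]] else 0
  if (mu[ord[1L]] >= dominance_margin * runner)
    return(lab(paste0(top, "_dominant"), top))
  lab("coexistence", top)
}

#' @export
print.attractor_label <- function(x, ...) {
  cat(sprintf("attractor: %s", x$label))
  if (!is.na(x$dominant_id)) cat(sprintf(" (dominant: %s)", x$dominant_id))
  cat("\n  tail mean:", paste(sprintf("%s=%.4f", names(x$tail_mean),
                                      x$tail_mean), collapse = ", "), "\n")
  invisible(x)
}

#' Scan the bystander help level and classify each regime
#'
#' For each help level in `h_grid`, integrates the assembly with every
#' bystander input set to that level, classifies the attractor, and (when
#' `lyapunov = TRUE`) attaches the twin-trajectory largest-Lyapunov
#' estimate. Deterministic given its inputs; solver failures are recorded
#' per grid point rather than aborting the scan.
#'
#' @param a A valid `click_assembly`.
#' @param h_grid Strictly increasing non-negative help levels.
#' @param params An [ode_params()] list.
#' @param init Optional initial abundance vector shared by all grid points.
#' @param lyapunov Logical; also estimate the sensitivity measure per point.
#' @param ... Passed to [classify_attractor()].
#' @return A `bifurcation_scan`: list with `help_values`, `labels`
#'   (character), `lyapunov` (numeric or `NA`), `final_states` (matrix) and
#'   `failed` (logical).
#' @export
scan_bystander_help <- function(a, h_grid, params = ode_params(),
                                init = NULL, lyapunov = TRUE, ...) {
  if (length(h_grid) == 0L)
    return(structure(list(help_values = numeric(0), labels = character(0),
                          lyapunov = numeric(0),
                          final_states = matrix(numeric(0), 0,
                                                nrow(a$populations),
                                                dimnames = list(NULL, a$populations$id)),
                          failed = logical(0)),
                     class = "bifurcation_scan"))
  if (any(diff(h_grid) <= 0) || any(h_grid < 0))
    stop("h_grid must be strictly increasing and non-negative")
  n <- length(h_grid)
  labels <- character(n); lam <- rep(NA_real_, n); failed <- logical(n)
  finals <- matrix(NA_real_, n, nrow(a$populations),
                   dimnames = list(NULL, a$populations$id))
  for (i in seq_len(n)) {
    res <- tryCatch({
      traj <- simulate_ode(a, params, init = init, help_level = h_grid[i])
      cls <- classify_attractor(traj, ...)
      list(label = cls$label, final = cls$final_state)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed[i] <- TRUE; labels[i] <- "failure"
      next
    }
    labels[i] <- res$label
    finals[i, ] <- res$final
    if (lyapunov)
      lam[i] <- tryCatch(
        lyapunov_estimate(a, params, init = init, help_level = h_grid[i]),
        error = function(e) NA_real_)
  }
  structure(list(help_values = h_grid, labels = labels, lyapunov = lam,
                 final_states = finals, failed = failed),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("bystander-help scan over %d levels\n", length(x$help_values)))
  df <- data.frame(h = x$help_values, label = x$labels, lyapunov = x$lyapunov)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabulate a bifurcation scan
#'
#' @param x A `bifurcation_scan`.
#' @param ... Unused.
#' @return `data.frame` with one row per help level.
#' @export
as.data.frame.bifurcation_scan <- function(x, ...) {
  cbind(data.frame(help = x$help_values, label = x$labels,
                   lyapunov = x$lyapunov, failed = x$failed),
        as.data.frame(x$final_states))
}

#' Delay return map of a trajectory
#'
#' For each population, pairs the trajectory with itself at a lag of `lag`
#' output-grid steps (the "time + 1 vs time" plot). Two overlap statistics
#' are computed, each a minimum distance between non-adjacent segments of a
#' traced path, normalized by the data range:
#' \describe{
#'   \item{`overlap` (scalar)}{on the joint delay path through all
#'     populations' delay coordinates at once. A periodic trajectory
#'     retraces this path exactly (statistic 0); a chaotic transition never
#'     does, so a strictly positive value marks non-overlapping paths.}
#'   \item{`overlap_by_population`}{on each population's planar
#'     (x_t, x_{t+lag}) curve separately; planar projections of
#'     higher-dimensional dynamics may cross transversally, making these
#'     zero even for aperiodic paths.}
#' }
#' Degenerate (zero-length) segments, which arise once a trajectory has
#' settled onto a fixed point, are excluded from both statistics.
#'
#' @param traj A `click_trajectory`.
#' @param lag Lag in output-grid steps (>= 1, < number of samples).
#' @param t_window Optional `c(t_min, t_max)` restricting the map to a time
#'   window (e.g. a transition window).
#' @return A `return_map`: list with `lag`, per-population `points`
#'   (two-column matrices of (x_t, x_{t+lag})), `overlap` (scalar joint
#'   statistic) and `overlap_by_population` (named numeric); statistics are
#'   `NA` when fewer than four usable segments remain.
#' @export
return_map <- function(traj, lag = 1L, t_window = NULL) {
  ab <- traj$abundances
  times <- traj$times
  if (!is.null(t_window)) {
    keep <- times >= t_window[1L] & times <= t_window[2L]
    ab <- ab[keep, , drop = FALSE]
    times <- times[keep]
  }
  T_len <- nrow(ab)
  if (lag < 1L || lag >= T_len) stop("lag must satisfy 1 <= lag < T")
  ids <- colnames(ab)
  pts <- list(); by_pop <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    x <- ab[, id]
    p <- cbind(x_t = x[seq_len(T_len - lag)],
               x_lag = x[seq_len(T_len - lag) + lag])
    pts[[id]] <- p
    rng <- diff(range(x))
    if (nrow(p) >= 5L && rng > 0)
      by_pop[id] <- min_segment_separation(p[, 1L], p[, 2L]) / rng
  }
  joint <- do.call(cbind, pts)
  rng_joint <- sqrt(sum(apply(ab, 2L, function(x) diff(range(x)))^2))
  overlap <- if (nrow(joint) >= 5L && rng_joint > 0)
    min_segment_separation_nd_cpp(unname(joint)) / rng_joint else NA_real_
  structure(list(lag = lag, points = pts, overlap = overlap,
                 overlap_by_population = by_pop),
            class = "return_map")
}

#' Largest-Lyapunov estimate by twin-trajectory divergence
#'
#' Integrates the assembly from `init` and from `init + eps * u` (unit
#' vector `u`, by default the diagonal direction), then fits log separation
#' against time by least squares over the pre-saturation window: from the
#' start until the separation first exceeds 1e-2 of the running state norm
#' (the saturation guard) or the horizon ends. The slope estimates the
#' largest finite-time Lyapunov exponent per unit time: negative at a stable
#' fixed point, positive when nearby states diverge exponentially, as during
#' a chaotic transition or a passage along a saddle's unstable manifold.
#'
#' @param a A valid `click_assembly`.
#' @param params An [ode_params()] list; `params$t_end` is the horizon.
#' @param init Optional initial abundance vector.
#' @param eps Perturbation magnitude (default 1e-6); must be small relative
#'   to the initial state norm.
#' @param help_level Optional scalar overriding the bystander help level.
#' @param direction Optional perturbation direction (normalized internally).
#' @param transient_fraction Leading fraction of the pre-saturation window
#'   discarded before the fit (default 0.3), so the estimate reflects the
#'   established exponential rate rather than the initial alignment
#'   transient.
#' @return The fitted slope (per unit time). Returns `NaN` (with a warning)
#'   when the separation sits at the solver noise floor and no meaningful
#'   fit exists.
#' @export
lyapunov_estimate <- function(a, params = ode_params(), init = NULL,
                              eps = 1e-6, help_level = NULL,
                              direction = NULL, transient_fraction = 0.3) {
  stopifnot(eps > 0, transient_fraction >= 0, transient_fraction < 1)
  ids <- a$populations$id
  if (is.null(init)) init <- stats::setNames(a$populations$initial_abundance, ids)
  init <- as.numeric(init)
  if (is.null(direction)) direction <- rep(1, length(init))
  u <- direction / sqrt(sum(direction^2))
  t1 <- simulate_ode(a, params, init = init, help_level = help_level)
  t2 <- simulate_ode(a, params, init = pmax(init + eps * u, 0),
                     help_level = help_level)
  sep <- sqrt(rowSums((t1$abundances - t2$abundances)^2))
  norm1 <- sqrt(rowSums(t1$abundances^2))
  floor_lvl <- max(1e-14, 10 * params$absolute_tolerance * 1e-2)
  saturated <- which(sep > 1e-2 * pmax(norm1, 1e-12))
  end <- if (length(saturated)) max(2L, saturated[1L]) else length(sep)
  idx <- seq(max(2L, floor(transient_fraction * end)), end)
  idx <- idx[sep[idx] > floor_lvl]
  if (length(idx) < 3L) {
    warning("separation at solver noise floor; Lyapunov estimate degenerate")
    return(NaN)
  }
  stats::coef(stats::lm(log(sep[idx]) ~ t1$times[idx]))[[2L]]
}

#' Sample initial conditions and measure basins of attraction
#'
#' Draws `n_inits` initial abundance vectors uniformly from \[0, 0.5\]^N
#' (seeded, reproducible), integrates each at help level `h`, classifies the
#' attractors and returns the fraction of starts reaching each label.
#' Solver failures are counted under a `"failure"` label, so the fractions
#' always sum to one.
#'
#' @param a A valid `click_assembly`.
#' @param h Bystander help level for all runs.
#' @param params An [ode_params()] list.
#' @param n_inits Number of sampled initial conditions (>= 2).
#' @param seed Integer seed for the sampler.
#' @param ... Passed to [classify_attractor()].
#' @return Named numeric vector of basin fractions (sums to 1).
#' @export
detect_bistability <- function(a, h, params = ode_params(), n_inits = 20L,
                               seed = 0L, ...) {
  if (n_inits < 2L) stop("detect_bistability() needs n_inits >= 2")
  n <- nrow(a$populations)
  inits <- with_preserved_rng({
    set.seed(seed)
    matrix(stats::runif(n_inits * n, 0, 0.5), n_inits, n)
  })
  labels <- vapply(seq_len(n_inits), function(i) {
    tryCatch(
      classify_attractor(simulate_ode(a, params, init = inits[i, ],
                                      help_level = h), ...)$label,
      error = function(e) "failure")
  }, character(1))
  tab <- table(labels) / n_inits
  stats::setNames(as.numeric(tab), names(tab))
}
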