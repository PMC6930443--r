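#' Solver and output-grid parameters for the ODE backend
#'
#' @param absolute_tolerance,relative_tolerance Integrator tolerances.
#' @param t_end End of the integration window (arbitrary time units).
#' @param n_samples Number of uniformly spaced output times (>= 2).
#' @param extinction_threshold Abundance below which a population is
#'   reported as lost.
#' @return A list of class `ode_params`.
#' @export
ode_params <- function(absolute_tolerance = 1e-9, relative_tolerance = 1e-7,
                       t_end = 400, n_samples = 2001,
                       extinction_threshold = 1e-8) {
  stopifnot(absolute_tolerance > 0, relative_tolerance > 0, t_end > 0,
            n_samples >= 2, extinction_threshold >= 0)
  structure(list(absolute_tolerance = absolute_tolerance,
                 relative_tolerance = relative_tolerance,
                 t_end = t_end, n_samples = as.integer(n_samples),
                 extinction_threshold = extinction_threshold),
            class = "ode_params")
}

# Per-population help level: the level of the bystander input targeting the
# population, or 0 if none. help_level (if non-NULL) overrides every input.
help_vector <- function(a, help_level = NULL) {
  ids <- a$populations$id
  h <- stats::setNames(numeric(length(ids)), ids)
  bi <- a$bystander_inputs
  if (nrow(bi)) h[bi$target] <- if (is.null(help_level)) bi$help_level else
    help_level
  h
}

#' Build the mean-field vector field of an assembly
#'
#' The deterministic model is a generalized Lotka-Volterra system on the
#' normalized response scale: for population i,
#' \deqn{dP_i/dt = P_i [ r_i (1 + \beta_i h_i)(1 - \sum_j P_j / K) - d_i -
#'   \sum_{j \dashv i} \kappa_{ji} P_j ] + \sum_{l \to i} m_l P_l - m_i P_i}
#' with logistic self-limitation shared through total abundance over K,
#' mass-action killing along the click edges, linear maturation flow, and
#' bystander help acting as a multiplicative growth modifier. The maturation
#' outflow term applies only to populations with an outgoing maturation edge.
#'
#' @param a A valid `click_assembly`.
#' @param help_level Optional scalar overriding every bystander input's help
#'   level (the control parameter of the bifurcation scans).
#' @return A function `f(P)` mapping a named abundance vector to its time
#'   derivative; attributes carry the parameter vectors.
#' @export
build_rhs <- function(a, help_level = NULL) {
  rep_ok <- validate_assembly(a)
  if (!rep_ok$valid)
    stop("invalid assembly: ",
         paste(rep_ok$violations$message, collapse = "; "))
  ids <- a$populations$id
  n <- length(ids)
  r <- stats::setNames(a$populations$growth_rate, ids)
  d <- stats::setNames(a$populations$death_rate, ids)
  beta <- stats::setNames(a$populations$help_coefficient, ids)
  h <- help_vector(a, help_level)
  K <- a$carrying_capacity
  growth <- r * (1 + beta * h)

  kill <- matrix(0, n, n, dimnames = list(ids, ids))   # kill[i, j]: j kills i
  ke <- a$kill_edges
  if (nrow(ke)) kill[cbind(ke$victim, ke$killer)] <- ke$kill_rate
  flow <- matrix(0, n, n, dimnames = list(ids, ids))   # maturation in - out
  me <- a$maturation_edges
  for (i in seq_len(nrow(me))) {
    flow[me$target[i], me$source[i]] <- flow[me$target[i], me$source[i]] + me$rate[i]
    flow[me$source[i], me$source[i]] <- flow[me$source[i], me$source[i]] - me$rate[i]
  }

  f <- function(P) {
    P <- stats::setNames(as.numeric(P), ids)
    as.numeric(P * (growth * (1 - sum(P) / K) - d - kill %*% P) + flow %*% P)
  }
  attr(f, "ids") <- ids
  attr(f, "params") <- list(growth = growth, death = d, kill = kill,
                            flow = flow, K = K, help = h)
  f
}

#' Integrate the mean-field dynamics of an assembly
#'
#' Uses a stiff-capable adaptive integrator (`deSolve::ode`, `lsoda`) on a
#' uniform output grid. Negative undershoot is clamped to zero at each output
#' step and the largest clamp magnitude is recorded in the metadata. The
#' trajectory is flagged converged when `max |dP/dt| < 1e-6` at the final
#' time.
#'
#' @param a A valid `click_assembly`.
#' @param params An [ode_params()] list.
#' @param init Optional non-negative initial abundance vector (defaults to
#'   the populations' `initial_abundance`).
#' @param help_level Optional scalar overriding the bystander help level.
#' @return A `click_trajectory` with fields `times`, `abundances` (matrix,
#'   one column per population) and `metadata` (backend `"ode"`, assembly
#'   fingerprint, parameter snapshot, `converged`, `max_clamp`).
#' @export
simulate_ode <- function(a, params = ode_params(), init = NULL,
                         help_level = NULL) {
  rhs <- build_rhs(a, help_level)
  ids <- attr(rhs, "ids")
  if (is.null(init)) init <- stats::setNames(a$populations$initial_abundance, ids)
  init <- as.numeric(init)
  if (length(init) != length(ids) || any(!is.finite(init)) || any(init < 0))
    stop("init must be a finite non-negative vector of length ", length(ids))
  times <- seq(0, params$t_end, length.out = params$n_samples)
  deriv <- function(t, y, parms) list(rhs(pmax(y, 0)))
  sol <- deSolve::ode(y = stats::setNames(init, ids), times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      atol = params$absolute_tolerance,
                      rtol = params$relative_tolerance)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed; last valid time ",
         max(sol[stats::complete.cases(sol), "time"]))
  ab <- unname(sol[, ids, drop = FALSE])
  colnames(ab) <- ids
  max_clamp <- max(0, -min(ab))
  ab[ab < 0] <- 0
  final <- ab[nrow(ab), ]
  converged <- max(abs(rhs(final))) < 1e-6
  new_trajectory(times = times, abundances = ab,
    metadata = list(backend = "ode",
                    assembly = fingerprint(unclass(a)),
                    params = unclass(params),
                    help_level = help_level,
                    converged = converged, max_clamp = max_clamp))
}

#' Locate an equilibrium of the mean-field dynamics
#'
#' Newton iteration on the vector field from [build_rhs()], with the
#' Jacobian computed by central finite differences (`pracma::jacobian`,
#' step `.Machine$double.eps^(1/3)` scaled). An equilibrium is accepted when
#' the residual max-norm falls below `tol`; stability is read off the sign
#' of the dominant eigenvalue real part of the Jacobian at the root.
#'
#' @param a A valid `click_assembly`.
#' @param guess Non-negative starting abundance vector.
#' @param help_level Optional scalar overriding the bystander help level.
#' @param tol Residual tolerance (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return List with `state` (named abundance vector), `stable` (logical),
#'   `eigenvalues` (Jacobian spectrum) and `residual`.
#' @export
find_equilibrium <- function(a, guess, help_level = NULL, tol = 1e-10,
                             max_iter = 100L) {
  rhs <- build_rhs(a, help_level)
  ids <- attr(rhs, "ids")
  x <- as.numeric(guess)
  if (any(!is.finite(x)) || any(x < 0))
    stop("guess must be finite and non-negative")
  for (it in seq_len(max_iter)) {
    fx <- rhs(x)
    if (max(abs(fx)) < tol) break
    J <- pracma::jacobian(rhs, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step)) step <- qr.solve(J + 1e-12 * diag(length(x)), fx)
    # damped update keeps the iterate in the admissible orthant
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (max(abs(rhs(pmax(xn, -1e-9)))) < max(abs(fx)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  fx <- rhs(x)
  if (max(abs(fx)) >= tol)
    stop("find_equilibrium() did not converge from the given guess (residual ",
         format(max(abs(fx))), ")")
  J <- pracma::jacobian(rhs, x)
  ev <- eigen(J, only.values = TRUE)$values
  list(state = stats::setNames(x, ids), stable = max(Re(ev)) < 0,
       eigenvalues = ev, residual = max(abs(fx)))
}
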