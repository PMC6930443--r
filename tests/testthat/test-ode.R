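single_logistic <- function(r = 1, d = 0, K = 1, init = 0.1) {
  assembly(population("P", "solo", "young", growth_rate = r, death_rate = d,
                      initial_abundance = init), carrying_capacity = K)
}

test_that("the vector field reduces to logistic growth for one isolated population", {
  f <- build_rhs(single_logistic())
  expect_equal(f(1), 0)                       # fixed point at K
  expect_equal(f(0), 0)                       # extinction absorbing
  expect_equal(f(0.5), 0.5 * 0.5)             # r P (1 - P/K)
  # extinction is absorbing for the full canonical model too
  a <- build_canonical_4click()
  expect_equal(build_rhs(a)(rep(0, 4)), rep(0, 4))
})

test_that("the vector field refuses invalid assemblies", {
  pops <- rbind(population("A", "x", "young"), population("B", "x", "mature"))
  bad <- assembly(pops, rbind(kill_edge("A", "B"), kill_edge("B", "A")))
  expect_error(build_rhs(bad), "invalid assembly")
})

test_that("a single logistic population integrates to carrying capacity", {
  a <- single_logistic(r = 1, d = 0.2)
  traj <- simulate_ode(a, ode_params(t_end = 60, n_samples = 301))
  final <- traj$abundances[nrow(traj$abundances), "P"]
  expect_equal(unname(final), 0.8, tolerance = 1e-6)   # K (1 - d/r)
  expect_true(traj$metadata$converged)
})

test_that("symmetric populations stay symmetric and zero init stays zero", {
  pops <- do.call(rbind, lapply(c("A", "B", "C"), function(id)
    population(id, id, "young", growth_rate = 1, death_rate = 0,
               initial_abundance = 0.05)))
  a <- assembly(pops)
  traj <- simulate_ode(a, ode_params(t_end = 30, n_samples = 151))
  expect_lt(max(abs(traj$abundances[, "A"] - traj$abundances[, "B"])), 1e-7)
  expect_lt(max(abs(traj$abundances[, "A"] - traj$abundances[, "C"])), 1e-7)

  z <- simulate_ode(build_canonical_4click(), ode_params(t_end = 20,
                                                         n_samples = 51),
                    init = rep(0, 4))
  expect_true(all(z$abundances == 0))
})

test_that("trajectories are non-negative and bounded under random parameters", {
  set.seed(42)
  for (rep in 1:8) {
    a <- random_assembly(sample(2:3, 1), rng_seed = rep)
    p <- ode_params(t_end = 80, n_samples = 201)
    init <- stats::runif(nrow(a$populations), 0, 0.3)
    traj <- simulate_ode(a, p, init = init)
    expect_true(all(traj$abundances >= 0))
    totals <- rowSums(traj$abundances)
    expect_lte(max(totals), max(sum(init), 1) + 1e-6)
    expect_true(all(diff(traj$times) > 0))
  }
})

test_that("integration and root-finding agree on the canonical resting equilibrium", {
  a <- build_canonical_4click()
  p <- ode_params(t_end = 9000, n_samples = 1801)
  traj <- simulate_ode(a, p)
  final <- traj$abundances[nrow(traj$abundances), ]
  eq <- find_equilibrium(a, final)
  expect_lt(max(abs(eq$state - final)), 1e-5)
  expect_true(eq$stable)
  expect_lt(eq$residual, 1e-10)
  # the RHS at the root is numerically zero
  f <- build_rhs(a)
  expect_lt(max(abs(f(eq$state))), 1e-6)
})

test_that("equilibrium finder handles trivial roots and reports instability", {
  a <- single_logistic(r = 1, d = 0.2)
  eq0 <- find_equilibrium(a, 0)
  expect_equal(unname(eq0$state), 0, tolerance = 1e-12)
  expect_false(eq0$stable)                    # r > d: extinction is unstable
  eqK <- find_equilibrium(a, 0.7)
  expect_equal(unname(eqK$state), 0.8, tolerance = 1e-8)
  expect_true(eqK$stable)
})

test_that("halving solver tolerances leaves the final state unchanged to 1e-5", {
  a <- build_canonical_4click()
  p1 <- ode_params(t_end = 400, n_samples = 401)
  p2 <- ode_params(absolute_tolerance = 5e-10, relative_tolerance = 5e-8,
                   t_end = 400, n_samples = 401)
  f1 <- simulate_ode(a, p1)$abundances[401, ]
  f2 <- simulate_ode(a, p2)$abundances[401, ]
  expect_lt(max(abs(f1 - f2)), 1e-5)
})

test_that("small perturbations of a stable equilibrium decay back", {
  a <- build_canonical_4click()
  p <- ode_params(t_end = 6000, n_samples = 1201)
  final <- simulate_ode(a, p)$abundances[1201, ]
  eq <- find_equilibrium(a, final)
  expect_true(eq$stable)
  pert <- simulate_ode(a, ode_params(t_end = 2500, n_samples = 501),
                       init = pmax(eq$state + 1e-4, 0))
  end <- pert$abundances[501, ]
  expect_lt(sqrt(sum((end - eq$state)^2)), 1e-4)
})
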