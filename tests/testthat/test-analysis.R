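make_traj <- function(times, mat) {
  colnames(mat) <- colnames(mat) %||% paste0("P", seq_len(ncol(mat)))
  clickassembly:::new_trajectory(times, mat, list(backend = "synthetic"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("attractor classification covers its label vocabulary", {
  tm <- seq(0, 99)
  flat <- function(vals) matrix(rep(vals, each = 100), 100,
                                dimnames = list(NULL, c("Tc", "Tnk", "Th", "Tr1")))
  expect_equal(classify_attractor(make_traj(tm, flat(c(0, 0, 0, 0))))$label,
               "extinct")
  dom <- classify_attractor(make_traj(tm, flat(c(0.05, 0.1, 0.02, 0.6))))
  expect_equal(dom$label, "Tr1_dominant")
  expect_equal(dom$dominant_id, "Tr1")
  tc <- classify_attractor(make_traj(tm, flat(c(0.7, 0.2, 0.01, 0.01))))
  expect_equal(tc$label, "Tc_dominant")
  coex <- classify_attractor(make_traj(tm, flat(c(0.4, 0.35, 0.1, 0.1))))
  expect_equal(coex$label, "coexistence")
  osc <- flat(c(0.3, 0.3, 0.1, 0.1))
  osc[, 1] <- 0.3 + 0.2 * sin(tm)            # CV far above threshold
  expect_equal(classify_attractor(make_traj(tm, osc))$label, "non_stationary")
  expect_error(classify_attractor(make_traj(numeric(0),
    matrix(numeric(0), 0, 4))), "empty")
})

test_that("classification is invariant to uniform time rescaling", {
  set.seed(3)
  mat <- matrix(rep(c(0.5, 0.1, 0.05, 0.02), each = 200), 200,
                dimnames = list(NULL, c("Tc", "Tnk", "Th", "Tr1")))
  mat <- mat * (1 + 0.01 * matrix(stats::rnorm(800), 200))
  t1 <- classify_attractor(make_traj(seq_len(200), mat))
  t2 <- classify_attractor(make_traj(seq_len(200) * 37.5, mat))
  expect_identical(t1$label, t2$label)
})

test_that("the shipped presets reproduce the resting and knockdown regimes", {
  cfg <- canonical_preset("fig2a")
  traj <- simulate_ode(cfg$assembly, cfg$params)
  cls <- classify_attractor(traj)
  expect_equal(cls$label, "Tr1_dominant")
  kd <- canonical_preset("fig2b")
  kcls <- classify_attractor(simulate_ode(kd$assembly, kd$params))
  expect_equal(kcls$label, "Tc_dominant")
})

test_that("bystander-help scans are reproducible and label-consistent", {
  a <- build_canonical_4click()
  p <- ode_params(t_end = 3000, n_samples = 1001)
  grid <- c(0.02, 0.05, 0.08)
  s1 <- scan_bystander_help(a, grid, p, lyapunov = FALSE)
  s2 <- scan_bystander_help(a, grid, p, lyapunov = FALSE)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$final_states, s2$final_states)
  # low-help regime: one label across the grid
  expect_equal(unique(s1$labels), "Tc_dominant")
  empty <- scan_bystander_help(a, numeric(0), p)
  expect_equal(length(empty$help_values), 0L)
  expect_error(scan_bystander_help(a, c(0.3, 0.2), p), "increasing")
})

test_that("return maps handle constant and periodic trajectories exactly", {
  tm <- seq_len(40)
  const <- make_traj(tm, matrix(0.25, 40, 1, dimnames = list(NULL, "P")))
  rm_c <- return_map(const, lag = 1)
  expect_true(all(rm_c$points$P[, 1] == rm_c$points$P[, 2]))  # on the diagonal
  p2 <- make_traj(tm, matrix(rep(c(0.2, 0.6), 20), 40,
                             dimnames = list(NULL, "P")))
  rm_p <- return_map(p2, lag = 1)
  pts <- unique(rm_p$points$P)
  expect_equal(nrow(pts), 2L)
  expect_setequal(pts[, 1], c(0.2, 0.6))
  # a period-2 path retraces itself: joint overlap is zero
  expect_equal(rm_p$overlap, 0)
  expect_error(return_map(p2, lag = 40), "lag")
})

test_that("the transition-window return map path is non-self-intersecting", {
  cfg <- canonical_preset("fig2c")
  traj <- simulate_ode(cfg$assembly, cfg$params,
                       help_level = cfg$analysis$transition_help)
  rm_ <- return_map(traj, lag = cfg$analysis$return_map_lag,
                    t_window = unlist(cfg$analysis$t_window))
  expect_gt(rm_$overlap, 0)
})

test_that("the Lyapunov estimate matches the logistic decay rate within 10%", {
  r <- 1.3
  a <- assembly(population("P", "solo", "young", growth_rate = r,
                           initial_abundance = 0.9),
                carrying_capacity = 1)
  # at the fixed point K the linearization eigenvalue is exactly -r; the
  # horizon is short so the separation stays above the solver noise floor
  lam <- lyapunov_estimate(a, ode_params(t_end = 6, n_samples = 301),
                           init = 0.9)
  expect_lt(abs(lam - (-r)) / r, 0.1)
})

test_that("twin-trajectory divergence agrees with the Jacobian at equilibrium", {
  a <- build_canonical_4click()
  p <- ode_params(t_end = 6000, n_samples = 3001)
  final <- simulate_ode(a, p)$abundances[3001, ]
  eq <- find_equilibrium(a, final)
  dom <- max(Re(eq$eigenvalues))
  lam <- lyapunov_estimate(a, ode_params(t_end = 2500, n_samples = 1251),
                           init = eq$state)
  expect_lt(abs(lam - dom) / abs(dom), 0.2)
})

test_that("the transition window is sensitive while both stable regimes are not", {
  cfg <- canonical_preset("fig2c")
  an <- cfg$analysis
  lam_t <- lyapunov_estimate(cfg$assembly, cfg$params,
                             help_level = an$transition_help)
  lam_lo <- lyapunov_estimate(cfg$assembly, cfg$params,
                              help_level = an$stable_low_help)
  lam_hi <- lyapunov_estimate(cfg$assembly, cfg$params,
                              help_level = an$stable_high_help)
  expect_gt(lam_t, 0)
  expect_lt(lam_lo, 0)
  expect_lt(lam_hi, 0)
})

test_that("basin fractions sum to one and find both attractors at the bistable preset", {
  a <- assembly(population("P", "solo", "young", growth_rate = 1,
                           death_rate = 0.1))
  fr1 <- detect_bistability(a, 0, ode_params(t_end = 60, n_samples = 121),
                            n_inits = 6, seed = 2)
  expect_equal(sum(fr1), 1)
  expect_equal(unname(fr1["P_dominant"]), 1)

  cfg <- canonical_preset("fig2c")
  fr <- detect_bistability(cfg$assembly, cfg$analysis$bistable_help,
                           cfg$params, n_inits = cfg$analysis$n_inits,
                           seed = cfg$seed)
  expect_equal(sum(fr), 1)
  expect_gt(fr[["Tr1_dominant"]], 0)
  expect_gt(fr[["Tc_dominant"]], 0)
  expect_error(detect_bistability(a, 0, n_inits = 1), "n_inits")
})
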