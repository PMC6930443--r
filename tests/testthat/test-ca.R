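two_pop_chain <- function(kill_rate = 1) {
  pops <- rbind(population("A", "x", "young", growth_rate = 1),
                population("B", "y", "young", growth_rate = 1))
  assembly(pops, kill_edge("A", "B", kill_rate = kill_rate))
}

flat_rates <- function(a, kill = 0, rep = 0, mat = 0, death = 0) {
  ids <- a$populations$id
  ca_rates(a,
    kill = stats::setNames(rep(kill, nrow(a$kill_edges)),
                           paste0(a$kill_edges$killer, "-|",
                                  a$kill_edges$victim)),
    reproduction = stats::setNames(rep(rep, length(ids)), ids),
    maturation = stats::setNames(rep(mat, nrow(a$maturation_edges)),
                                 a$maturation_edges$source),
    death = stats::setNames(rep(death, length(ids)), ids))
}

test_that("lattice initialization is seeded, density-faithful and error-checked", {
  a <- build_canonical_4click()
  l1 <- init_lattice(a, 50, 40, densities = list(Tc = 0.2, Tr1 = 0.3),
                     seed = 9)
  l2 <- init_lattice(a, 50, 40, densities = list(Tc = 0.2, Tr1 = 0.3),
                     seed = 9)
  expect_identical(l1$states, l2$states)
  expect_equal(dim(l1$states), c(40L, 50L))

  empty <- init_lattice(a, 10, 10, densities = list(), seed = 1)
  expect_true(all(empty$states == 0L))
  full <- init_lattice(a, 10, 10, densities = list(Tc = 1.0), seed = 1)
  expect_true(all(full$states == 1L))

  # binomial sampling bound: counts within 4 sd of n p on a 100x100 lattice
  dens <- stats::setNames(as.list(rep(0.2, 4)), a$populations$id)
  big <- init_lattice(a, 100, 100, densities = dens, seed = 33)
  counts <- tabulate(big$states, nbins = 4L)
  sd_bin <- sqrt(1e4 * 0.2 * 0.8)
  expect_true(all(abs(counts - 2000) < 4 * sd_bin))

  expect_error(init_lattice(a, 10, 10, densities = list(Tc = 0.7, Tr1 = 0.6)),
               "sum")
})

test_that("degenerate sweeps behave exactly: empty stays empty, pure growth fills", {
  a <- two_pop_chain()
  r0 <- flat_rates(a)
  l <- init_lattice(a, 8, 8, densities = list(), seed = 1)
  l2 <- step_ca(l, a, r0, sweeps = 5)
  expect_true(all(l2$states == 0L))
  expect_equal(l2$generation, 5L)

  rg <- flat_rates(a, rep = 1)
  l <- init_lattice(a, 8, 8, densities = list(A = 0.1), seed = 4)
  occ <- sum(l$states > 0)
  for (i in 1:12) {
    l <- step_ca(l, a, rg)
    occ_new <- sum(l$states > 0)
    expect_gte(occ_new, occ)       # reproduction only: occupancy never drops
    occ <- occ_new
  }
  expect_true(all(l$states == 1L)) # lattice saturates with the single type
})

test_that("site counts are conserved and kills change only the victim site", {
  a <- build_canonical_4click()
  r <- map_ode_rates_to_ca(a)
  l <- init_lattice(a, 30, 30, densities = list(Tc = 0.2, Tnk = 0.2,
                                                Th = 0.2, Tr1 = 0.2),
                    seed = 7)
  for (i in 1:10) {
    l <- step_ca(l, a, r)
    expect_equal(sum(l$states >= 0L), 900L)   # every site holds one code
    expect_true(all(l$states %in% 0:4))
  }

  # all-kill dynamics: killer counts never decrease when only kills can occur
  b <- two_pop_chain()
  rk <- flat_rates(b, kill = 1)
  lb <- init_lattice(b, 20, 20, densities = list(A = 0.4, B = 0.4), seed = 2)
  for (i in 1:10) {
    before <- sum(lb$states == 1L)
    lb <- step_ca(lb, b, rk)
    expect_gte(sum(lb$states == 1L), before)
    expect_equal(length(lb$states), 400L)
  }
})

test_that("the compiled sweep matches an independent R reference stepper", {
  a <- build_canonical_4click()
  r <- map_ode_rates_to_ca(a)
  tabs <- clickassembly:::ca_rate_tables(a, r)
  l <- init_lattice(a, 6, 5, densities = list(Tc = 0.25, Tnk = 0.2,
                                              Th = 0.2, Tr1 = 0.2),
                    seed = 13)
  stepped <- step_ca(l, a, r, sweeps = 3)
  set.seed(l$rng_seed + l$generation)
  ref <- l$states
  for (s in 1:3)
    ref <- reference_ca_sweep(ref, l$ids, tabs$kill_edge, tabs$kill_prob,
                              tabs$rep_prob, tabs$mat_prob, tabs$mat_target,
                              tabs$death_prob)
  expect_identical(stepped$states, ref)
})

test_that("runs are reproducible and recorded as trajectories", {
  a <- build_canonical_4click()
  r <- map_ode_rates_to_ca(a)
  l <- init_lattice(a, 25, 25, densities = list(Tc = 0.2, Tnk = 0.1,
                                                Th = 0.1, Tr1 = 0.3),
                    seed = 21)
  t1 <- run_ca(a, r, l, sweeps = 30)
  t2 <- run_ca(a, r, l, sweeps = 30)
  expect_identical(t1$abundances, t2$abundances)
  expect_equal(t1$metadata$backend, "ca")
  expect_equal(nrow(t1$abundances), 31L)
  expect_true(all(t1$abundances >= 0 & t1$abundances <= 1))
  # all-empty init gives the all-zero trajectory
  l0 <- init_lattice(a, 10, 10, densities = list(), seed = 3)
  expect_true(all(run_ca(a, r, l0, sweeps = 5)$abundances == 0))
})

test_that("a symmetric kill cycle gives equal long-run abundances across replicates", {
  ids <- c("P1", "P2", "P3", "P4")
  pops <- do.call(rbind, lapply(ids, function(id)
    population(id, id, "young", growth_rate = 1, death_rate = 0.02)))
  kes <- do.call(rbind, lapply(1:4, function(i)
    kill_edge(ids[i], ids[i %% 4 + 1], kill_rate = 1)))
  a <- assembly(pops, kes)
  r <- map_ode_rates_to_ca(a)
  dens <- stats::setNames(as.list(rep(0.2, 4)), ids)
  means <- t(vapply(1:16, function(s) {
    l <- init_lattice(a, 60, 60, densities = dens, seed = s)
    tr <- run_ca(a, r, l, sweeps = 160)
    colMeans(tr$abundances[82:161, ])
  }, numeric(4)))
  grand <- colMeans(means)
  se <- apply(means, 2, stats::sd) / sqrt(nrow(means))
  overall <- mean(grand)
  for (j in 1:4)
    expect_lt(abs(grand[j] - overall), 3 * se[j])
})

test_that("well-mixed CA agrees with the ODE equilibrium in the cytotoxic regime", {
  a <- build_canonical_4click(list(help_level = 0.05))
  traj <- simulate_ode(a, ode_params(t_end = 4000, n_samples = 1001))
  eq <- find_equilibrium(a, traj$abundances[1001, ])
  r <- map_ode_rates_to_ca(a)
  l0 <- init_lattice(a, 200, 200,
                     densities = as.list(pmax(eq$state, 1e-4)), seed = 5)
  ca <- run_ca(a, r, l0, sweeps = 500)
  mu <- colMeans(ca$abundances[seq(402, 501), ])
  expect_true(all(abs(mu - eq$state) < 0.1))
})

test_that("lattice snapshots write as plain-text grids and round-trip as RLE", {
  a <- build_canonical_4click()
  l <- init_lattice(a, 12, 8, densities = list(Tc = 0.3, Th = 0.3), seed = 2)
  path <- tempfile(fileext = ".txt")
  write_lattice(l, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#"))
  expect_equal(length(lines), 9L)          # header + 8 rows
  expect_true(all(nchar(lines[-1]) == 12L))

  rle_path <- tempfile(fileext = ".json")
  write_lattice(l, rle_path, format = "rle")
  back <- read_lattice(rle_path)
  expect_identical(back$states, l$states)
  expect_identical(back$ids, l$ids)
  expect_identical(back$generation, l$generation)
})
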