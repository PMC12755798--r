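test_that("single species follows the logistic limit", {
  st <- null_structure(1)
  sys <- interaction_system(st, 0)
  tr <- integrate_glv(sys, sim_config(t_max = 60), x0 = 0.01)
  expect_lt(abs(tr$abundances[1, ncol(tr$abundances)] - 1), 1e-6)
  expect_true(all(tr$abundances >= 0))
})

test_that("two weak mutualists reach the linear fixed point", {
  # x = 1 + 0.1 x  =>  x* = 1/0.9
  st <- community_structure(impact = diag(2),
                            sensitivity = rbind(c(0, 0.2), c(0.2, 0)),
                            check_low_rank = FALSE)  # mu = [[0,.1],[.1,0]]
  expect_equal(structural_matrix(st), rbind(c(0, 0.1), c(0.1, 0)),
               tolerance = 1e-12)
  sys <- interaction_system(st, 0)
  tr <- integrate_glv(sys, sim_config(t_max = 120), x0 = c(0.5, 0.7))
  expect_equal(tr$abundances[, ncol(tr$abundances)], rep(1 / 0.9, 2),
               tolerance = 1e-4, ignore_attr = TRUE)
  # declared stationarity means the right-hand side really is small
  g <- tr$abundances[, ncol(tr$abundances)]
  resid <- max(abs(g * (1 - g + drop(sys$A %*% g)) + tr$config$m))
  expect_true(!tr$equilibrium || resid < tr$config$equilibrium_tol)
})

test_that("function magnitudes are the impact-weighted species averages", {
  st <- suppressWarnings(group_structure(c(2, 3), rbind(c(0, -1), c(-1, 0))))
  x <- matrix(runif(5 * 4), 5, 4)
  tr <- fake_traj(x, st = st)
  f <- compute_functions(tr)
  expect_equal(f[1, ], colSums(x[1:2, ]) / 5)
  expect_equal(f[2, ], colSums(x[3:5, ]) / 5)
  expect_identical(f, tr$functions)
  expect_equal(compute_functions(fake_traj(matrix(0, 3, 4))),
               matrix(0, 1, 4), ignore_attr = TRUE)
})

test_that("equal-time correlator averages the second moment", {
  tr <- fake_traj(matrix(c(2, 2, 0, 0), 4, 10))
  expect_equal(equal_time_correlator(tr), 2)       # (4+4+0+0)/4
  trc <- fake_traj(matrix(0.5, 3, 10))
  expect_equal(equal_time_correlator(trc), 0.25)
  # invariance under species permutation
  x <- matrix(runif(40), 4, 10)
  expect_equal(equal_time_correlator(fake_traj(x)),
               equal_time_correlator(fake_traj(x[c(3, 1, 4, 2), ])))
  expect_error(equal_time_correlator(fake_traj(x), window = 1e-9), "window")
})

test_that("extinction census thresholds on multiples of the immigration rate", {
  x <- rbind(rep(1, 8), rep(1e-8, 8))
  tr <- fake_traj(x)
  cen <- extinction_census(tr)
  expect_equal(cen$survivors, c(TRUE, FALSE))
  expect_equal(cen$phi_sim, 0.5)
  # monotone non-increasing in the extinction factor
  x2 <- rbind(rep(1, 8), rep(5e-7, 8), rep(1e-8, 8))
  phis <- vapply(c(2, 10, 100), function(k) {
    tr2 <- fake_traj(x2)
    tr2$config$extinction_factor <- k
    extinction_census(tr2)$phi_sim
  }, numeric(1))
  expect_true(all(diff(phis) <= 0))
})

test_that("census is insensitive to the extinction factor when abundances are O(1)", {
  st <- coexistence_structure(50)
  sys <- interaction_system(st, 0.15, seed = 2)
  tr <- integrate_glv(sys, sim_config(t_max = 200))
  phis <- vapply(c(10, 100, 1e4), function(k) {
    cfg <- tr$config; cfg$extinction_factor <- k
    extinction_census(tr, cfg)$phi_sim
  }, numeric(1))
  expect_equal(phis[1], phis[2])
  expect_equal(phis[1], phis[3])
})

test_that("analytic-signal embedding traces circles for sinusoids", {
  t <- seq(0, 20 * pi, length.out = 2048)
  z <- hilbert_embedding(sin(t))
  core <- seq(floor(0.1 * length(t)), ceiling(0.9 * length(t)))
  expect_true(all(abs(Mod(z[core]) - 1) < 0.02))
  # amplitude scales linearly
  z3 <- hilbert_embedding(3 * sin(t))
  expect_true(all(abs(Mod(z3[core]) - 3) < 0.06))
  # constant series collapses to the origin
  expect_true(all(Mod(hilbert_embedding(rep(2, 256))) < 1e-12))
  expect_error(hilbert_embedding(1:4, times = c(0, 1, 2, 4)), "non-uniform")
})

test_that("fluctuation variances compare species and group scales", {
  st <- suppressWarnings(group_structure(c(3, 3), rbind(c(0, 0), c(0, 0))))
  # fixed point: both zero
  fv0 <- fluctuation_variances(fake_traj(matrix(1, 6, 20), st = st))
  expect_equal(fv0$species_level, 0)
  expect_equal(fv0$group_level, 0)
  # synchronized species: rescaled group variance equals species variance
  base <- sin(seq(0, 6 * pi, length.out = 50))
  xs <- matrix(rep(base, each = 6), 6, 50)
  fv1 <- fluctuation_variances(fake_traj(xs, st = st))
  expect_equal(fv1$group_level, fv1$species_level, tolerance = 1e-12)
  # s independent fluctuating species per group: group variance ~ species/s
  set.seed(5)
  s <- 40
  st2 <- suppressWarnings(group_structure(c(s, s), rbind(c(0, 0), c(0, 0))))
  xi <- matrix(rnorm(2 * s * 400), 2 * s, 400)
  fv2 <- fluctuation_variances(fake_traj(xi, st = st2))
  expect_lt(abs(fv2$group_level / (fv2$species_level / s) - 1), 0.25)
})

test_that("species within a group stay coherent without disorder", {
  st <- suppressWarnings(group_structure(c(4, 4), rbind(c(0, -2), c(-0.5, 0))))
  sys <- interaction_system(st, 0)
  x0 <- rep(c(0.3, 0.6), each = 4)
  tr <- integrate_glv(sys, sim_config(t_max = 80), x0 = x0)
  spread <- apply(tr$abundances[1:4, ], 2, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
  # asymptotic convergence from unequal starts within a group
  x0b <- c(0.2, 0.4, 0.6, 0.8, rep(0.5, 4))
  trb <- integrate_glv(sys, sim_config(t_max = 200,
                                       stop_at_equilibrium = FALSE), x0 = x0b)
  final_spread <- diff(range(trb$abundances[1:4, ncol(trb$abundances)]))
  expect_lt(final_spread, 1e-4)
})

test_that("group magnitudes obey the reduced group-level dynamics at sigma = 0", {
  sizes <- c(30, 20)
  b <- rbind(c(0, -1.5), c(-0.7, 0))
  st <- group_structure(sizes, b)
  S <- sum(sizes)
  sys <- interaction_system(st, 0)
  x0 <- rep(c(0.4, 0.9), sizes)
  cfg <- sim_config(t_max = 50, n_samples = 100, stop_at_equilibrium = FALSE)
  tr <- integrate_glv(sys, cfg, x0 = x0)
  # independent reduced integration of the two group magnitudes
  rhs <- function(t, f, p) {
    list(f * (1 - (S / sizes) * f + drop(b %*% f)) + 1e-8 * sizes / S)
  }
  f0 <- x0[c(1, 31)] * sizes / S
  red <- deSolve::ode(f0, tr$times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$functions[1, ], red[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tr$functions[2, ], red[, 3], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("integration diagnostics and failure modes are reported", {
  st <- null_structure(3)
  sys <- interaction_system(st, 0)
  expect_error(integrate_glv(sys, x0 = c(-1, 1, 1)), "positive")
  tr <- integrate_glv(sys, sim_config(t_max = 100))
  expect_true(tr$equilibrium)
  expect_lt(tr$rhs_norm, 1e-9)
  # abundances stay strictly positive with immigration
  expect_gt(min(tr$abundances[, ncol(tr$abundances)]), 0)
})
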