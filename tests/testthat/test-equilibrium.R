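test_that("closed-form truncated-Gaussian moments match quadrature", {
  w <- seq(-8, 8, by = 0.25)
  for (k in 0:2)
    expect_lt(max(abs(omega_k(w, k) - omega_quadrature(w, k))), 1e-10)
  expect_equal(omega_k(0, 0), 0.5)
  expect_equal(omega_k(0, 1), 1 / sqrt(2 * pi))
  expect_equal(omega_k(0, 2), 0.5)
  # large-argument asymptotics: omega_k(w) -> w^k, omega_0 -> 1
  expect_equal(omega_k(30, 0), 1)
  expect_equal(omega_k(30, 1), 30, tolerance = 1e-12)
  expect_equal(omega_k(30, 2), 900 + 1, tolerance = 1e-10)  # w^2 + 1
  # far-negative guard returns tiny non-negative values without cancellation
  expect_true(all(omega_k(c(-10, -20, -35), 1) >= 0))
  expect_true(all(omega_k(c(-10, -20, -35), 2) >= 0))
  expect_error(omega_k(0, 3), "k must be")
  expect_error(omega_k(Inf, 1), "finite")
})

test_that("sigma = 0 solver reproduces hand-solved equilibria", {
  # single self-regulating function: f = max(0, 1 - c f) => f* = 1/(1+c)
  st1 <- trait_structure(matrix(1, 20, 1), matrix(-2, 20, 1))
  expect_equal(as.numeric(solve_sigma_zero(st1)), 1 / 3, tolerance = 1e-10)

  # symmetric exclusion pair: branch selected by the initial condition
  st2 <- exclusion_structure(2)
  f_a <- as.numeric(solve_sigma_zero(st2, init = c(0.5, 0)))
  expect_equal(f_a, c(0.5, 0), tolerance = 1e-10)
  f_b <- as.numeric(solve_sigma_zero(st2, init = c(0, 0.5)))
  expect_equal(f_b, c(0, 0.5), tolerance = 1e-10)
  expect_equal(modal_abundances(st2, f_a), c(1, 1, -1, -1),
               tolerance = 1e-10)

  # no interactions: every species sits at 1, f = mean impact
  imp <- matrix(runif(30), 15, 2)
  st3 <- suppressWarnings(community_structure(imp, matrix(0, 15, 2)))
  expect_equal(as.numeric(solve_sigma_zero(st3)), colMeans(imp) / 1,
               tolerance = 1e-10)
})

test_that("support enumeration lists the coexisting and exclusion equilibria", {
  st <- exclusion_structure(2)
  eqs <- sigma_zero_equilibria(st)
  eqs <- eqs[order(vapply(eqs, function(f) f[1] - f[2], 1))]
  # two exclusion states plus the (dynamically unstable) interior point
  expect_equal(length(eqs), 3L)
  expect_equal(eqs[[1]], c(0, 0.5), tolerance = 1e-10)
  expect_equal(eqs[[2]], c(1, 1) / 6, tolerance = 1e-10)  # f = 0.5(1 - 4f)
  expect_equal(eqs[[3]], c(0.5, 0), tolerance = 1e-10)

  stc <- suppressWarnings(group_structure(c(2, 2), rbind(c(0, -0.5),
                                                         c(-0.5, 0))))
  eqc <- sigma_zero_equilibria(stc)
  expect_equal(length(eqc), 1L)          # weak competition: only coexistence
  expect_equal(eqc[[1]], rep(0.4, 2), tolerance = 1e-10)  # f = 0.5(1 - f/2)
})

test_that("modal abundances are the affine trait map", {
  st <- coexistence_structure(10)
  expect_equal(modal_abundances(st, c(0, 0)), rep(1, 20))
  st1 <- suppressWarnings(trait_structure(matrix(1, 5, 1), matrix(-2, 5, 1)))
  expect_equal(modal_abundances(st1, 0.25), rep(0.5, 5))
  # constant within groups
  xp <- modal_abundances(st, c(0.2, 0.1))
  expect_equal(length(unique(round(xp, 12))), 2L)
})

test_that("self-consistency solution satisfies its defining relations", {
  st <- coexistence_structure(500)
  eq <- solve_self_consistency(st, 0.6)
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-9)
  # invariants of the state
  expect_equal(eq$modal, modal_abundances(st, eq$f_star))
  expect_equal(eq$gamma, eq$sigma * sqrt(eq$C_star))
  expect_equal(eq$phi_star, mean(omega_k(eq$modal / eq$gamma, 0)))
  expect_equal(eq$survival, omega_k(eq$modal / eq$gamma, 0))
  # the two closed relations hold to tolerance
  w <- eq$modal / eq$gamma
  f_rhs <- eq$gamma * drop(crossprod(st$impact, omega_k(w, 1))) / 1000
  expect_lt(max(abs(f_rhs - eq$f_star)), 1e-9)
  expect_lt(abs(eq$sigma^2 * mean(omega_k(w, 2)) - 1), 1e-9)
})

test_that("the sigma -> 0 limit recovers the structure-only equilibrium", {
  st <- coexistence_structure(200)
  f0 <- as.numeric(solve_sigma_zero(st))
  init <- list(f = f0, gamma = 1e-6)
  for (sg in c(0.2, 0.1, 0.05, 0.02)) {
    eq <- solve_self_consistency(st, sg, init = init)
    init <- list(f = eq$f_star, gamma = eq$gamma)
  }
  expect_equal(eq$f_star, f0, tolerance = 5e-3)
  expect_lt(eq$gamma, 0.03)
})

test_that("without structure the solver matches direct simulation", {
  st <- null_structure(2000)
  eq <- solve_self_consistency(st, 0.5)
  phis <- c(); gams <- c()
  for (seed in 1:3) {
    sys <- interaction_system(st, 0.5, seed = seed)
    tr <- integrate_glv(sys, sim_config(t_max = 200, rel_tol = 1e-6,
                                        abs_tol = 1e-10))
    phis <- c(phis, extinction_census(tr)$phi_sim)
    gams <- c(gams, 0.5 * sqrt(equal_time_correlator(tr)))
  }
  expect_rel(mean(phis), eq$phi_star, 0.03)
  expect_rel(mean(gams), eq$gamma, 0.03)
})

test_that("analytic SAD is normalized and degenerates correctly", {
  st <- coexistence_structure(300)
  eq <- solve_self_consistency(st, 0.5)
  for (n_grid in c(400, 1600)) {
    grid <- seq(0, max(eq$modal) + 6 * eq$gamma, length.out = n_grid)
    sad <- sad_density(eq, grid)
    mass <- sad$zero_mass +
      sum((sad$density[-1] + sad$density[-n_grid]) / 2 * diff(grid))
    expect_lt(abs(mass - 1), 1e-4)
  }
  # gamma = 0: point masses at distinct positive modal abundances
  st2 <- exclusion_structure(3)
  eq0 <- solve_self_consistency(st2, 0, init = list(f = c(0.5, 0)))
  sad0 <- sad_density(eq0)
  expect_equal(sad0$atoms[, "abundance"], 1, ignore_attr = TRUE)
  expect_equal(sad0$atoms[, "weight"], 0.5, ignore_attr = TRUE)
  expect_equal(sad0$zero_mass, 0.5)
  # narrow disorder around a single positive mode: one bump, no zero mass
  stn <- null_structure(50)
  eqn <- solve_self_consistency(stn, 0.1)
  sadn <- sad_density(eqn)
  expect_lt(sadn$zero_mass, 1e-10)
  expect_equal(sadn$grid[which.max(sadn$density)], 1, tolerance = 0.05)
})

test_that("sampled equilibrium abundances follow the truncated-Gaussian law", {
  st <- coexistence_structure(500)
  eq <- solve_self_consistency(st, 0.5)
  # gamma = 0 sampling is deterministic
  eq0 <- solve_self_consistency(exclusion_structure(2), 0,
                                init = list(f = c(0.5, 0)))
  expect_equal(as.numeric(simulate(eq0, seed = 1)), c(1, 1, 0, 0))

  draws <- simulate(eq, nsim = 50, seed = 42)
  phi_emp <- mean(draws > 0)
  se <- sqrt(eq$phi_star * (1 - eq$phi_star) / length(draws))
  expect_lt(abs(phi_emp - eq$phi_star), 3 * se)

  # per-group survivors against the truncated Gaussian (xp, gamma)
  one <- as.numeric(simulate(eq, seed = 7))
  g1 <- one[st$group_ids == 1]
  surv <- g1[g1 > 0]
  ks <- suppressWarnings(
    stats::ks.test(surv, function(q) ptrunc_gauss(q, eq$modal[1], eq$gamma)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a symmetric balanced tree leaves the abundance law unstructured", {
  st <- tree_structure(6, rep(-0.4, 6))     # 64 species, equal coefficients
  eq <- solve_self_consistency(st, 0.5)
  # all modal abundances coincide: the SAD is one truncated Gaussian
  expect_lt(diff(range(eq$modal)), 1e-8)
  grid <- seq(0, 3, length.out = 200)
  sad <- sad_density(eq, grid)
  ref <- dnorm((grid - eq$modal[1]) / eq$gamma) / eq$gamma
  expect_equal(sad$density, ref, tolerance = 1e-10)
})

test_that("power-law traits give a heavy right tail that fades with disorder", {
  st <- power_law_structure(3000, alpha = 2.2, coupling = 0.6,
                            baseline = -1.5, seed = 3)
  init <- NULL
  sk <- vapply(c(0.2, 0.6, 0.9, 1.2), function(sg) {
    eq <- solve_self_consistency(st, sg, init = init)
    init <<- list(f = eq$f_star, gamma = eq$gamma)
    x <- as.numeric(simulate(eq, seed = 5))
    s <- x[x > 0]
    mean((s - mean(s))^3) / sd(s)^3    # right-tail skewness
  }, numeric(1))
  expect_gt(sk[1], 3)            # strongly skewed at weak disorder
  expect_true(all(diff(sk) < 0))  # Gaussian blur progressively erodes the tail
})
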