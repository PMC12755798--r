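# Shared fixtures and independent oracles.

# Community with no structural component (mu = 0): zero-column trait tables.
null_structure <- function(S) {
  community_structure(matrix(0, S, 0), matrix(0, S, 0))
}

# Two equal groups in symmetric strong competition: the sigma = 0 system is
# bistable (either group excludes the other).
exclusion_structure <- function(per_group = 2) {
  suppressWarnings(
    group_structure(c(per_group, per_group), rbind(c(0, -4), c(-4, 0))))
}

# Two equal groups in stable coexistence (product of cross couplings < 1).
coexistence_structure <- function(per_group = 1000) {
  group_structure(c(per_group, per_group), rbind(c(0, -1.2), c(-0.8, 0)))
}

# Quadrature oracle for the truncated-Gaussian moments: direct numerical
# integration of the defining integral, independent of the closed forms.
omega_quadrature <- function(w, k) {
  vapply(w, function(wi)
    stats::integrate(function(z) exp(-z^2 / 2) * (wi + z)^k / sqrt(2 * pi),
                     lower = -wi, upper = Inf, rel.tol = 1e-12,
                     abs.tol = 1e-13)$value,
    numeric(1))
}

# CDF of a Gaussian(xp, gam) conditioned on being positive (survivor law).
ptrunc_gauss <- function(q, xp, gam) {
  p0 <- stats::pnorm(0, xp, gam)
  (stats::pnorm(q, xp, gam) - p0) / (1 - p0)
}

# Minimal hand-built trajectory object for unit tests of the diagnostics.
fake_traj <- function(abundances, times = seq(0, 1, length.out = ncol(abundances)),
                      st = NULL) {
  if (is.null(st))
    st <- suppressWarnings(group_structure(nrow(abundances), matrix(0)))
  traj <- list(times = times, abundances = abundances, functions = NULL,
               config = sim_config(), system = list(structure = st),
               equilibrium = FALSE, rhs_norm = NA)
  class(traj) <- "glv_sim"
  traj$functions <- crossprod(st$impact, abundances) / st$n_species
  traj
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}

# Persistent-fluctuation discriminator: late-window species variance above an
# absolute floor AND not decaying relative to the mid window (critical slowing
# makes both the fixed-point flag and any absolute threshold unreliable).
persistent_fluctuation <- function(tr, floor = 1e-7, ratio = 0.05) {
  if (tr$equilibrium) return(FALSE)
  segvar <- function(lo, hi) {
    t1 <- max(tr$times)
    k <- tr$times > lo * t1 & tr$times <= hi * t1
    mean(apply(tr$abundances[, k, drop = FALSE], 1, stats::var))
  }
  v_late <- segvar(0.75, 1)
  v_late > floor && v_late > ratio * segvar(0.5, 0.75)
}
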