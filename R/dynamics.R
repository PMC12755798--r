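#' Simulation configuration
#'
#' Settings for integrating the community dynamics
#' \eqn{dx_i/dt = x_i[1 - x_i + \sum_j A_{ij} x_j] + m}. The immigration rate
#' m keeps excluded species at a small positive abundance from which they can
#' re-invade; species whose stationary abundance stays below
#' `extinction_factor * m` are counted as extinct so that immigration does not
#' artificially inflate diversity. With the default m = 1e-8 abundances span
#' eight decades, so integration works in linear space with `abs_tol` below m
#' (log-space integration would break on the additive immigration term).
#'
#' @param m immigration rate (default 1e-8).
#' @param t_max integration horizon.
#' @param n_samples number of output intervals (uniform grid; default 400).
#' @param rel_tol,abs_tol integrator tolerances (defaults 1e-8, 1e-12;
#'   `abs_tol` must stay below `m`).
#' @param extinction_factor multiple of m below which a species counts as
#'   extinct (default 10; any factor in 10..1e4 gives the same census when
#'   surviving abundances are O(1)).
#' @param init range (min, max) of the uniform initial abundances.
#' @param init_seed seed for the initial condition draw.
#' @param equilibrium_tol max-norm of the right-hand side below which the
#'   state counts as a fixed point (default 1e-9).
#' @param window fraction of the trajectory (from the end) used for
#'   stationary statistics (default 0.5).
#' @param method integration method (default `"adams"`; the dynamics is not
#'   stiff -- all per-capita rates are O(1) even for species at the
#'   immigration floor -- and the non-stiff multistep method avoids the cost
#'   of Jacobian factorizations at large S. [integrate_glv()] falls back to
#'   `"lsoda"` if a chunk fails).
#' @param stop_at_equilibrium stop integrating once a fixed point is detected
#'   (default TRUE); chaotic or cyclic runs always use the full horizon.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(m = 1e-8, t_max = 300, n_samples = 400,
                       rel_tol = 1e-8, abs_tol = 1e-12,
                       extinction_factor = 10, init = c(0.1, 1),
                       init_seed = 1L, equilibrium_tol = 1e-9,
                       window = 0.5, stop_at_equilibrium = TRUE,
                       method = "adams") {
  stopifnot(m > 0, abs_tol < m, extinction_factor > 1,
            t_max > 0, n_samples >= 10, window > 0, window <= 1)
  structure(list(m = m, t_max = t_max, n_samples = n_samples,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 extinction_factor = extinction_factor, init = init,
                 init_seed = as.integer(init_seed),
                 equilibrium_tol = equilibrium_tol, window = window,
                 stop_at_equilibrium = stop_at_equilibrium, method = method),
            class = "sim_config")
}

# Smooth RHS: no clamping (non-smoothness breaks the step-size control);
# with m > 0 the flow is repelled from zero, transient round-off negatives
# decay back to +m/rate.
glv_rhs <- function(t, x, parms) {
  list(x * (1 - x + drop(parms$A %*% x)) + parms$m)
}

#' Integrate the community dynamics
#'
#' Solves the generalized Lotka-Volterra equations with immigration for the
#' given interaction system on a uniform output grid, using [deSolve::ode()]
#' (Adams multistep by default, with an automatic lsoda retry on failure).
#' Integration proceeds in chunks; if the right-hand side max-norm
#' falls below `equilibrium_tol` the run is declared at a fixed point and
#' (optionally) stopped early. Abundances are clamped at zero against
#' round-off; with m > 0 the exact dynamics never reaches zero.
#'
#' @param system an [interaction_system()].
#' @param config a [sim_config()].
#' @param x0 optional explicit initial abundances (length S, > 0); by default
#'   drawn uniformly from `config$init` with `config$init_seed`.
#' @param x_cap abundance above which the run is aborted as runaway growth
#'   (default 1e4; rescaled abundances are O(1), so reaching this means the
#'   community is in the unbounded-growth regime).
#' @return an object of class `glv_sim`: `times`, `abundances` (S x T),
#'   `functions` (n_F x T, the collective function magnitudes), `config`,
#'   `system`, `equilibrium` flag and final `rhs_norm`.
#' @export
integrate_glv <- function(system, config = sim_config(), x0 = NULL,
                          x_cap = 1e4) {
  stopifnot(inherits(system, "interaction_system"),
            inherits(config, "sim_config"))
  S <- system$structure$n_species
  if (is.null(x0)) {
    set.seed(config$init_seed)
    x0 <- runif(S, config$init[1], config$init[2])
  }
  if (length(x0) != S || any(x0 <= 0)) stop("x(0) must be positive, length S")

  times <- seq(0, config$t_max, length.out = config$n_samples + 1)
  n_chunks <- max(1L, min(20L, config$n_samples %/% 20L))
  breaks <- unique(round(seq(1L, length(times), length.out = n_chunks + 1L)))
  parms <- list(A = system$A, m = config$m)

  out_rows <- vector("list", length(breaks) - 1L)
  state <- x0
  eq <- FALSE
  last_norm <- Inf
  for (k in seq_len(length(breaks) - 1L)) {
    idx <- breaks[k]:breaks[k + 1L]
    sol <- suppressWarnings(
      deSolve::ode(y = state, times = times[idx], func = glv_rhs,
                   parms = parms, method = config$method,
                   rtol = config$rel_tol, atol = config$abs_tol,
                   maxsteps = 20000))
    bad <- nrow(sol) < length(idx) || any(!is.finite(sol))
    if (bad) {
      # abundances racing past any ecological scale: report runaway growth
      # rather than retrying an integration doomed by a finite-time blow-up
      fin <- sol[apply(is.finite(sol), 1, all), , drop = FALSE]
      if (nrow(fin) && max(fin[nrow(fin), -1]) > x_cap)
        stop("runaway growth (abundance above ", x_cap, ") near time ",
             format(fin[nrow(fin), 1]))
      if (config$method != "lsoda") {
        sol <- suppressWarnings(
          deSolve::ode(y = state, times = times[idx], func = glv_rhs,
                       parms = parms, method = "lsoda",
                       rtol = config$rel_tol, atol = config$abs_tol,
                       maxsteps = 20000))
        bad <- nrow(sol) < length(idx) || any(!is.finite(sol))
      }
    }
    if (bad)
      stop("integrator failure (non-finite state); last good time ",
           format(sol[max(which(apply(is.finite(sol), 1, all))), 1]))
    if (max(sol[nrow(sol), -1]) > x_cap)
      stop("runaway growth (abundance above ", x_cap, ") near time ",
           format(sol[nrow(sol), 1]))
    block <- sol[, -1, drop = FALSE]
    out_rows[[k]] <- if (k == 1L) block else block[-1, , drop = FALSE]
    state <- pmax(block[nrow(block), ], 0)
    last_norm <- max(abs(state * (1 - state + drop(parms$A %*% state)) + parms$m))
    if (last_norm < config$equilibrium_tol) {
      eq <- TRUE
      if (config$stop_at_equilibrium) break
    }
  }
  x <- t(do.call(rbind, out_rows))   # S x T
  x[x < 0] <- 0
  t_used <- times[seq_len(ncol(x))]
  traj <- structure(
    list(times = t_used, abundances = x, functions = NULL,
         config = config, system = system,
         equilibrium = eq, rhs_norm = last_norm),
    class = "glv_sim")
  traj$functions <- compute_functions(traj)
  traj
}

#' @export
print.glv_sim <- function(x, ...) {
  cat("gLV trajectory: S =", nrow(x$abundances), "| t in [0,",
      max(x$times), "] |", ncol(x$abundances), "samples |",
      if (x$equilibrium) "fixed point reached" else "not at fixed point",
      sprintf("(|rhs| = %.2e)\n", x$rhs_norm))
  invisible(x)
}

#' @export
plot.glv_sim <- function(x, what = c("functions", "species"), n_show = 20, ...) {
  what <- match.arg(what)
  y <- if (what == "functions") x$functions else x$abundances
  y <- y[seq_len(min(nrow(y), n_show)), , drop = FALSE]
  graphics::matplot(x$times, t(y), type = "l", lty = 1,
                    xlab = "time", ylab = what, ...)
  invisible(x)
}

#' Collective function magnitudes along a trajectory
#'
#' Computes \eqn{f_\lambda(t) = S^{-1}\sum_i \mathcal{I}_i(\lambda) x_i(t)},
#' the species-averaged impact-weighted abundances; identical to the
#' `functions` field stored on the trajectory.
#'
#' @param traj a `glv_sim`.
#' @return numeric n_F x T matrix.
#' @export
compute_functions <- function(traj) {
  stopifnot(inherits(traj, "glv_sim"))
  st <- traj$system$structure
  crossprod(st$impact, traj$abundances) / st$n_species
}

stationary_index <- function(traj, window) {
  t_end <- max(traj$times)
  t_start <- min(traj$times)
  keep <- traj$times >= t_end - window * (t_end - t_start)
  if (sum(keep) < 2) stop("window longer than trajectory")
  keep
}

#' Equal-time community correlator
#'
#' Time average, over the stationary window, of the species-averaged second
#' moment \eqn{S^{-1}\sum_i x_i(t)^2}; at a fixed point this is the
#' equilibrium correlator C*.
#'
#' @param traj a `glv_sim`.
#' @param window fraction of the trajectory used (default from the config).
#' @return scalar C*.
#' @export
equal_time_correlator <- function(traj, window = traj$config$window) {
  keep <- stationary_index(traj, window)
  mean(colMeans(traj$abundances[, keep, drop = FALSE]^2))
}

#' Extinction census
#'
#' Flags as extinct every species whose time-averaged abundance over the
#' stationary window is below `extinction_factor * m`, and reports the
#' surviving fraction.
#'
#' @param traj a `glv_sim`.
#' @param config a [sim_config()] supplying m and the extinction factor
#'   (default: the trajectory's own).
#' @param window stationary window fraction.
#' @return list with `survivors` (logical mask) and `phi_sim` (fraction).
#' @export
extinction_census <- function(traj, config = traj$config,
                              window = config$window) {
  keep <- stationary_index(traj, window)
  avg <- rowMeans(traj$abundances[, keep, drop = FALSE])
  survivors <- avg >= config$extinction_factor * config$m
  list(survivors = survivors, phi_sim = mean(survivors))
}

#' Analytic-signal (Hilbert) embedding of a time series
#'
#' Returns the complex analytic signal \eqn{(x - \bar x) + i\,H[x - \bar x]}
#' of a uniformly sampled series, computed by the FFT half-spectrum method.
#' Plotting imaginary against real part projects an oscillation onto a loop
#' in the complex plane, which is how synchronized group and species
#' trajectories are compared visually.
#'
#' @param series numeric vector, uniformly sampled.
#' @param times optional sample times; if given, sampling must be uniform
#'   (resample upstream otherwise).
#' @return complex vector of the same length.
#' @export
hilbert_embedding <- function(series, times = NULL) {
  if (!is.null(times)) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-8 * mean(dt))
      stop("non-uniform sampling; resample upstream")
  }
  n <- length(series)
  xc <- series - mean(series)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(xc) * h, inverse = TRUE) / n
}

#' Species- and group-level fluctuation amplitudes
#'
#' Mean (over species) temporal variance of individual abundances, and mean
#' (over functions) temporal variance of the group magnitudes rescaled to the
#' per-species abundance scale. Since \eqn{f_\lambda} is the group sum over
#' S, its variance is multiplied by \eqn{(S/s_\lambda)^2} (s_lambda = total
#' group impact), so perfectly synchronized dynamics gives equal species- and
#' group-level amplitudes, while asynchronous species fluctuations average
#' out at the group level (variance ratio ~ 1/s).
#'
#' @param traj a `glv_sim`.
#' @param window stationary window fraction.
#' @return list with `species_level` and `group_level` variances.
#' @export
fluctuation_variances <- function(traj, window = traj$config$window) {
  keep <- stationary_index(traj, window)
  x <- traj$abundances[, keep, drop = FALSE]
  f <- traj$functions[, keep, drop = FALSE]
  st <- traj$system$structure
  sp <- mean(apply(x, 1, stats::var))
  s_lambda <- colSums(st$impact)
  ok <- s_lambda > 0
  grp <- mean(apply(f[ok, , drop = FALSE], 1, stats::var) *
                (st$n_species / s_lambda[ok])^2)
  list(species_level = sp, group_level = grp)
}
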