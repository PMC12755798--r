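#' Bulk instability index
#'
#' The randomness-driven (bulk) instability criterion: the dense eigenvalue
#' cloud of the reduced Jacobian destabilizes the equilibrium when
#' \eqn{\phi^\star \sigma^2 - 1} crosses zero. Structure only enters through
#' the dependence of the surviving fraction on sigma.
#'
#' @param state a converged `glv_equilibrium`.
#' @return scalar \eqn{\phi^\star\sigma^2 - 1} (negative = bulk-stable).
#' @export
bulk_index <- function(state) {
  stopifnot(inherits(state, "glv_equilibrium"))
  state$phi_star * state$sigma^2 - 1
}

# Equilibrium abundance vector used on the pseudo-Jacobian diagonal.
# "mean": disorder-averaged abundances gamma * omega_1(x+/gamma);
# "sample": one truncated-Gaussian realization (captures the within-class
# abundance spread, which the mean variant collapses).
jacobian_abundances <- function(state, abundances = c("mean", "sample"),
                                seed = NULL) {
  abundances <- match.arg(abundances)
  if (abundances == "mean") {
    if (state$gamma > 0) state$gamma * omega_k(state$modal / state$gamma, 1)
    else pmax(state$modal, 0)
  } else {
    as.numeric(simulate(state, nsim = 1, seed = seed))
  }
}

#' Pseudo-Jacobian of the structured equilibrium
#'
#' The matrix \eqn{\mathcal{J}_{ij} = -x_i^\star(\delta_{ij} - \mu_{ij})}
#' whose collective (outlier) eigenvalues locate structure-driven
#' bifurcations. It depends on randomness only through the equilibrium
#' abundances \eqn{x_i^\star}. Two conventions for the diagonal are exposed:
#' `"mean"` uses the disorder-averaged survivor abundances
#' \eqn{\gamma\,\omega_1(x_i^+/\gamma)}; `"sample"` draws one realization of
#' the truncated-Gaussian equilibrium abundances, preserving the within-class
#' abundance spread whose associated spread of dynamical time scales is what
#' lets microscopic randomness stabilize collective oscillations -- the mean
#' variant collapses that spread and can misjudge stability, so `"sample"`
#' (averaged over draws) is the default for regime classification. An
#' explicit abundance vector (e.g. from a simulation) can also be supplied.
#' Species with survival probability below `drop_below` (or sampled at zero)
#' are removed, mirroring the reduced matrix of extant species.
#'
#' @param state a converged `glv_equilibrium`.
#' @param x_star optional abundance vector (length S) overriding `abundances`.
#' @param abundances `"mean"` or `"sample"` (see Details).
#' @param seed seed for the `"sample"` draw.
#' @param drop_below survival-probability threshold under which species are
#'   dropped (default 1e-3).
#' @return the pseudo-Jacobian over retained species, with attribute `kept`.
#' @export
pseudo_jacobian <- function(state, x_star = NULL,
                            abundances = c("mean", "sample"), seed = NULL,
                            drop_below = 1e-3) {
  stopifnot(inherits(state, "glv_equilibrium"))
  xs <- if (is.null(x_star)) jacobian_abundances(state, abundances, seed)
        else x_star
  keep <- state$survival >= drop_below & xs > 0
  mu <- structural_matrix(state$structure)[keep, keep, drop = FALSE]
  J <- -xs[keep] * (diag(sum(keep)) - mu)
  attr(J, "kept") <- keep
  J
}

#' Collective-mode (outlier) spectrum of the pseudo-Jacobian
#'
#' The pseudo-Jacobian splits into a diagonal cluster at \eqn{-x_i^\star}
#' (all strictly stable) and collective eigenvalues tied to the low-rank
#' structure. When the retained species fall into trait-equivalence classes
#' with identical diagonal entries (the `"mean"` variant on group-built
#' structures), the class-constant subspace is exactly invariant and the
#' collective spectrum is computed from the K x K reduced matrix
#' \eqn{R_{cd} = x_c^\star (n_d \tilde\mu_{cd} - \delta_{cd})}; the
#' complementary within-class modes contribute eigenvalues
#' \eqn{-x_c^\star}. Otherwise (the `"sample"` variant, or structures
#' without equivalence classes) the full spectrum is computed densely; its
#' diagonal cluster is strictly negative, so the leading real part is
#' unaffected.
#'
#' @inheritParams pseudo_jacobian
#' @return complex vector of collective eigenvalues.
#' @export
outlier_spectrum <- function(state, x_star = NULL,
                             abundances = c("mean", "sample"), seed = NULL,
                             drop_below = 1e-3) {
  stopifnot(inherits(state, "glv_equilibrium"))
  if (state$structure$n_functions == 0L) return(complex(0))
  xs <- if (is.null(x_star)) jacobian_abundances(state, abundances, seed)
        else x_star
  keep <- state$survival >= drop_below & xs > 0
  if (!any(keep)) return(complex(0))
  st <- state$structure
  traits <- cbind(st$impact, st$sensitivity, xs)[keep, , drop = FALSE]
  key <- apply(signif(traits, 12), 1, paste, collapse = "|")
  classes <- match(key, unique(key))
  K <- max(classes)
  if (K < sum(keep)) {
    first <- match(seq_len(K), classes)
    n_d <- tabulate(classes, nbins = K)
    Ik <- st$impact[keep, , drop = FALSE][first, , drop = FALSE]
    Sk <- st$sensitivity[keep, , drop = FALSE][first, , drop = FALSE]
    mu_cd <- tcrossprod(Sk, Ik) / st$n_species
    a <- xs[keep][first]
    R <- a * (sweep(mu_cd, 2, n_d, `*`) - diag(K))
    as.complex(eigen(R, only.values = TRUE)$values)
  } else {
    as.complex(eigen(pseudo_jacobian(state, x_star = xs,
                                     drop_below = drop_below),
                     only.values = TRUE)$values)
  }
}

#' Leading collective eigenvalue, averaged over abundance draws
#'
#' For the sampled-abundance convention the leading real part fluctuates
#' from draw to draw; this helper averages it (and the matching imaginary
#' part) over `n_draws` truncated-Gaussian realizations.
#'
#' @inheritParams pseudo_jacobian
#' @param n_draws number of abundance realizations (default 10).
#' @return list with `re` (mean leading real part), `im` (mean |Im| of the
#'   leading eigenvalue), `re_sd`.
#' @keywords internal
leading_collective <- function(state, abundances = "sample", n_draws = 10,
                               seed = 1L, drop_below = 1e-3) {
  if (abundances == "mean") n_draws <- 1L
  if (!is.null(seed)) set.seed(seed)
  re <- im <- numeric(n_draws)
  for (k in seq_len(n_draws)) {
    ev <- outlier_spectrum(state, abundances = abundances,
                           drop_below = drop_below)
    if (!length(ev)) { re[k] <- -Inf; im[k] <- 0; next }
    i <- which.max(Re(ev))
    re[k] <- Re(ev[i]); im[k] <- abs(Im(ev[i]))
  }
  list(re = mean(re), im = mean(im), re_sd = stats::sd(re))
}

#' Critical disorder intensity of the bulk transition
#'
#' Locates the sigma at which \eqn{\phi^\star(\sigma)\,\sigma^2 = 1} along
#' the equilibrium branch continued upward in sigma. Where the solver stops
#' converging (for a structureless community the equilibrium branch
#' terminates exactly at the transition) the indicator is treated as
#' positive, so the bisection returns the branch endpoint.
#'
#' @param structure a [community_structure()].
#' @param lower,upper sigma bracket (defaults 0.5, 3).
#' @param tol bisection tolerance on sigma (default 1e-3).
#' @param ... passed to [solve_self_consistency()].
#' @return the critical sigma.
#' @export
bulk_critical_sigma <- function(structure, lower = 0.5, upper = 3,
                                tol = 1e-3, ...) {
  init <- NULL
  indicator <- function(sg) {
    st <- tryCatch(solve_self_consistency(structure, sg, init = init, ...),
                   error = function(e) NULL)
    if (is.null(st)) return(1)
    init <<- list(f = st$f_star, gamma = st$gamma)
    bulk_index(st)
  }
  if (indicator(lower) > 0)
    stop("bulk index already positive at lower bracket")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (indicator(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Classify the dynamical regime of an equilibrium
#'
#' Combines the bulk criterion with the collective spectrum of the
#' pseudo-Jacobian: `bulk_unstable` when \eqn{\phi^\star\sigma^2 > 1},
#' `structure_hopf` when the bulk is stable but the leading collective
#' eigenvalue pair has non-negative real part and nonzero imaginary part (a
#' Hopf bifurcation of the coarse-grained variables), `structure_unstable`
#' for a real crossing, `both` when the two coexist, `stable` otherwise.
#'
#' @param state a converged `glv_equilibrium`.
#' @param abundances diagonal convention, `"sample"` (default) or `"mean"`;
#'   see [pseudo_jacobian()].
#' @param n_draws abundance draws averaged for the sampled convention.
#' @param seed seed for the draws.
#' @param im_tol imaginary-part threshold distinguishing Hopf from real
#'   crossings (default 1e-8).
#' @param drop_below survival threshold for retained species.
#' @return an object of class `stability_report` with fields `bulk_index`,
#'   `outliers` (one representative spectrum), `leading_real_part`,
#'   `leading_imag`, `classification`, `sigma`, `state`.
#' @export
classify_regime <- function(state, abundances = c("sample", "mean"),
                            n_draws = 10, seed = 1L, im_tol = 1e-8,
                            drop_below = 1e-3) {
  abundances <- match.arg(abundances)
  b <- bulk_index(state)
  lead <- leading_collective(state, abundances = abundances,
                             n_draws = n_draws, seed = seed,
                             drop_below = drop_below)
  out <- outlier_spectrum(state, abundances = abundances, seed = seed,
                          drop_below = drop_below)
  struct_unstable <- is.finite(lead$re) && lead$re >= 0
  cls <- if (b > 0 && struct_unstable) "both"
  else if (b > 0) "bulk_unstable"
  else if (struct_unstable && lead$im > im_tol) "structure_hopf"
  else if (struct_unstable) "structure_unstable"
  else "stable"
  base::structure(
    list(bulk_index = b, outliers = out, leading_real_part = lead$re,
         leading_imag = lead$im, classification = cls,
         sigma = state$sigma, state = state),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability at sigma =", x$sigma, ":", x$classification, "\n")
  cat("  bulk index phi*sigma^2 - 1 =", format(x$bulk_index, digits = 5),
      "| leading collective Re =", format(x$leading_real_part, digits = 5),
      "\n")
  invisible(x)
}

#' Scan disorder intensity and map dynamical regimes
#'
#' Solves the self-consistency equations along a sigma grid with
#' continuation (descending by default, since for strongly structured
#' communities the equilibrium branch may only exist above a threshold
#' sigma; failed points are retried from the neighbouring solution),
#' classifies every equilibrium, and brackets the transition sigmas where
#' the bulk index or the leading collective real part changes sign.
#' Optionally integrates the dynamics at each sigma, initialized at a
#' sampled realization of the theoretical equilibrium when one exists (a
#' local stability probe), and records the simulated surviving fraction and
#' fluctuation amplitudes.
#'
#' @param structure a [community_structure()].
#' @param sigma_grid ascending vector of sigma values.
#' @param simulate if TRUE, run a simulation at each sigma.
#' @param config a [sim_config()] for the simulations.
#' @param seed disorder seed for the simulations and abundance draws.
#' @param abundances diagonal convention for [classify_regime()].
#' @param n_draws abundance draws per sigma for the sampled convention.
#' @param from_top start the continuation at the largest sigma (default
#'   TRUE).
#' @param drop_below survival threshold for the pseudo-Jacobian.
#' @param ... passed to [solve_self_consistency()].
#' @return an object of class `regime_scan`: `sigma_grid`, `states`,
#'   `reports`, `table` (data frame of indices per sigma), `transitions`
#'   (bulk and structure sigma brackets), and simulation diagnostics when
#'   requested.
#' @export
sigma_scan <- function(structure, sigma_grid, simulate = FALSE,
                       config = sim_config(), seed = 1L,
                       abundances = c("sample", "mean"), n_draws = 10,
                       from_top = TRUE, drop_below = 1e-3, ...) {
  stopifnot(!is.unsorted(sigma_grid))
  abundances <- match.arg(abundances)
  n <- length(sigma_grid)
  states <- vector("list", n)
  order1 <- if (from_top) rev(seq_len(n)) else seq_len(n)
  # anchor the continuation: strongly structured communities may only admit
  # an equilibrium branch reachable from large sigma, where the cold start
  # is reliable; walk down from above the grid if needed
  init <- NULL
  if (from_top) {
    top <- max(sigma_grid)
    for (sg in seq(2 * top, top, length.out = 5)) {
      st <- tryCatch(solve_self_consistency(structure, sg, init = init, ...),
                     error = function(e) NULL)
      if (!is.null(st)) init <- list(f = st$f_star, gamma = st$gamma)
    }
  }
  for (i in order1) {
    st <- tryCatch(
      solve_self_consistency(structure, sigma_grid[i], init = init, ...),
      error = function(e) NULL)
    states[i] <- list(st)
    if (!is.null(st)) init <- list(f = st$f_star, gamma = st$gamma)
  }
  for (i in rev(order1)) {      # second sweep for failed points
    if (is.null(states[[i]])) {
      nb <- c(i - 1L, i + 1L)
      nb <- nb[nb >= 1L & nb <= n]
      for (j in nb) {
        if (is.null(states[[j]])) next
        st <- tryCatch(
          solve_self_consistency(structure, sigma_grid[i],
                                 init = list(f = states[[j]]$f_star,
                                             gamma = states[[j]]$gamma), ...),
          error = function(e) NULL)
        if (!is.null(st)) { states[i] <- list(st); break }
      }
    }
  }
  reports <- lapply(states, function(s)
    if (is.null(s)) NULL
    else classify_regime(s, abundances = abundances, n_draws = n_draws,
                         seed = seed, drop_below = drop_below))
  tab <- data.frame(
    sigma = sigma_grid,
    converged = !vapply(states, is.null, logical(1)),
    phi_star = vapply(states, function(s) if (is.null(s)) NA_real_ else s$phi_star, 1),
    gamma = vapply(states, function(s) if (is.null(s)) NA_real_ else s$gamma, 1),
    bulk_index = vapply(reports, function(r) if (is.null(r)) NA_real_ else r$bulk_index, 1),
    leading_real_part = vapply(reports, function(r)
      if (is.null(r)) NA_real_ else r$leading_real_part, 1),
    classification = vapply(reports, function(r)
      if (is.null(r)) NA_character_ else r$classification, ""))

  if (simulate) {
    ref <- Find(Negate(is.null), states)
    sims <- lapply(seq_len(n), function(i) {
      src <- if (!is.null(states[[i]])) states[[i]] else ref
      sys <- interaction_system(structure, sigma_grid[i], seed = seed)
      x0 <- if (!is.null(src))
        pmax(as.numeric(stats::simulate(src, seed = seed + 7L)), 10 * config$m)
      else NULL
      tr <- tryCatch(suppressWarnings(integrate_glv(sys, config, x0 = x0)),
                     error = function(e) NULL)
      if (is.null(tr))
        return(c(phi_sim = NA, species_var = NA, group_var = NA,
                 at_equilibrium = NA))
      fv <- fluctuation_variances(tr)
      c(phi_sim = extinction_census(tr)$phi_sim,
        species_var = fv$species_level, group_var = fv$group_level,
        at_equilibrium = as.numeric(tr$equilibrium))
    })
    tab <- cbind(tab, do.call(rbind, sims))
  }

  bracket <- function(v) {
    s <- sign(v)
    i <- which(!is.na(s[-1] * s[-n]) & s[-1] * s[-n] < 0)
    if (length(i)) cbind(lower = sigma_grid[i], upper = sigma_grid[i + 1])
    else NULL
  }
  base::structure(
    list(sigma_grid = sigma_grid, states = states, reports = reports,
         table = tab,
         transitions = list(bulk = bracket(tab$bulk_index),
                            structure = bracket(tab$leading_real_part))),
    class = "regime_scan")
}

#' @export
print.regime_scan <- function(x, ...) {
  cat("Regime scan over", length(x$sigma_grid), "sigma values\n")
  print(x$table[, setdiff(names(x$table), "converged")], digits = 4,
        row.names = FALSE)
  invisible(x)
}
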