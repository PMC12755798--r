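#' Truncated-Gaussian moments
#'
#' \eqn{\omega_k(w) = (2\pi)^{-1/2}\int_{-w}^{\infty} e^{-z^2/2}(w+z)^k\,dz},
#' the k-th moment of a unit-variance Gaussian centred at w and truncated at
#' zero. \eqn{\omega_0} is a survival probability, \eqn{\omega_1} the mean and
#' \eqn{\omega_2} the second moment of the positive part. Evaluated in closed
#' form through the standard normal distribution,
#' \deqn{\omega_0 = \Phi(w),\quad \omega_1 = w\Phi(w) + \psi(w),\quad
#'       \omega_2 = (1+w^2)\Phi(w) + w\psi(w),}
#' with an asymptotic (Mills-ratio) guard for w < -8 where the closed forms
#' lose all significant digits to cancellation.
#'
#' @param w numeric vector.
#' @param k moment order, one of 0, 1, 2.
#' @return numeric vector of the same length as `w`.
#' @export
omega_k <- function(w, k) {
  if (!(length(k) == 1L && k %in% 0:2)) stop("k must be 0, 1 or 2")
  if (any(!is.finite(w))) stop("w must be finite")
  out <- switch(as.character(k),
    "0" = stats::pnorm(w),
    "1" = w * stats::pnorm(w) + stats::dnorm(w),
    "2" = (1 + w^2) * stats::pnorm(w) + w * stats::dnorm(w))
  far <- w < -8
  if (any(far) && k > 0) {
    wf <- w[far]
    psi <- stats::dnorm(wf)
    out[far] <- if (k == 1) psi * (1 / wf^2 - 3 / wf^4)
                else        psi * (-2 / wf^3 + 12 / wf^5)
  }
  pmax(out, 0)
}

#' Modal abundances
#'
#' The affine map \eqn{x_i^+ = 1 + \sum_\lambda \mathcal{S}_i(\lambda)
#' f_\lambda^\star}: the most likely equilibrium abundance of a surviving
#' species, set entirely by the collective functions and the species' own
#' sensitivity traits (hence self-averaging, unlike individual abundances).
#'
#' @param structure a [community_structure()].
#' @param f numeric vector of function magnitudes (length n_F).
#' @return numeric vector of length S.
#' @export
modal_abundances <- function(structure, f) {
  stopifnot(inherits(structure, "community_structure"),
            length(f) == structure$n_functions)
  if (structure$n_functions == 0L) return(rep(1, structure$n_species))
  drop(1 + structure$sensitivity %*% f)
}

sigma_zero_map <- function(structure, f) {
  xp <- modal_abundances(structure, f)
  drop(crossprod(structure$impact, pmax(xp, 0))) / structure$n_species
}

#' Equilibrium function magnitudes without randomness
#'
#' Solves the closed fixed-point system for the function magnitudes at
#' sigma = 0, \eqn{f_\lambda = S^{-1}\sum_i \mathcal{I}_i(\lambda)\,
#' \max(0, 1 + \sum_\mu \mathcal{S}_i(\mu) f_\mu)}, whose solutions are the
#' Lotka-Volterra equilibria of the structured community (equilibrium
#' abundances are \eqn{\max(0, x_i^+)}). Uses support iteration: guess the
#' surviving set, solve the then-linear system for f, recompute the set,
#' repeat; falls back to damped fixed-point iteration if the support cycles.
#' The system can be multistable (competitive exclusion); the returned branch
#' is the one selected by `init`.
#'
#' @param structure a [community_structure()].
#' @param init optional initial f (length n_F); default: all species extant.
#' @param tol residual tolerance (default 1e-12).
#' @param max_iter support-iteration cap (default 200).
#' @return numeric vector f with attributes `residual` and `iterations`.
#' @export
solve_sigma_zero <- function(structure, init = NULL, tol = 1e-12,
                             max_iter = 200) {
  with_attrs <- function(f, residual, iterations) {
    attr(f, "residual") <- residual
    attr(f, "iterations") <- iterations
    f
  }
  S <- structure$n_species
  n_F <- structure$n_functions
  if (n_F == 0L) return(with_attrs(numeric(0), 0, 0L))
  I <- structure$impact
  Sn <- structure$sensitivity
  f <- if (is.null(init)) rep(0, n_F) else as.numeric(init)
  active <- modal_abundances(structure, f) > 0
  seen <- character(0)
  for (it in seq_len(max_iter)) {
    key <- paste(which(active), collapse = ",")
    if (key %in% seen) break            # support cycling: damped fallback below
    seen <- c(seen, key)
    if (!any(active)) { f <- rep(0, n_F); break }
    Ia <- I[active, , drop = FALSE]
    Sa <- Sn[active, , drop = FALSE]
    a <- colSums(Ia) / S
    B <- crossprod(Ia, Sa) / S
    f_new <- tryCatch(solve(diag(n_F) - B, a), error = function(e) NULL)
    if (is.null(f_new)) break
    f <- f_new
    new_active <- modal_abundances(structure, f) > 0
    if (identical(new_active, active)) {
      res <- max(abs(sigma_zero_map(structure, f) - f))
      if (res < tol)
        return(with_attrs(f, res, it))
    }
    active <- new_active
  }
  # damped fixed-point fallback
  d <- 0.3
  for (it2 in seq_len(5000)) {
    f_new <- sigma_zero_map(structure, f)
    res <- max(abs(f_new - f))
    f <- (1 - d) * f + d * f_new
    if (res < tol)
      return(with_attrs(f, res, max_iter + it2))
  }
  stop("sigma=0 equilibrium iteration did not converge (residual ",
       format(max(abs(sigma_zero_map(structure, f) - f))), ")")
}

#' Enumerate all sigma = 0 equilibria of a group-built community
#'
#' For structures with recorded groups and few of them, lists every
#' Lotka-Volterra equilibrium by enumerating subsets of surviving groups,
#' solving the linear system on each support and keeping the feasible ones
#' (surviving groups at positive modal abundance, excluded groups at
#' negative). Useful because the sigma = 0 system can be multistable.
#'
#' @param structure a group-built [community_structure()] with at most
#'   `max_groups` groups.
#' @param max_groups enumeration cap (default 12).
#' @return list of feasible f vectors.
#' @export
sigma_zero_equilibria <- function(structure, max_groups = 12) {
  if (is.null(structure$group_ids))
    stop("support enumeration needs a group-built structure")
  k <- structure$n_functions
  if (k > max_groups) stop("too many groups to enumerate (", k, ")")
  S <- structure$n_species
  I <- structure$impact
  Sn <- structure$sensitivity
  sizes <- tabulate(structure$group_ids, nbins = k)
  first <- match(seq_len(k), structure$group_ids)
  out <- list()
  for (mask in 0:(2^k - 1)) {
    act_g <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    f <- rep(0, k)
    if (any(act_g)) {
      active <- act_g[structure$group_ids]
      Ia <- I[active, , drop = FALSE]
      Sa <- Sn[active, , drop = FALSE]
      f <- tryCatch(solve(diag(k) - crossprod(Ia, Sa) / S, colSums(Ia) / S),
                    error = function(e) NULL)
      if (is.null(f)) next
    }
    xg <- modal_abundances(structure, f)[first]   # one representative per group
    if (all(xg[act_g] > 1e-12) && all(xg[!act_g] < -1e-12))
      out[[length(out) + 1L]] <- f
  }
  out
}

# Root of the heterogeneity relation 1 = sigma^2 * mean_i omega_2(x+ / gamma)
# for fixed modal abundances; returns NA when no positive root exists.
solve_gamma <- function(xp, sigma, gamma_prev = NULL,
                        lo = 1e-8, hi = 1e4, n_scan = 400) {
  h <- function(g) sigma^2 * mean(omega_k(xp / g, 2)) - 1
  grid <- exp(seq(log(lo), log(hi), length.out = n_scan))
  hv <- vapply(grid, h, numeric(1))
  sgn <- sign(hv)
  idx <- which(sgn[-1] * sgn[-n_scan] < 0)
  if (length(idx) == 0) return(NA_real_)
  if (length(idx) > 1 && !is.null(gamma_prev)) {
    mid <- sqrt(grid[idx] * grid[idx + 1])
    idx <- idx[which.min(abs(log(mid) - log(gamma_prev)))]
  } else idx <- idx[1]
  stats::uniroot(h, c(grid[idx], grid[idx + 1]), tol = 1e-14)$root
}

#' Solve the macroscopic self-consistency equations
#'
#' Jointly solves, for a structured community with disorder intensity sigma,
#' the closed set of n_F + 1 equilibrium relations
#' \deqn{f_\lambda = \frac{\gamma}{S}\sum_i \mathcal{I}_i(\lambda)\,
#'   \omega_1(x_i^+/\gamma), \qquad
#'   1 = \frac{\sigma^2}{S}\sum_i \omega_2(x_i^+/\gamma),}
#' with \eqn{x_i^+ = 1 + \sum_\lambda \mathcal{S}_i(\lambda) f_\lambda}. The
#' scheme is damped fixed-point iteration on f (damping 0.5) with a nested
#' bracketed 1-D root solve for gamma at every step, followed by a
#' finite-difference Newton polish on (f, log gamma); plain Newton is used as
#' fallback when the damped iteration stalls. Initialization defaults to
#' continuation from the sigma = 0 solution with a small gamma floor; pass
#' `init` to follow a particular branch (the sigma = 0 system can be
#' multistable).
#'
#' @param structure a [community_structure()].
#' @param sigma disorder intensity > 0 (sigma = 0 delegates to
#'   [solve_sigma_zero()]).
#' @param init optional list with elements `f` and `gamma`.
#' @param tol residual tolerance on the relations (default 1e-9).
#' @param max_iter damped-iteration cap (default 400).
#' @param damping damping factor in (0, 1] (default 0.5).
#' @return an object of class `glv_equilibrium` with fields `f_star`,
#'   `gamma`, `C_star`, `modal`, `phi_star`, `survival`, `sigma`,
#'   `residual`, `converged`, `structure`.
#' @export
solve_self_consistency <- function(structure, sigma, init = NULL,
                                   tol = 1e-9, max_iter = 400,
                                   damping = 0.5) {
  stopifnot(inherits(structure, "community_structure"), sigma >= 0)
  S <- structure$n_species
  n_F <- structure$n_functions
  I <- structure$impact

  if (sigma == 0) {
    f <- solve_sigma_zero(structure, init = init$f)
    xp <- modal_abundances(structure, as.numeric(f))
    return(new_equilibrium(structure, sigma = 0, f = as.numeric(f), gamma = 0,
                           xp = xp, residual = attr(f, "residual"),
                           converged = TRUE))
  }

  f <- init$f
  if (is.null(f)) {
    f <- tryCatch(as.numeric(solve_sigma_zero(structure)),
                  error = function(e) rep(colMeans(I), length.out = n_F))
  }
  gamma <- if (!is.null(init$gamma) && init$gamma > 0) init$gamma else 1e-6

  residual_of <- function(f, gamma) {
    xp <- modal_abundances(structure, f)
    w <- xp / gamma
    r_f <- gamma * drop(crossprod(I, omega_k(w, 1))) / S - f
    r_g <- sigma^2 * mean(omega_k(w, 2)) - 1
    max(abs(c(r_f, r_g)))
  }

  newton_try <- function(f0, gamma0) {
    g_fun <- function(theta) {
      fv <- theta[seq_len(n_F)]
      gv <- exp(theta[n_F + 1])
      xp <- modal_abundances(structure, fv)
      w <- xp / gv
      c(gv * drop(crossprod(I, omega_k(w, 1))) / S - fv,
        sigma^2 * mean(omega_k(w, 2)) - 1)
    }
    theta <- c(f0, log(max(gamma0, 1e-10)))
    for (nit in seq_len(80)) {
      gv <- g_fun(theta)
      if (max(abs(gv)) < tol) return(list(f = theta[seq_len(n_F)],
                                          gamma = exp(theta[n_F + 1])))
      J <- numeric_jacobian(g_fun, theta)
      step <- tryCatch(solve(J, -gv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        theta_new <- theta + lam * step
        if (max(abs(g_fun(theta_new))) < max(abs(gv)) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (lam < 1e-4) return(NULL)
      theta <- theta_new
    }
    NULL
  }

  converged <- FALSE
  # with a supplied starting point (continuation along a branch), Newton
  # tracks the branch even where the damped fixed-point map is unstable
  if (!is.null(init$f)) {
    sol <- newton_try(f, gamma)
    if (!is.null(sol)) {
      f <- sol$f; gamma <- sol$gamma; converged <- TRUE
    }
  }
  best <- list(res = Inf, f = f, gamma = gamma)
  if (!converged) for (it in seq_len(max_iter)) {
    xp <- modal_abundances(structure, f)
    g <- solve_gamma(xp, sigma, gamma_prev = gamma)
    if (is.na(g)) break
    gamma <- g
    f_new <- gamma * drop(crossprod(I, omega_k(xp / gamma, 1))) / S
    res <- residual_of(f_new, gamma)
    if (res < best$res) best <- list(res = res, f = f_new, gamma = gamma)
    if (res < tol) { f <- f_new; converged <- TRUE; break }
    f <- (1 - damping) * f + damping * f_new
  }

  if (!converged) {
    sol <- newton_try(best$f, best$gamma)
    if (!is.null(sol)) { f <- sol$f; gamma <- sol$gamma; converged <- TRUE }
  }

  xp <- modal_abundances(structure, f)
  res <- residual_of(f, gamma)
  if (!converged && res > tol)
    stop("self-consistency solver did not converge at sigma = ", sigma,
         " (residual ", format(res, digits = 3), ")")
  new_equilibrium(structure, sigma = sigma, f = f, gamma = gamma, xp = xp,
                  residual = res, converged = TRUE)
}

numeric_jacobian <- function(fun, x, eps = 1e-7) {
  f0 <- fun(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    dx <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + dx
    J[, j] <- (fun(xp) - f0) / dx
  }
  J
}

new_equilibrium <- function(structure, sigma, f, gamma, xp, residual,
                            converged) {
  if (gamma > 0) {
    surv <- omega_k(xp / gamma, 0)
  } else {
    surv <- as.numeric(xp > 0)
  }
  base::structure(
    list(structure = structure, sigma = sigma, f_star = f, gamma = gamma,
         C_star = if (sigma > 0) (gamma / sigma)^2 else
           mean(pmax(xp, 0)^2),
         modal = xp, phi_star = mean(surv), survival = surv,
         residual = residual, converged = converged),
    class = "glv_equilibrium")
}

#' @export
print.glv_equilibrium <- function(x, ...) {
  cat("Macroscopic equilibrium (sigma =", x$sigma, ")\n")
  cat("  f* :", paste(format(utils::head(x$f_star, 8), digits = 4),
                      collapse = " "),
      if (length(x$f_star) > 8) "...\n" else "\n")
  cat("  gamma =", format(x$gamma, digits = 5),
      "| C* =", format(x$C_star, digits = 5),
      "| phi* =", format(x$phi_star, digits = 5), "\n")
  cat("  residual", format(x$residual, digits = 3),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' @export
summary.glv_equilibrium <- function(object, ...) {
  st <- object$structure
  out <- list(sigma = object$sigma, f_star = object$f_star,
              gamma = object$gamma, C_star = object$C_star,
              phi_star = object$phi_star)
  if (!is.null(st$group_ids)) {
    first <- match(seq_len(st$n_functions), st$group_ids)
    out$group_modal <- object$modal[first]
    out$group_survival <- object$survival[first]
  }
  class(out) <- "summary.glv_equilibrium"
  out
}

#' @export
print.summary.glv_equilibrium <- function(x, ...) {
  cat("sigma =", x$sigma, " gamma =", format(x$gamma, digits = 5),
      " C* =", format(x$C_star, digits = 5),
      " phi* =", format(x$phi_star, digits = 5), "\n")
  if (!is.null(x$group_modal)) {
    print(data.frame(f_star = x$f_star, modal = x$group_modal,
                     survival = x$group_survival))
  }
  invisible(x)
}

#' @export
coef.glv_equilibrium <- function(object, ...) {
  c(setNames(object$f_star,
             paste0("f", seq_along(object$f_star))),
    gamma = object$gamma, phi_star = object$phi_star,
    C_star = object$C_star)
}

#' Analytic species abundance distribution
#'
#' The equilibrium SAD is an atom of mass \eqn{1-\phi^\star} at zero
#' (extinct species) plus, for x > 0, the species-averaged mixture of
#' Gaussians of width gamma centred on the modal abundances,
#' \eqn{\rho_+(x) = (S\gamma)^{-1}\sum_i \psi((x - x_i^+)/\gamma)}. The
#' species average (1/S) makes the total mass one, consistent with the
#' diversity being the species-averaged survival probability. For a
#' sigma = 0 state (gamma = 0) the continuous part degenerates to point
#' masses at the distinct positive modal abundances.
#'
#' @param state a converged `glv_equilibrium`.
#' @param grid abundance grid (>= 0) on which to evaluate the density.
#' @return a list of class `sad_model`: `grid`, `density`, `zero_mass`, and
#'   for gamma = 0 a two-column matrix `atoms` (abundance, weight).
#' @export
sad_density <- function(state, grid = NULL) {
  stopifnot(inherits(state, "glv_equilibrium"))
  xp <- state$modal
  S <- length(xp)
  if (state$gamma == 0) {
    pos <- round(xp[xp > 0], 12)
    tab <- table(pos)
    atoms <- cbind(abundance = as.numeric(names(tab)),
                   weight = as.numeric(tab) / S)
    return(structure(list(grid = NULL, density = NULL,
                          zero_mass = 1 - state$phi_star, atoms = atoms,
                          state = state), class = "sad_model"))
  }
  if (is.null(grid))
    grid <- seq(0, max(xp + 5 * state$gamma, state$gamma), length.out = 512)
  dens <- vapply(grid, function(x)
    mean(stats::dnorm((x - xp) / state$gamma)) / state$gamma, numeric(1))
  structure(list(grid = grid, density = dens,
                 zero_mass = 1 - state$phi_star, atoms = NULL, state = state),
            class = "sad_model")
}

#' @export
print.sad_model <- function(x, ...) {
  cat("Species abundance distribution: zero mass",
      format(x$zero_mass, digits = 4))
  if (is.null(x$atoms)) cat(", continuous part on [",
                            format(min(x$grid), digits = 3), ",",
                            format(max(x$grid), digits = 3), "]\n")
  else cat(",", nrow(x$atoms), "atom(s)\n")
  invisible(x)
}

#' @export
plot.glv_equilibrium <- function(x, grid = NULL, ...) {
  sad <- sad_density(x, grid)
  if (is.null(sad$atoms)) {
    graphics::plot(sad$grid, sad$density, type = "l",
                   xlab = "abundance", ylab = "density", ...)
  } else {
    graphics::plot(sad$atoms[, 1], sad$atoms[, 2], type = "h",
                   xlab = "abundance", ylab = "weight", ...)
  }
  invisible(x)
}

#' Draw equilibrium abundances from the truncated-Gaussian law
#'
#' One realization of the quenched randomness corresponds to abundances
#' \eqn{x_i^\star = \max(0, x_i^+ + \gamma\,\xi_i)} with i.i.d. standard
#' Gaussian \eqn{\xi_i}. `simulate` returns `nsim` such draws.
#'
#' @param object a converged `glv_equilibrium`.
#' @param nsim number of replicate communities (default 1).
#' @param seed optional integer seed.
#' @param ... unused.
#' @return S x nsim matrix of abundances.
#' @export
simulate.glv_equilibrium <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$modal)
  if (object$gamma == 0)
    return(matrix(pmax(object$modal, 0), S, nsim))
  xi <- matrix(stats::rnorm(S * nsim), S, nsim)
  pmax(object$modal + object$gamma * xi, 0)
}
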