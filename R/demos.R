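#' Two-group showcase community
#'
#' The default two-group community used throughout the package: group 1 is
#' larger but less competitive, group 2 smaller but more competitive, so that
#' without randomness group 2 excludes group 1, while increasing disorder
#' rescues the excluded group and can eventually reverse the functional
#' dominance.
#'
#' @param S total number of species (default 2000).
#' @param fractions group size fractions (default c(0.75, 0.25)).
#' @param group_matrix 2 x 2 coupling matrix; default
#'   `rbind(c(0, -6), c(-2, 0))` (column effect on row growth).
#' @return a [community_structure()].
#' @export
two_group_structure <- function(S = 2000,
                                fractions = c(0.75, 0.25),
                                group_matrix = rbind(c(0, -6), c(-2, 0))) {
  sizes <- round(S * fractions)
  group_structure(sizes, group_matrix, labels = c("group1", "group2"))
}

#' Two-group demonstration: rescue, dominance reversal, diversity peak
#'
#' Runs the macroscopic theory along a sigma grid for the two-group
#' community (continuation from the sigma = 0 exclusion equilibrium),
#' optionally cross-checks a subset of sigmas with direct simulation, and
#' reports the qualitative signatures: exclusion of group 1 at sigma = 0,
#' rescue by randomness, reversal of group dominance, and a non-monotone
#' total diversity.
#'
#' @param sigma_grid ascending sigma values (default seq(0, 1.4, by = 0.1)).
#' @param structure the community (default [two_group_structure()]).
#' @param sim_sigmas sigma values at which to also simulate (default none).
#' @param seeds disorder seeds per simulated sigma (default 1:3).
#' @param config a [sim_config()] for the simulations.
#' @return list of class `two_group_demo`: `theory` (data frame with f1, f2,
#'   phi per group and total, gamma vs sigma), `simulation` (data frame or
#'   NULL), and logical `flags` (`exclusion_at_zero`, `rescue`,
#'   `dominance_reversal`, `diversity_nonmonotone`).
#' @export
run_two_group_demo <- function(sigma_grid = seq(0, 1.4, by = 0.1),
                               structure = two_group_structure(),
                               sim_sigmas = numeric(0), seeds = 1:3,
                               config = sim_config()) {
  stopifnot(structure$n_functions == 2L)
  first <- match(1:2, structure$group_ids)
  # sigma = 0 branch: group 2 wins (start from group-2 dominance)
  f0 <- solve_sigma_zero(structure, init = c(0, mean(structure$group_ids == 2)))
  rows <- vector("list", length(sigma_grid))
  init <- list(f = as.numeric(f0), gamma = 1e-6)
  for (i in seq_along(sigma_grid)) {
    sg <- sigma_grid[i]
    st <- if (sg == 0) solve_self_consistency(structure, 0, init = init)
          else solve_self_consistency(structure, sg, init = init)
    if (st$sigma > 0) init <- list(f = st$f_star, gamma = st$gamma)
    surv_g <- st$survival[first]
    rows[[i]] <- data.frame(sigma = sg, f1 = st$f_star[1], f2 = st$f_star[2],
                            gamma = st$gamma, phi = st$phi_star,
                            phi_group1 = surv_g[1], phi_group2 = surv_g[2])
  }
  theory <- do.call(rbind, rows)

  simulation <- NULL
  if (length(sim_sigmas)) {
    sim_rows <- list()
    for (sg in sim_sigmas) for (sd in seeds) {
      sys <- interaction_system(structure, sg, seed = sd)
      tr <- integrate_glv(sys, config)
      keep <- stationary_index(tr, config$window)
      fbar <- rowMeans(tr$functions[, keep, drop = FALSE])
      cen <- extinction_census(tr)
      sim_rows[[length(sim_rows) + 1L]] <-
        data.frame(sigma = sg, seed = sd, f1 = fbar[1], f2 = fbar[2],
                   phi = cen$phi_sim)
    }
    simulation <- do.call(rbind, sim_rows)
  }

  flags <- list(
    exclusion_at_zero = theory$f1[1] == 0 && theory$f2[1] > 0,
    rescue = any(theory$phi_group1[theory$sigma > 0] > 0.05),
    dominance_reversal = theory$f1[1] < theory$f2[1] &&
      any(theory$f1 > theory$f2),
    diversity_nonmonotone = {
      ph <- theory$phi
      which.max(ph) > 1 && which.max(ph) < length(ph) &&
        max(ph) > ph[1] && max(ph) > ph[length(ph)]
    })
  base::structure(list(theory = theory, simulation = simulation,
                       flags = flags, structure = structure),
                  class = "two_group_demo")
}

#' @export
print.two_group_demo <- function(x, ...) {
  cat("Two-group demo over sigma in [", min(x$theory$sigma), ",",
      max(x$theory$sigma), "]\n")
  cat("  flags:", paste(names(which(unlist(x$flags))), collapse = ", "), "\n")
  print(utils::head(x$theory), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Many-groups demonstration: regime sequence under increasing randomness
#'
#' Simulates the many-groups community (disordered group couplings, chaotic
#' at sigma = 0) at a set of within-group disorder intensities and collects
#' the diagnostics of the regime sequence synchronized-chaos -> limit cycle
#' -> fixed point -> asynchronous species chaos: fluctuation amplitudes at
#' species and group level, simulated diversity, fixed-point flags, and the
#' analytic-signal embedding of the first group magnitude. A theory-side
#' [sigma_scan()] supplies the bulk and collective transition estimates.
#'
#' @param structure a [many_groups_structure()]; default 15 groups of 40
#'   species (the group count scaled down, the group size kept at the
#'   showcase value), a size at which the full pipeline runs in minutes.
#' @param sigma_values disorder intensities to simulate.
#' @param theory_grid sigma grid for the macroscopic scan.
#' @param config a [sim_config()]; the default uses a long horizon so the
#'   stationary window excludes transients.
#' @param seed disorder seed for the within-group randomness.
#' @return list of class `many_groups_demo`: `table` (per-sigma diagnostics),
#'   `embeddings` (complex trajectories of f_1), `scan` (the regime scan),
#'   `transitions`.
#' @export
run_many_groups_demo <- function(structure = many_groups_structure(15, 40,
                                                                   seed = 3),
                                 sigma_values = c(0, 1, 1.6, 2.2),
                                 theory_grid = seq(1, 2.5, by = 0.125),
                                 config = sim_config(t_max = 800,
                                                     n_samples = 800),
                                 seed = 1L) {
  rows <- list()
  embeddings <- list()
  for (sg in sigma_values) {
    sys <- interaction_system(structure, sg, seed = seed)
    tr <- integrate_glv(sys, config)
    fv <- fluctuation_variances(tr)
    keep <- stationary_index(tr, config$window)
    embeddings[[as.character(sg)]] <-
      hilbert_embedding(tr$functions[1, keep])
    rows[[length(rows) + 1L]] <- data.frame(
      sigma = sg, at_equilibrium = tr$equilibrium,
      species_var = fv$species_level, group_var = fv$group_level,
      phi_sim = extinction_census(tr)$phi_sim)
  }
  scan <- sigma_scan(structure, theory_grid)
  base::structure(
    list(table = do.call(rbind, rows), embeddings = embeddings,
         scan = scan, transitions = scan$transitions,
         structure = structure),
    class = "many_groups_demo")
}

#' @export
print.many_groups_demo <- function(x, ...) {
  cat("Many-groups demo (", x$structure$n_functions, "groups x",
      sum(x$structure$group_ids == 1L), "species )\n")
  print(x$table, digits = 4, row.names = FALSE)
  tr <- x$transitions
  if (!is.null(tr$structure))
    cat("  collective (Hopf) crossing in [", tr$structure[1, 1], ",",
        tr$structure[1, 2], "]\n")
  if (!is.null(tr$bulk))
    cat("  bulk crossing in [", tr$bulk[1, 1], ",", tr$bulk[1, 2], "]\n")
  invisible(x)
}
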