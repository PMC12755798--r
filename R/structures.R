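#' Community structure from impact and sensitivity traits
#'
#' A `community_structure` holds the two trait tables that mediate structured
#' interactions through a small set of collective functions. The impact trait
#' \eqn{\mathcal{I}_i(\lambda)} is the per-capita contribution of species
#' \eqn{i} to function \eqn{\lambda}; the sensitivity trait
#' \eqn{\mathcal{S}_i(\lambda)} is the effect of function \eqn{\lambda} on the
#' per-capita growth rate of species \eqn{i}. The structural interaction
#' matrix is \eqn{\mu_{ij} = S^{-1}\sum_\lambda \mathcal{S}_i(\lambda)
#' \mathcal{I}_j(\lambda)}, so its rank is at most the number of functions.
#'
#' Orientation convention (worked 2x2 example): with one function, impact
#' column \eqn{(1, 0)} and sensitivity column \eqn{(-2, -3)},
#' \eqn{\mu = \frac{1}{2}\begin{pmatrix}-2 & 0\\ -3 & 0\end{pmatrix}}:
#' sensitivity selects the *row* (who is affected), impact the *column*
#' (who acts).
#'
#' @param impact numeric S x n_F matrix of impact traits.
#' @param sensitivity numeric S x n_F matrix of sensitivity traits, same shape.
#' @param labels optional character vector of function names (length n_F).
#' @param group_ids optional integer vector (length S) recording, for
#'   group-built structures, which group each species belongs to.
#' @param check_low_rank if `TRUE` (default), require n_F < S and warn when
#'   n_F exceeds S/10, since the macroscopic theory assumes few functions
#'   relative to species. The balanced-tree builder, whose function set is one
#'   per internal node, disables the warning.
#' @return an object of class `community_structure` with fields `impact`,
#'   `sensitivity`, `n_species`, `n_functions`, `labels`, `group_ids`.
#' @export
community_structure <- function(impact, sensitivity, labels = NULL,
                                group_ids = NULL, check_low_rank = TRUE) {
  impact <- as.matrix(impact)
  sensitivity <- as.matrix(sensitivity)
  if (!identical(dim(impact), dim(sensitivity)))
    stop("impact and sensitivity must have identical shapes")
  if (!all(is.finite(impact)) || !all(is.finite(sensitivity)))
    stop("trait tables must be finite")
  S <- nrow(impact)
  n_F <- ncol(impact)
  if (S < 1L) stop("need at least one species")
  if (n_F > S)
    stop("number of functions (", n_F, ") cannot exceed the number of species (", S, ")")
  if (check_low_rank && n_F > S / 10)
    warning("n_F = ", n_F, " is not small compared to S = ", S,
            "; the macroscopic theory assumes n_F << S", call. = FALSE)
  if (!is.null(labels) && length(labels) != n_F)
    stop("labels must have length n_F")
  if (!is.null(group_ids)) {
    group_ids <- as.integer(group_ids)
    if (length(group_ids) != S) stop("group_ids must have length S")
  }
  structure(
    list(impact = impact, sensitivity = sensitivity,
         n_species = S, n_functions = n_F,
         labels = labels, group_ids = group_ids),
    class = "community_structure")
}

#' @export
print.community_structure <- function(x, ...) {
  cat("Community structure:", x$n_species, "species,",
      x$n_functions, "collective function(s)\n")
  if (!is.null(x$group_ids))
    cat("  group sizes:", paste(tabulate(x$group_ids), collapse = ", "), "\n")
  mu <- structural_matrix(x)
  cat("  structural matrix entries in [", format(min(mu), digits = 4), ",",
      format(max(mu), digits = 4), "]\n")
  invisible(x)
}

#' Structural interaction matrix
#'
#' Contracts the trait tables into the S x S low-rank structural matrix
#' \eqn{\mu_{ij} = S^{-1}\sum_\lambda \mathcal{S}_i(\lambda)\mathcal{I}_j(\lambda)}.
#'
#' @param structure a [community_structure()].
#' @return numeric S x S matrix of rank at most `n_functions`.
#' @export
structural_matrix <- function(structure) {
  stopifnot(inherits(structure, "community_structure"))
  tcrossprod(structure$sensitivity, structure$impact) / structure$n_species
}

#' Functional-group structure
#'
#' Non-overlapping functional groups: the collective functions are the total
#' (species-averaged) biomasses of the groups. Impact is the membership
#' indicator; the sensitivity of every species in group g to function lambda
#' is `group_matrix[g, lambda]`.
#'
#' @param group_sizes vector of positive integers, one per group.
#' @param group_matrix square numeric matrix of group-to-group couplings,
#'   side `length(group_sizes)`; entry (g, lambda) is the effect of group
#'   lambda's biomass on the growth of group-g species.
#' @param labels optional function names.
#' @return a [community_structure()] with `group_ids` recorded.
#' @export
group_structure <- function(group_sizes, group_matrix, labels = NULL) {
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1L)) stop("all groups must be non-empty")
  group_matrix <- as.matrix(group_matrix)
  k <- length(group_sizes)
  if (!all(dim(group_matrix) == k))
    stop("group_matrix must be square with side length(group_sizes)")
  g <- rep(seq_len(k), group_sizes)
  impact <- matrix(0, length(g), k)
  impact[cbind(seq_along(g), g)] <- 1
  sensitivity <- group_matrix[g, , drop = FALSE]
  community_structure(impact, sensitivity, labels = labels, group_ids = g)
}

#' Trait-mediated (public goods / resource) structure
#'
#' Wraps arbitrary impact and sensitivity tables verbatim, for structures
#' where functions are e.g. public-good or resource levels: impact encodes
#' consumption or production, sensitivity the yield-weighted growth response.
#'
#' @inheritParams community_structure
#' @return a [community_structure()].
#' @export
trait_structure <- function(impact, sensitivity, labels = NULL) {
  community_structure(impact, sensitivity, labels = labels)
}

#' Power-law sensitivity structure
#'
#' Single collective function (the community's total average abundance,
#' impact identically 1) with heavy-tailed sensitivities
#' \eqn{\mathcal{S}_i = baseline + coupling \cdot P_i}, where \eqn{P_i} are
#' Pareto(alpha) draws with unit minimum. A negative baseline keeps the mean
#' response competitive so a finite equilibrium exists, while the heavy
#' positive tail produces a power-law right tail in the structure-driven
#' species abundance distribution.
#'
#' @param S number of species.
#' @param alpha Pareto tail exponent (> 1; default 2.5).
#' @param coupling scale of the heavy-tailed part (default 0.5).
#' @param baseline constant offset of the sensitivities (default -2).
#' @param seed integer seed for the Pareto draws.
#' @return a [community_structure()] with one function.
#' @export
power_law_structure <- function(S, alpha = 2.5, coupling = 0.5,
                                baseline = -2, seed = 1L) {
  stopifnot(alpha > 1)
  set.seed(seed)
  pareto <- runif(S)^(-1 / alpha)
  trait_structure(impact = matrix(1, S, 1),
                  sensitivity = matrix(baseline + coupling * pareto, S, 1),
                  labels = "total_abundance")
}

#' Balanced binary tree (phylogenetic) structure
#'
#' Species are the 2^depth leaves of a balanced binary tree; each internal
#' node (subtree) defines one collective function, its species-averaged total
#' biomass. A species impacts every subtree it belongs to (indicator), and its
#' sensitivity to a subtree at level l (l = 1 is the root) is
#' `level_coefficients[l]` if it is a member and 0 otherwise, so interactions
#' between two species are set by the coefficients of all their shared
#' ancestors -- a nested, block-constant (fractal) structural matrix.
#'
#' @param depth tree depth (>= 1); S = 2^depth species, 2^depth - 1 functions.
#' @param level_coefficients numeric vector of length `depth`, sensitivity
#'   coefficient per tree level, root first.
#' @return a [community_structure()].
#' @export
tree_structure <- function(depth, level_coefficients) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (length(level_coefficients) != depth)
    stop("need one level coefficient per tree level")
  S <- 2L^depth
  n_F <- S - 1L
  impact <- matrix(0, S, n_F)
  sensitivity <- matrix(0, S, n_F)
  lab <- character(n_F)
  node <- 0L
  for (lev in seq_len(depth)) {
    n_nodes <- 2L^(lev - 1L)
    width <- S %/% n_nodes          # leaves per subtree at this level
    for (k in seq_len(n_nodes)) {
      node <- node + 1L
      members <- ((k - 1L) * width + 1L):(k * width)
      impact[members, node] <- 1
      sensitivity[members, node] <- level_coefficients[lev]
      lab[node] <- paste0("L", lev, ".", k)
    }
  }
  community_structure(impact, sensitivity, labels = lab,
                      check_low_rank = FALSE)
}

#' Many-groups structure with strong heterogeneous competitive couplings
#'
#' A large set of functional groups whose pairwise couplings are strong,
#' heterogeneous and competitive: on the scale of group mean abundances the
#' group-level Lotka-Volterra system has interaction coefficients
#' \eqn{-u_{\lambda\mu}} with \eqn{u \sim
#' \mathrm{Uniform}(\bar a(1-spread), \bar a(1+spread))} i.i.d., zero
#' diagonal, so the trait-table entries are \eqn{b_{\lambda\mu} = -n_F\,
#' u_{\lambda\mu}}. With mean competition \eqn{\bar a} around 1 (comparable
#' to self-regulation) and weak immigration, many realizations show
#' persistent turnover between a few dominant and many rare groups rather
#' than a fixed point; being purely competitive the dynamics is bounded.
#' Realizations differ: pick a `seed` whose group dynamics has the character
#' (chaotic, cyclic, stable) the experiment calls for.
#'
#' @param n_groups number of functional groups (n_F).
#' @param species_per_group species per group (s); S = n_groups * s.
#' @param competition_mean mean group-group competition strength on the
#'   group-level scale (default 1).
#' @param spread relative half-width of the uniform coupling distribution
#'   (default 1, i.e. couplings in (0, 2 * competition_mean)).
#' @param seed integer seed for the group-matrix draw.
#' @return a [community_structure()] with `group_ids`; the sampled group
#'   matrix is attached as attribute `"group_matrix"` together with the seed.
#' @export
many_groups_structure <- function(n_groups, species_per_group,
                                  competition_mean = 1, spread = 1,
                                  seed = 1L) {
  stopifnot(n_groups >= 1L, species_per_group >= 1L, competition_mean >= 0,
            spread >= 0, spread <= 1)
  set.seed(seed)
  u <- matrix(runif(n_groups^2, competition_mean * (1 - spread),
                    competition_mean * (1 + spread)), n_groups, n_groups)
  b <- -n_groups * u
  diag(b) <- 0
  st <- group_structure(rep(species_per_group, n_groups), b)
  attr(st, "group_matrix") <- b
  attr(st, "seed") <- as.integer(seed)
  st
}

#' Recover traits from a low-rank interaction matrix
#'
#' Inverts the trait contraction by singular value decomposition of
#' \eqn{S \cdot \mu}: singular triplets with singular value above
#' `rank_tolerance` times the largest are kept, and traits are split as
#' \eqn{\mathcal{S} = U_r \sqrt{D_r}}, \eqn{\mathcal{I} = V_r \sqrt{D_r}},
#' so that the structural matrix of the result reproduces the input. The
#' recovered traits span the same functional space but need not correspond to
#' named ecological processes.
#'
#' @param matrix square numeric matrix (a candidate structural matrix).
#' @param rank_tolerance relative singular-value cutoff (default 1e-10).
#' @return a [community_structure()]; errors if the retained rank reaches
#'   S/2, i.e. the matrix is not low-rank structured.
#' @export
decompose_structure <- function(matrix, rank_tolerance = 1e-10) {
  matrix <- as.matrix(matrix)
  S <- nrow(matrix)
  if (ncol(matrix) != S) stop("matrix must be square")
  sv <- svd(S * matrix)
  if (sv$d[1] <= 0) {   # zero matrix: empty trait set
    return(structure(
      list(impact = matrix(0, S, 0), sensitivity = matrix(0, S, 0),
           n_species = S, n_functions = 0L, labels = NULL, group_ids = NULL),
      class = "community_structure"))
  }
  keep <- sv$d > rank_tolerance * sv$d[1]
  r <- sum(keep)
  if (r >= S / 2)
    stop("matrix is not low-rank structured (retained rank ", r,
         " >= S/2 = ", S / 2, ")")
  root_d <- sqrt(sv$d[keep])
  community_structure(
    impact = sweep(sv$v[, keep, drop = FALSE], 2, root_d, `*`),
    sensitivity = sweep(sv$u[, keep, drop = FALSE], 2, root_d, `*`),
    check_low_rank = FALSE)
}
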