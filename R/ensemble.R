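#' Sample the random interaction component
#'
#' Draws the i.i.d. disorder matrix z: off-diagonal entries have zero mean and
#' unit variance, the diagonal is zero (self-regulation is already carried by
#' the -x_i term of the dynamics, and perturbing it would silently change the
#' model). The distribution tag exists to test universality: macroscopic
#' predictions depend only on the variance.
#'
#' @param S number of species.
#' @param seed integer seed; the draw is reproducible from (S, seed,
#'   distribution).
#' @param distribution `"gaussian"` (default) or `"uniform"` (standardized to
#'   unit variance, entries bounded by sqrt(3)).
#' @return numeric S x S matrix.
#' @export
sample_random_component <- function(S, seed = 1L,
                                    distribution = c("gaussian", "uniform")) {
  stopifnot(S >= 1L)
  distribution <- match.arg(distribution)
  set.seed(seed)
  z <- switch(distribution,
    gaussian = matrix(rnorm(S * S), S, S),
    uniform  = matrix(runif(S * S, -sqrt(3), sqrt(3)), S, S))
  diag(z) <- 0
  z
}

#' Assemble the total interaction matrix
#'
#' Superposes the structural and the random components:
#' \eqn{A_{ij} = \mu_{ij} + \sigma z_{ij} / \sqrt S}. The \eqn{S^{-1/2}}
#' scaling keeps single random interactions small compared to the aggregate
#' effect of the whole community, so that sigma is the natural intensity of
#' disorder at the community level.
#'
#' @param structure a [community_structure()].
#' @param sigma randomness intensity, >= 0.
#' @param seed integer seed for the disorder draw.
#' @param distribution passed to [sample_random_component()].
#' @return an object of class `interaction_system` with fields `structure`,
#'   `sigma`, `seed`, `distribution`, `z`, `mu` and the total matrix `A`.
#' @export
interaction_system <- function(structure, sigma, seed = 1L,
                               distribution = c("gaussian", "uniform")) {
  stopifnot(inherits(structure, "community_structure"))
  if (sigma < 0) stop("sigma must be non-negative")
  distribution <- match.arg(distribution)
  S <- structure$n_species
  z <- sample_random_component(S, seed = seed, distribution = distribution)
  mu <- structural_matrix(structure)
  structure(
    list(structure = structure, sigma = sigma, seed = as.integer(seed),
         distribution = distribution, z = z, mu = mu,
         A = mu + sigma * z / sqrt(S)),
    class = "interaction_system")
}

#' @export
print.interaction_system <- function(x, ...) {
  cat("Interaction system: S =", x$structure$n_species,
      "| n_F =", x$structure$n_functions,
      "| sigma =", x$sigma,
      paste0("(", x$distribution, " disorder, seed ", x$seed, ")\n"))
  invisible(x)
}
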