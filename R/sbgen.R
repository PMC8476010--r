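# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Specification for a synthetic reaction-based model
#'
#' Describes the random-model family: network size, log-uniform sampling
#' ranges for initial concentrations (default `[1e-4, 1)`) and kinetic
#' constants (default `[1e-6, 10]`), and the stoichiometry constraints
#' (only zero-, first- and second-order reactions, i.e. reactant
#' multiplicities summing to at most 2, and at most two product
#' molecules). Concentrations and constants span several orders of
#' magnitude in real networks, which the log-uniform (uniform in log
#' space) sampling reflects.
#'
#' @param n_species number of species `N` (>= 1).
#' @param n_reactions number of reactions `M` (>= 1).
#' @param x0_range length-2 positive bounds for initial concentrations.
#' @param k_range length-2 positive bounds for kinetic constants.
#' @param max_reactant_order maximum total reactant multiplicity (2).
#' @param max_products maximum total product multiplicity (2).
#' @param zero_order allow reactions with an empty reactant side
#'   (constant sources); when `FALSE`, orders are drawn from `{1, 2}`.
#' @param seed integer seed making generation deterministic.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species, n_reactions,
                           x0_range = c(1e-4, 1),
                           k_range = c(1e-6, 10),
                           max_reactant_order = 2,
                           max_products = 2,
                           zero_order = TRUE,
                           seed = 1L) {
  if (!is.finite(n_species) || n_species < 1)
    stop("n_species must be >= 1", call. = FALSE)
  if (!is.finite(n_reactions) || n_reactions < 1)
    stop("n_reactions must be >= 1", call. = FALSE)
  for (r in list(x0_range, k_range)) {
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
      stop("ranges must be positive with low < high", call. = FALSE)
  }
  structure(
    list(n_species = as.integer(n_species),
         n_reactions = as.integer(n_reactions),
         x0_range = x0_range, k_range = k_range,
         max_reactant_order = as.integer(max_reactant_order),
         max_products = as.integer(max_products),
         zero_order = isTRUE(zero_order),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a random mass-action reaction network
#'
#' Draws, for each reaction, a reactant order uniformly from
#' `{0, 1, ..., max_reactant_order}` (omitting 0 when `zero_order` is
#' off) and a product count from `{0, ..., max_products}`, then picks the
#' participating species uniformly with replacement (so `2A` and `A + B`
#' are both possible). Reactions that would be empty on both sides are
#' redrawn. Initial concentrations and kinetic constants are sampled
#' i.i.d. log-uniformly from the spec's ranges. Generation is a pure
#' function of the spec (including its seed); the seed is recorded in the
#' returned model's metadata. Duplicate reactions may occur; under mass
#' action they are benign (fluxes add).
#'
#' @param spec a [synthetic_spec()].
#' @return an [rbm()] with attribute-level metadata field `meta` holding
#'   the generating seed.
#' @examples
#' m <- generate_rbm(synthetic_spec(8, 8, seed = 42))
#' validate_rbm(m)
#' @export
generate_rbm <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_species; M <- spec$n_reactions
  with_local_seed(spec$seed, {
    A <- matrix(0L, M, N)
    B <- matrix(0L, M, N)
    orders <- if (spec$zero_order) 0:spec$max_reactant_order
              else seq_len(spec$max_reactant_order)
    for (i in seq_len(M)) {
      repeat {
        ra <- rep(0L, N); rb <- rep(0L, N)
        no <- sample(orders, 1)
        if (no > 0) {
          for (j in sample.int(N, no, replace = TRUE)) ra[j] <- ra[j] + 1L
        }
        np <- sample(0:spec$max_products, 1)
        if (np > 0) {
          for (j in sample.int(N, np, replace = TRUE)) rb[j] <- rb[j] + 1L
        }
        if (sum(ra) + sum(rb) > 0) break
      }
      A[i, ] <- ra; B[i, ] <- rb
    }
    K <- runif_log(M, spec$k_range[1], spec$k_range[2])
    X0 <- runif_log(N, spec$x0_range[1], spec$x0_range[2])
    m <- rbm(A, B, K, X0)
    m$meta <- list(seed = spec$seed, generator = "rbmsim-sbgen")
    m
  })
}

#' Perturb kinetic constants log-uniformly within +/- 25%
#'
#' Applies, component-wise,
#' \deqn{k' = \exp(\ln(k - 0.25k) + (\ln(k + 0.25k) - \ln(k - 0.25k))
#'   \cdot rnd)}
#' with `rnd` in `[0, 1)`, i.e. a log-uniform draw from `[0.75k, 1.25k)`.
#' This is the standard perturbation used to build batches of
#' parameterizations around a reference kinetic set.
#'
#' @param K positive numeric vector of kinetic constants.
#' @param rnd numeric vector of the same length with entries in `[0, 1)`.
#' @return perturbed constants, element-wise in `[0.75 K, 1.25 K)`.
#' @examples
#' perturb_kinetics(c(2, 2), c(0, 0.5))
#' @export
perturb_kinetics <- function(K, rnd) {
  K <- as.numeric(K); rnd <- as.numeric(rnd)
  if (length(K) != length(rnd))
    stop("K and rnd must have the same length", call. = FALSE)
  if (any(!is.finite(K)) || any(K <= 0))
    stop("kinetic constants must be positive", call. = FALSE)
  if (any(rnd < 0) || any(rnd >= 1))
    stop("rnd entries must lie in [0, 1)", call. = FALSE)
  lo <- log(K - 0.25 * K)
  hi <- log(K + 0.25 * K)
  exp(lo + (hi - lo) * rnd)
}

#' Build a batch of perturbed parameterizations
#'
#' Produces `R` rows, each obtained by applying [perturb_kinetics()] to
#' the model's kinetic constants with an independent seeded uniform
#' stream; the initial state is shared across rows.
#'
#' @param rbm an [rbm()] object.
#' @param R number of parameterizations (>= 1).
#' @param seed integer seed for the perturbation stream.
#' @return a [parameterization_set()] with an `R x M` `K_batch`.
#' @export
make_batch <- function(rbm, R, seed = 1L) {
  stopifnot(inherits(rbm, "rbm"))
  if (!is.finite(R) || R < 1) stop("R must be >= 1", call. = FALSE)
  R <- as.integer(R)
  M <- nrow(rbm$A)
  with_local_seed(seed, {
    rnd <- matrix(stats::runif(R * M), R, M)
    K_batch <- t(apply(rnd, 1, function(r) perturb_kinetics(rbm$K, r)))
    if (M == 1) K_batch <- matrix(K_batch, ncol = 1)
    X0_batch <- matrix(rbm$X0, R, length(rbm$X0), byrow = TRUE)
    parameterization_set(X0_batch, K_batch)
  })
}
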