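#' Construct a reaction-based model (RBM)
#'
#' An RBM describes a biochemical network as `M` reactions over `N` species.
#' Reaction `i` consumes `A[i, j]` molecules of species `j` and produces
#' `B[i, j]`, with mass-action rate constant `K[i]`. Under the law of
#' mass-action the network induces the ODE system
#' \deqn{dX/dt = (B - A)^T (K \circ X^A)}
#' where \eqn{(X^A)_i = \prod_j X_j^{A_{ij}}} and \eqn{\circ} is the
#' element-wise product. The model is unit-agnostic: `K` must be expressed
#' in units consistent with the reaction orders and the units of `X0`
#' (concentrations or molecule counts both work, but cannot be mixed).
#'
#' @param A `M x N` matrix of non-negative integer reactant stoichiometries.
#' @param B `M x N` matrix of non-negative integer product stoichiometries.
#' @param K length-`M` vector of positive kinetic constants.
#' @param X0 length-`N` vector of non-negative initial concentrations.
#' @param species optional character vector of `N` species names
#'   (defaults to `S1 ... SN`).
#'
#' @return An object of class `rbm`: a list with elements `species`, `A`,
#'   `B`, `K`, `X0` plus cached structures used by the ODE right-hand side.
#' @examples
#' # A -> B with k = 2
#' m <- rbm(A = matrix(c(1, 0), 1), B = matrix(c(0, 1), 1), K = 2, X0 = c(3, 5))
#' mass_action_rhs(m, c(3, 5))
#' @export
rbm <- function(A, B, K, X0, species = NULL) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  dimnames(A) <- dimnames(B) <- NULL
  K <- as.numeric(K)
  X0 <- as.numeric(X0)
  if (is.null(species)) species <- paste0("S", seq_len(ncol(A)))
  obj <- structure(
    list(species = as.character(species), A = A, B = B, K = K, X0 = X0),
    class = "rbm"
  )
  bad <- validate_rbm(obj)
  if (length(bad) > 0) {
    stop("invalid RBM:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  }
  obj$ode <- compile_mass_action(A, B)
  obj
}

#' Validate an RBM, reporting every broken invariant
#'
#' Checks the structural invariants a simulable model must satisfy:
#' matching `M x N` shapes for `A` and `B`, non-negative integer
#' stoichiometries, strictly positive kinetic constants, non-negative
#' finite initial state, and no empty reaction (a row of zeros in both
#' `A` and `B`). Validation never raises; it returns a character vector
#' of human-readable violations, empty when the model is valid.
#'
#' @param x an `rbm` object or a bare list with fields `A`, `B`, `K`, `X0`
#'   (and optionally `species`).
#' @return character vector of violations; `character(0)` iff valid.
#' @export
validate_rbm <- function(x) {
  v <- character(0)
  A <- x$A; B <- x$B; K <- x$K; X0 <- x$X0
  if (!is.matrix(A) || !is.matrix(B)) {
    return("A and B must be matrices")
  }
  if (!all(dim(A) == dim(B))) {
    return(sprintf("shape mismatch: A is %dx%d but B is %dx%d",
                   nrow(A), ncol(A), nrow(B), ncol(B)))
  }
  M <- nrow(A); N <- ncol(A)
  if (M < 1 || N < 1) v <- c(v, "model must have at least one reaction and one species")
  if (!all(is.finite(A)) || any(A < 0) || any(A != round(A)))
    v <- c(v, "A must contain non-negative integers")
  if (!all(is.finite(B)) || any(B < 0) || any(B != round(B)))
    v <- c(v, "B must contain non-negative integers")
  if (length(K) != M) {
    v <- c(v, sprintf("K has length %d, expected M = %d", length(K), M))
  } else {
    bad_k <- which(!is.finite(K) | K <= 0)
    if (length(bad_k) > 0)
      v <- c(v, sprintf("kinetic constant must be positive and finite: reaction %s",
                        paste(bad_k, collapse = ", ")))
  }
  if (length(X0) != N) {
    v <- c(v, sprintf("X0 has length %d, expected N = %d", length(X0), N))
  } else {
    bad_x <- which(!is.finite(X0) | X0 < 0)
    if (length(bad_x) > 0)
      v <- c(v, sprintf("initial concentration must be non-negative and finite: species %s",
                        paste(bad_x, collapse = ", ")))
  }
  if (all(is.finite(A)) && all(is.finite(B))) {
    empty <- which(rowSums(A) + rowSums(B) == 0)
    if (length(empty) > 0)
      v <- c(v, sprintf("empty reaction (no reactants and no products): reaction %s",
                        paste(empty, collapse = ", ")))
  }
  if (!is.null(x$species) && length(x$species) != N)
    v <- c(v, sprintf("species has length %d, expected N = %d", length(x$species), N))
  v
}

# Cache a padded sparse view of A used to evaluate X^A without per-reaction
# loops: jmat[i, l] indexes into c(x, 1) and emat[i, l] is the exponent
# (0 on padding slots, so padded factors are 1 by the 0^0 = 1 convention,
# which R's `^` already follows).
compile_mass_action <- function(A, B) {
  M <- nrow(A); N <- ncol(A)
  nz <- lapply(seq_len(M), function(i) which(A[i, ] > 0))
  L <- max(1L, max(lengths(nz)))
  jmat <- matrix(N + 1L, M, L)
  emat <- matrix(0L, M, L)
  for (i in seq_len(M)) {
    js <- nz[[i]]
    if (length(js) > 0) {
      jmat[i, seq_along(js)] <- js
      emat[i, seq_along(js)] <- as.integer(A[i, js])
    }
  }
  list(BmAt = t(B - A), jmat = jmat, emat = emat, M = M, N = N, L = L)
}

# Internal fast path shared by the integrators: rhs of dX/dt at state x for
# kinetic constants k, given the cached representation.
mass_action_rhs_ <- function(ode, k, x) {
  xx <- c(x, 1)
  flux <- k
  for (l in seq_len(ode$L)) {
    flux <- flux * xx[ode$jmat[, l]]^ode$emat[, l]
  }
  drop(ode$BmAt %*% flux)
}

mass_action_jac_ <- function(ode, k, x) {
  xx <- c(x, 1)
  L <- ode$L; M <- ode$M; N <- ode$N
  # per-slot factors x_j^{a_ij}
  P <- matrix(1, M, L)
  for (l in seq_len(L)) P[, l] <- xx[ode$jmat[, l]]^ode$emat[, l]
  W <- matrix(0, M, N)
  for (l in seq_len(L)) {
    e <- ode$emat[, l]
    idx <- which(e > 0)
    if (length(idx) == 0) next
    other <- rep(1, length(idx))
    for (l2 in seq_len(L)) {
      if (l2 != l) other <- other * P[idx, l2]
    }
    j <- ode$jmat[idx, l]
    dP <- e[idx] * xx[j]^(e[idx] - 1L)
    cells <- cbind(idx, j)
    W[cells] <- W[cells] + k[idx] * dP * other
  }
  ode$BmAt %*% W
}

#' Mass-action ODE right-hand side
#'
#' Evaluates \eqn{dX/dt = (B - A)^T (K \circ X^A)} at state `x`. The
#' convention \eqn{0^0 = 1} applies, so species absent from a reaction never
#' affect its flux. Negative entries in `x` (which an adaptive solver may
#' produce transiently) are accepted unmodified: clamping would destroy the
#' smoothness the integrators rely on.
#'
#' @param rbm an [rbm()] object.
#' @param x numeric state vector of length `N`.
#' @param k optional replacement vector of kinetic constants (length `M`);
#'   defaults to `rbm$K`. Used by the batch engine for per-row kinetics.
#' @return numeric length-`N` vector of time derivatives.
#' @export
mass_action_rhs <- function(rbm, x, k = rbm$K) {
  stopifnot(inherits(rbm, "rbm"))
  x <- as.numeric(x)
  if (length(x) != ncol(rbm$A))
    stop(sprintf("state has length %d, model has N = %d species",
                 length(x), ncol(rbm$A)), call. = FALSE)
  if (length(k) != nrow(rbm$A))
    stop(sprintf("k has length %d, model has M = %d reactions",
                 length(k), nrow(rbm$A)), call. = FALSE)
  if (!all(is.finite(x))) stop("state vector must be finite", call. = FALSE)
  mass_action_rhs_(rbm$ode, k, x)
}

#' Analytic Jacobian of the mass-action right-hand side
#'
#' Returns the `N x N` matrix `J` with
#' \deqn{J_{pq} = \sum_i (b_{ip} - a_{ip}) k_i a_{iq} x_q^{a_{iq}-1}
#'   \prod_{j \ne q} x_j^{a_{ij}},}
#' i.e. the exact partial derivatives of [mass_action_rhs()]. Terms with
#' \eqn{a_{iq} = 0} vanish.
#'
#' @inheritParams mass_action_rhs
#' @return numeric `N x N` Jacobian matrix.
#' @export
mass_action_jacobian <- function(rbm, x, k = rbm$K) {
  stopifnot(inherits(rbm, "rbm"))
  x <- as.numeric(x)
  if (length(x) != ncol(rbm$A))
    stop(sprintf("state has length %d, model has N = %d species",
                 length(x), ncol(rbm$A)), call. = FALSE)
  if (length(k) != nrow(rbm$A))
    stop(sprintf("k has length %d, model has M = %d reactions",
                 length(k), nrow(rbm$A)), call. = FALSE)
  mass_action_jac_(rbm$ode, k, x)
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("<rbm> %d species, %d reactions\n", ncol(x$A), nrow(x$A)))
  ord <- rowSums(x$A)
  cat(sprintf("  reaction orders: %s\n",
              paste(sprintf("%d x order-%d", tabulate(ord + 1L, 5L),
                            0:4)[tabulate(ord + 1L, 5L) > 0], collapse = ", ")))
  cat(sprintf("  K in [%.3g, %.3g], X0 in [%.3g, %.3g]\n",
              min(x$K), max(x$K), min(x$X0), max(x$X0)))
  invisible(x)
}

#' Tidy an RBM into a per-reaction tibble
#'
#' One row per reaction with a human-readable equation string, the reactant
#' and product orders, and the kinetic constant.
#'
#' @param x an [rbm()] object.
#' @param ... unused.
#' @return a tibble with columns `reaction`, `equation`, `order`,
#'   `n_products`, `k`.
#' @exportS3Method generics::tidy
tidy.rbm <- function(x, ...) {
  side <- function(S, i) {
    j <- which(S[i, ] > 0)
    if (length(j) == 0) return("0")
    paste(ifelse(S[i, j] > 1, paste0(S[i, j], " "), ""), x$species[j],
          sep = "", collapse = " + ")
  }
  M <- nrow(x$A)
  tibble::tibble(
    reaction = seq_len(M),
    equation = vapply(seq_len(M), function(i)
      paste(side(x$A, i), "->", side(x$B, i)), character(1)),
    order = rowSums(x$A),
    n_products = rowSums(x$B),
    k = x$K
  )
}
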