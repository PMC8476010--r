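# Radical-inverse Halton sequence: deterministic low-discrepancy points in
# the unit hypercube, one prime base per dimension. Small by design; used
# only to build the base/resample matrices of the Saltelli scheme.
halton_sequence <- function(n, d, skip = 20L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53,
              59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113,
              127, 131, 137, 139, 149, 151, 157, 163, 167, 173, 179, 181,
              191, 193, 197, 199, 211, 223, 227, 229)
  if (d > length(primes))
    stop(sprintf("Halton sequence limited to %d dimensions", length(primes)),
         call. = FALSE)
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  idx <- skip + seq_len(n)
  vapply(seq_len(d),
         function(j) vapply(idx, radical_inverse, numeric(1),
                            base = primes[j]),
         numeric(n))
}

#' Saltelli sampling design for Sobol sensitivity analysis
#'
#' Builds the cross-sampled design that the Sobol index estimators
#' consume: two low-discrepancy base matrices `A` and `B` of `n_base`
#' points each, plus the hybrid matrices `AB_j` (column `j` of `A`
#' replaced from `B`) and, with `second_order`, the mirrored `BA_j`.
#' Rows are interleaved per base point in the order
#' `A, AB_1 ... AB_D, (BA_1 ... BA_D,) B`, giving `n_base * (2D + 2)` rows
#' with second order and `n_base * (D + 2)` without. Each column is scaled
#' into its factor's bounds.
#'
#' @param bounds `D x 2` matrix (or list of length-2 vectors) of factor
#'   bounds.
#' @param n_base base sample count; a power of two is recommended.
#' @param second_order include the `BA_j` blocks needed for second-order
#'   indices (default `TRUE`).
#' @return numeric design matrix with `D` columns and an attribute
#'   `"saltelli"` recording `n_base`, `D` and `second_order`.
#' @examples
#' dim(saltelli_sample(matrix(rep(c(0, 1), 11), ncol = 2, byrow = TRUE), 512))
#' @export
saltelli_sample <- function(bounds, n_base, second_order = TRUE) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || any(!is.finite(bounds)) ||
      any(bounds[, 1] >= bounds[, 2]))
    stop("bounds must be a D x 2 matrix with lo < hi", call. = FALSE)
  if (!is.finite(n_base) || n_base < 1)
    stop("n_base must be a positive integer", call. = FALSE)
  n_base <- as.integer(n_base)
  D <- nrow(bounds)
  U <- halton_sequence(n_base, 2L * D)
  A <- U[, seq_len(D), drop = FALSE]
  B <- U[, D + seq_len(D), drop = FALSE]
  blocks_per_point <- if (second_order) 2L * D + 2L else D + 2L
  X <- matrix(0, n_base * blocks_per_point, D)
  row <- 0L
  for (i in seq_len(n_base)) {
    X[row + 1L, ] <- A[i, ]
    for (j in seq_len(D)) {
      ab <- A[i, ]; ab[j] <- B[i, j]
      X[row + 1L + j, ] <- ab
    }
    off <- D + 1L
    if (second_order) {
      for (j in seq_len(D)) {
        ba <- B[i, ]; ba[j] <- A[i, j]
        X[row + off + j, ] <- ba
      }
      off <- off + D
    }
    X[row + off + 1L, ] <- B[i, ]
    row <- row + blocks_per_point
  }
  for (j in seq_len(D)) {
    X[, j] <- bounds[j, 1] + X[, j] * (bounds[j, 2] - bounds[j, 1])
  }
  attr(X, "saltelli") <- list(n_base = n_base, D = D,
                              second_order = isTRUE(second_order))
  X
}

#' Sobol sensitivity indices from a Saltelli design
#'
#' Variance-based global sensitivity analysis: decomposes the variance of
#' the model output over the factor space into first-order fractions
#' `S1_j` (the main effect of factor `j`) and total-order fractions
#' `ST_j` (main effect plus all interactions involving `j`). Estimators:
#' the Saltelli-2010 form for `S1` and the Jansen form for `ST`;
#' second-order indices `S2` use the mirrored blocks when present.
#' Confidence half-widths come from percentile bootstrap over the base
#' sample.
#'
#' @param Y numeric vector of model outputs ordered exactly as the rows of
#'   [saltelli_sample()].
#' @param D number of factors.
#' @param n_base base sample count of the design.
#' @param second_order whether the design included the `BA_j` blocks.
#' @param n_boot bootstrap resamples for the confidence intervals
#'   (default 1000).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `sobol_result`: list with `S1`, `S1_conf`,
#'   `ST`, `ST_conf`, optional `S2`, `n_base`, `n_boot`, `degenerate`
#'   (TRUE when the output variance is zero; all indices are then 0).
#' @export
sobol_indices <- function(Y, D, n_base, second_order = TRUE,
                          n_boot = 1000L, conf_level = 0.95) {
  blocks <- if (second_order) 2L * D + 2L else D + 2L
  if (length(Y) != n_base * blocks)
    stop(sprintf("Y has length %d, design expects %d rows",
                 length(Y), n_base * blocks), call. = FALSE)
  if (any(!is.finite(Y))) stop("Y must be finite", call. = FALSE)
  Ym <- matrix(Y, nrow = blocks)  # one column per base point
  yA <- Ym[1L, ]
  yAB <- Ym[1L + seq_len(D), , drop = FALSE]
  yBA <- if (second_order) Ym[1L + D + seq_len(D), , drop = FALSE] else NULL
  yB <- Ym[blocks, ]

  estimate <- function(idx) {
    a <- yA[idx]; b <- yB[idx]
    ab <- yAB[, idx, drop = FALSE]
    V <- stats::var(c(a, b))
    if (!is.finite(V) || V <= 0) {
      return(list(S1 = rep(0, D), ST = rep(0, D), V = 0))
    }
    S1 <- vapply(seq_len(D),
                 function(j) mean(b * (ab[j, ] - a)) / V, numeric(1))
    ST <- vapply(seq_len(D),
                 function(j) 0.5 * mean((a - ab[j, ])^2) / V, numeric(1))
    list(S1 = S1, ST = ST, V = V)
  }

  full <- estimate(seq_len(n_base))
  degenerate <- full$V <= 0
  S1_conf <- ST_conf <- rep(0, D)
  if (!degenerate && n_boot > 0) {
    bs_S1 <- matrix(0, n_boot, D)
    bs_ST <- matrix(0, n_boot, D)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_base, n_base, replace = TRUE)
      est <- estimate(idx)
      bs_S1[b, ] <- est$S1
      bs_ST[b, ] <- est$ST
    }
    half <- function(m, point) {
      lo <- (1 - conf_level) / 2
      vapply(seq_len(D), function(j) {
        q <- stats::quantile(m[, j], c(lo, 1 - lo), names = FALSE)
        (q[2] - q[1]) / 2
      }, numeric(1))
    }
    S1_conf <- half(bs_S1, full$S1)
    ST_conf <- half(bs_ST, full$ST)
  }
  S2 <- NULL
  if (second_order && !degenerate) {
    S2 <- matrix(NA_real_, D, D)
    V <- full$V
    for (j in seq_len(D - 1)) {
      for (l in (j + 1):D) {
        Vjl <- mean(yBA[j, ] * yAB[l, ] - yA * yB) / V
        S2[j, l] <- Vjl - full$S1[j] - full$S1[l]
      }
    }
  }
  structure(
    list(S1 = full$S1, S1_conf = S1_conf, ST = full$ST, ST_conf = ST_conf,
         S2 = S2, n_base = as.integer(n_base), n_boot = as.integer(n_boot),
         conf_level = conf_level, degenerate = degenerate),
    class = "sobol_result"
  )
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("<sobol_result> %d factors, n_base = %d%s\n",
              length(x$S1), x$n_base,
              if (x$degenerate) " (degenerate: zero output variance)" else ""))
  print(tidy.sobol_result(x), n = length(x$S1))
  invisible(x)
}

#' Tidy Sobol indices into a per-factor tibble
#'
#' Mirrors the usual sensitivity-analysis table layout: one row per
#' factor with first- and total-order indices and their confidence
#' half-widths.
#'
#' @param x a `sobol_result` from [sobol_indices()].
#' @param ... unused.
#' @return tibble with columns `factor`, `S1`, `S1_conf`, `ST`,
#'   `ST_conf`.
#' @exportS3Method generics::tidy
tidy.sobol_result <- function(x, ...) {
  tibble::tibble(factor = seq_along(x$S1), S1 = x$S1, S1_conf = x$S1_conf,
                 ST = x$ST, ST_conf = x$ST_conf)
}

#' One-row summary of a Sobol analysis
#'
#' @inheritParams tidy.sobol_result
#' @return one-row tibble with the design size and degeneracy flag.
#' @exportS3Method generics::glance
glance.sobol_result <- function(x, ...) {
  tibble::tibble(n_factors = length(x$S1), n_base = x$n_base,
                 n_boot = x$n_boot, conf_level = x$conf_level,
                 sum_S1 = sum(x$S1), degenerate = x$degenerate)
}

#' Plot Sobol indices
#'
#' @param object a `sobol_result`.
#' @param ... unused.
#' @return a ggplot dot-and-errorbar chart of `S1` and `ST` per factor.
#' @exportS3Method ggplot2::autoplot
autoplot.sobol_result <- function(object, ...) {
  d <- tidy.sobol_result(object) |>
    tidyr::pivot_longer(c("S1", "ST"), names_to = "order",
                        values_to = "index") |>
    dplyr::mutate(conf = ifelse(.data$order == "S1", object$S1_conf[.data$factor],
                                object$ST_conf[.data$factor]))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$factor), .data$index,
                                  colour = .data$order)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$index - .data$conf,
                                          ymax = .data$index + .data$conf),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "factor", y = "Sobol index", colour = NULL)
}
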