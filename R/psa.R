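#' Define a sweep axis for a bi-dimensional parameter sweep
#'
#' An axis varies either the initial concentration of one species or a set
#' of kinetic constants selected by a mask (every masked constant is *set*
#' to the axis value, mirroring sweeps of a shared macroscopic parameter
#' that determines many microscopic constants at once).
#'
#' @param what `"x0"` (initial concentration) or `"k"` (kinetic
#'   constants).
#' @param index species index for `"x0"`; integer or logical mask over
#'   reactions for `"k"`.
#' @param lo,hi sweep bounds, `lo < hi`; `lo > 0` required on the log
#'   scale.
#' @param n number of grid points (>= 2).
#' @param scale `"linear"` or `"log"` spacing.
#' @return an object of class `sweep_axis` with the evaluated grid in
#'   `$points`.
#' @export
sweep_axis <- function(what = c("x0", "k"), index, lo, hi, n,
                       scale = c("linear", "log")) {
  what <- match.arg(what)
  scale <- match.arg(scale)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("sweep bounds must satisfy lo < hi", call. = FALSE)
  if (scale == "log" && lo <= 0)
    stop("log-scale sweep requires lo > 0", call. = FALSE)
  if (!is.finite(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  points <- if (scale == "linear") seq(lo, hi, length.out = n)
            else exp(seq(log(lo), log(hi), length.out = n))
  structure(list(what = what, index = index, lo = lo, hi = hi,
                 n = as.integer(n), scale = scale, points = points),
            class = "sweep_axis")
}

apply_axis <- function(axis, rbm, x0, k, value) {
  if (axis$what == "x0") {
    j <- axis$index
    if (length(j) != 1 || j < 1 || j > length(x0))
      stop("x0 sweep axis must target one existing species", call. = FALSE)
    x0[j] <- value
  } else {
    mask <- axis$index
    if (is.logical(mask)) mask <- which(mask)
    if (length(mask) == 0 || any(mask < 1 | mask > length(k)))
      stop("k sweep axis mask targets non-existing reactions", call. = FALSE)
    k[mask] <- value
  }
  list(x0 = x0, k = k)
}

#' Enumerate a bi-dimensional sweep campaign
#'
#' Builds the Cartesian grid of the two axes (rows = axis1, columns =
#' axis2) and the corresponding batch schedule without running anything.
#' [psa_2d()] executes this plan.
#'
#' @param axis1,axis2 [sweep_axis()] objects.
#' @param batch_size parameterizations per batch (default 512, the batch
#'   size that saturates wide parallel hardware; on a sequential backend
#'   it only affects scheduling granularity).
#' @return list with `grid` (tibble of `i`, `j`, `value1`, `value2`),
#'   `n_parameterizations` and `n_batches`.
#' @export
psa_plan <- function(axis1, axis2, batch_size = 512L) {
  stopifnot(inherits(axis1, "sweep_axis"), inherits(axis2, "sweep_axis"))
  grid <- tidyr::expand_grid(i = seq_len(axis1$n), j = seq_len(axis2$n)) |>
    dplyr::mutate(value1 = axis1$points[.data$i],
                  value2 = axis2$points[.data$j])
  list(grid = grid,
       n_parameterizations = nrow(grid),
       n_batches = as.integer(ceiling(nrow(grid) / batch_size)),
       batch_size = as.integer(batch_size))
}

#' Bi-dimensional parameter sweep analysis (PSA-2D)
#'
#' Runs the model over the Cartesian grid of two [sweep_axis()] targets,
#' dispatching the parameterizations through [run_batch()] in batches,
#' and summarizes each trajectory with `summary_fn` (e.g.
#' [oscillation_amplitude()]). Grid orientation: rows follow `axis1`,
#' columns follow `axis2`. Cells are mutually independent, so each grid
#' value equals the corresponding individually computed run.
#'
#' @param rbm an [rbm()] object.
#' @param axis1,axis2 [sweep_axis()] objects.
#' @param settings a [solver_settings()] object.
#' @param summary_fn function mapping a `trajectory` to one number.
#' @param batch_size parameterizations per dispatched batch.
#' @return object of class `psa2d_result`: list with the `n1 x n2`
#'   `values` matrix, the axes, and the per-cell `status` matrix.
#' @export
psa_2d <- function(rbm, axis1, axis2, settings, summary_fn,
                   batch_size = 512L) {
  stopifnot(inherits(rbm, "rbm"), inherits(settings, "solver_settings"),
            is.function(summary_fn))
  plan <- psa_plan(axis1, axis2, batch_size)
  grid <- plan$grid
  n_cells <- nrow(grid)
  N <- length(rbm$X0); M <- length(rbm$K)
  X0_batch <- matrix(0, n_cells, N)
  K_batch <- matrix(0, n_cells, M)
  for (r in seq_len(n_cells)) {
    p1 <- apply_axis(axis1, rbm, rbm$X0, rbm$K, grid$value1[r])
    p2 <- apply_axis(axis2, rbm, p1$x0, p1$k, grid$value2[r])
    X0_batch[r, ] <- p2$x0
    K_batch[r, ] <- p2$k
  }
  values <- numeric(n_cells)
  statuses <- character(n_cells)
  for (start in seq(1, n_cells, by = plan$batch_size)) {
    idx <- start:min(start + plan$batch_size - 1L, n_cells)
    br <- run_batch(rbm, parameterization_set(X0_batch[idx, , drop = FALSE],
                                              K_batch[idx, , drop = FALSE]),
                    settings)
    statuses[idx] <- br$status
    values[idx] <- vapply(br$trajectories, function(tr) {
      if (tr$status == "success") summary_fn(tr) else NA_real_
    }, numeric(1))
  }
  structure(
    list(values = matrix(values, axis1$n, axis2$n, byrow = TRUE),
         status = matrix(statuses, axis1$n, axis2$n, byrow = TRUE),
         axis1 = axis1, axis2 = axis2,
         n_parameterizations = plan$n_parameterizations,
         n_batches = plan$n_batches),
    class = "psa2d_result"
  )
}

#' Tidy a PSA-2D result
#'
#' @param x a `psa2d_result` from [psa_2d()].
#' @param ... unused.
#' @return tibble with columns `value1`, `value2`, `summary`, `status`.
#' @exportS3Method generics::tidy
tidy.psa2d_result <- function(x, ...) {
  tidyr::expand_grid(i = seq_len(x$axis1$n), j = seq_len(x$axis2$n)) |>
    dplyr::mutate(value1 = x$axis1$points[.data$i],
                  value2 = x$axis2$points[.data$j],
                  summary = x$values[cbind(.data$i, .data$j)],
                  status = x$status[cbind(.data$i, .data$j)]) |>
    dplyr::select(-"i", -"j")
}

#' Plot a PSA-2D summary surface
#'
#' @param object a `psa2d_result`.
#' @param ... unused.
#' @return a ggplot raster of the per-cell summary over the two swept
#'   parameters.
#' @exportS3Method ggplot2::autoplot
autoplot.psa2d_result <- function(object, ...) {
  d <- tidy.psa2d_result(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$value2, .data$value1,
                                       fill = .data$summary)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "axis 2", y = "axis 1", fill = "summary")
  if (object$axis1$scale == "log") p <- p + ggplot2::scale_y_log10()
  if (object$axis2$scale == "log") p <- p + ggplot2::scale_x_log10()
  p
}

#' Average oscillation amplitude of one species
#'
#' Discards the leading `transient_fraction` of the output grid, locates
#' strict local maxima and minima of the species series, and averages the
#' drops from each maximum to the following minimum. Returns 0 for
#' non-oscillating dynamics: fewer than two maxima, or a total range
#' below `1e-6 * max(1, global max)`.
#'
#' @param traj a successful `trajectory`.
#' @param species_index 1-based species column.
#' @param transient_fraction fraction of the grid to discard, in `[0, 1)`
#'   (default 0.5).
#' @return non-negative mean peak-to-trough amplitude.
#' @export
oscillation_amplitude <- function(traj, species_index,
                                  transient_fraction = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$status != "success")
    stop(sprintf("cannot summarize a failed trajectory (status: %s)",
                 traj$status), call. = FALSE)
  if (transient_fraction < 0 || transient_fraction >= 1)
    stop("transient_fraction must lie in [0, 1)", call. = FALSE)
  y <- traj$states[, species_index]
  n <- length(y)
  start <- min(n, floor(n * transient_fraction) + 1L)
  y <- y[start:n]
  if (length(y) < 3) return(0)
  if ((max(y) - min(y)) < 1e-6 * max(1, max(y))) return(0)
  dy <- diff(y)
  # strict local extrema of the sampled series
  is_max <- which(dy[-length(dy)] > 0 & dy[-1] < 0) + 1L
  is_min <- which(dy[-length(dy)] < 0 & dy[-1] > 0) + 1L
  if (length(is_max) < 2) return(0)
  drops <- vapply(is_max, function(im) {
    nxt <- is_min[is_min > im]
    if (length(nxt) == 0) NA_real_ else y[im] - y[nxt[1]]
  }, numeric(1))
  drops <- drops[!is.na(drops)]
  if (length(drops) == 0) return(0)
  mean(drops)
}
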