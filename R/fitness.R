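#' Sensitivity-analysis output statistic: deviation of the final state
#'
#' Returns the difference between the final simulated concentration of one
#' species and a reference value (typically the final concentration of an
#' unperturbed base run), the scalar model output fed to
#' [sobol_indices()].
#'
#' @param traj a successful `trajectory`.
#' @param species_index 1-based species column.
#' @param reference_value reference concentration.
#' @return `X[species](t_end) - reference_value`.
#' @export
sa_output_statistic <- function(traj, species_index, reference_value) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$status != "success")
    stop(sprintf("cannot summarize a failed trajectory (status: %s)",
                 traj$status), call. = FALSE)
  unname(traj$states[nrow(traj$states), species_index] - reference_value)
}

#' Relative distance between simulated and target dynamics
#'
#' The parameter-estimation objective: the mean, over every target point
#' (each selected species at each target time), of
#' `|sim - target| / max(|target|, 1e-12)`. The guard keeps the distance
#' finite where the target is 0. The fitness is non-negative, zero iff
#' the simulation matches the target exactly on the grid, and invariant
#' to the ordering of species. A failed trajectory returns `Inf` so that
#' optimizers penalize the parameterization.
#'
#' @param sim a `trajectory`.
#' @param target a data frame (or tibble) with a `time` column plus one
#'   column per targeted species, named as in the model; every target
#'   time must occur in `sim$times`.
#' @return non-negative scalar (possibly `Inf`).
#' @export
fitness_relative_distance <- function(sim, target) {
  stopifnot(inherits(sim, "trajectory"))
  if (sim$status != "success") return(Inf)
  target <- as.data.frame(target)
  if (!"time" %in% names(target))
    stop("target must contain a 'time' column", call. = FALSE)
  sp <- setdiff(names(target), "time")
  if (length(sp) == 0) stop("target has no species columns", call. = FALSE)
  missing_sp <- setdiff(sp, colnames(sim$states))
  if (length(missing_sp) > 0)
    stop(sprintf("target species not in the simulation: %s",
                 paste(missing_sp, collapse = ", ")), call. = FALSE)
  ti <- vapply(target$time, function(tt) {
    i <- which(abs(sim$times - tt) <= 1e-9 * max(1, abs(tt)))
    if (length(i) == 0)
      stop(sprintf("target time %g is not on the simulation grid", tt),
           call. = FALSE)
    i[1]
  }, integer(1))
  simv <- as.numeric(sim$states[ti, sp, drop = FALSE])
  tarv <- as.numeric(as.matrix(target[, sp, drop = FALSE]))
  if (any(!is.finite(tarv))) stop("target values must be finite", call. = FALSE)
  mean(abs(simv - tarv) / pmax(abs(tarv), 1e-12))
}

#' Estimate free kinetic constants from target dynamics
#'
#' Minimal reference optimizer for parameter estimation: minimizes
#' [fitness_relative_distance()] over the selected kinetic constants,
#' searching in log10 space with Nelder-Mead ([stats::optim()]) from a
#' small deterministic grid of starting points (the supplied start
#' shifted by -1, 0, +1 decade per free constant, capped at 27
#' combinations) and keeping the best optimum. The multi-start guards
#' against the local minima that kinetic landscapes routinely have; a
#' proper global optimizer can replace this routine through the exposed
#' fitness.
#'
#' @param rbm an [rbm()] object; its `K` provides the fixed constants.
#' @param free integer indices of the constants to estimate.
#' @param target target dynamics (see [fitness_relative_distance()]).
#' @param settings a [solver_settings()] whose `t_out` covers the target
#'   times.
#' @param start optional starting values for the free constants (defaults
#'   to the model's current values).
#' @param solver `"auto"` dispatches per evaluation via stiffness
#'   classification; `"dopri5"`/`"radau5"` force a solver.
#' @param control passed to [stats::optim()].
#' @return list with `k_hat` (estimated constants), `fitness` (objective
#'   at the optimum), `convergence` (optim code) and `optim` (raw result).
#' @export
fit_kinetics <- function(rbm, free, target, settings, start = NULL,
                         solver = c("auto", "dopri5", "radau5"),
                         control = list(maxit = 500, reltol = 1e-10)) {
  stopifnot(inherits(rbm, "rbm"))
  solver <- match.arg(solver)
  free <- as.integer(free)
  if (any(free < 1 | free > length(rbm$K)))
    stop("free indices out of range", call. = FALSE)
  if (is.null(start)) start <- rbm$K[free]
  objective <- function(logk) {
    k <- rbm$K
    k[free] <- 10^logk
    tr <- switch(solver,
      auto = {
        cls <- classify_stiffness(rbm, rbm$X0, k,
                                  settings$stiffness_threshold)
        if (cls$label == "nonstiff") {
          tr0 <- dopri5_integrate(rbm, rbm$X0, settings, k = k)
          if (tr0$status != "success")
            tr0 <- radau5_integrate(rbm, rbm$X0, settings, k = k)
          tr0
        } else {
          radau5_integrate(rbm, rbm$X0, settings, k = k)
        }
      },
      dopri5 = dopri5_integrate(rbm, rbm$X0, settings, k = k),
      radau5 = radau5_integrate(rbm, rbm$X0, settings, k = k))
    fitness_relative_distance(tr, target)
  }
  p <- length(free)
  offsets <- if (p <= 3) {
    as.matrix(do.call(expand.grid, rep(list(c(0, -1, 1)), p)))
  } else {
    rbind(matrix(0, 1, p), 2 * halton_sequence(9, p) - 1)
  }
  best <- NULL
  for (i in seq_len(nrow(offsets))) {
    st <- log10(start) + offsets[i, ]
    if (!is.finite(objective(st))) next  # e.g. solver failure at this start
    res <- stats::optim(st, objective, method = "Nelder-Mead",
                        control = control)
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value <= 1e-8) break
  }
  if (is.null(best))
    stop("no starting point gave a finite fitness", call. = FALSE)
  list(k_hat = 10^best$par, fitness = best$value,
       convergence = best$convergence, optim = best)
}
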