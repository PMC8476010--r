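#' Solver settings
#'
#' Collects the error-control and output parameters shared by both
#' integrators. Defaults follow widely used deterministic-simulation
#' practice: absolute tolerance `1e-12`, relative tolerance `1e-6`, and at
#' most `1e4` steps per trajectory.
#'
#' @param t_out strictly increasing numeric vector of output times. A
#'   single value of 0 is allowed and returns the initial state.
#' @param eps_a absolute error tolerance (> 0).
#' @param eps_r relative error tolerance (> 0).
#' @param max_steps maximum number of attempted steps (>= 1).
#' @param h_init optional initial step size; selected automatically from
#'   the magnitude of the right-hand side when `NULL`.
#' @param h_fixed optional fixed step size. When set, the adaptive
#'   controller is disabled and every step uses exactly this size (used
#'   e.g. for convergence-order studies).
#' @param stiffness_threshold spectral-radius threshold separating
#'   non-stiff from stiff parameterizations in the batch engine
#'   (default 500).
#' @param t0 initial time (default 0); must satisfy `t0 <= min(t_out)`.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(t_out,
                            eps_a = 1e-12,
                            eps_r = 1e-6,
                            max_steps = 1e4,
                            h_init = NULL,
                            h_fixed = NULL,
                            stiffness_threshold = 500,
                            t0 = 0) {
  t_out <- as.numeric(t_out)
  if (length(t_out) < 1 || any(!is.finite(t_out)))
    stop("t_out must be a non-empty finite vector", call. = FALSE)
  if (any(diff(t_out) <= 0))
    stop("t_out must be strictly increasing", call. = FALSE)
  if (!is.finite(eps_a) || eps_a <= 0) stop("eps_a must be > 0", call. = FALSE)
  if (!is.finite(eps_r) || eps_r <= 0) stop("eps_r must be > 0", call. = FALSE)
  if (!is.finite(max_steps) || max_steps < 1)
    stop("max_steps must be >= 1", call. = FALSE)
  if (t0 > t_out[1]) stop("t0 must not exceed the first output time", call. = FALSE)
  if (!is.null(h_fixed) && (!is.finite(h_fixed) || h_fixed <= 0))
    stop("h_fixed must be > 0", call. = FALSE)
  if (!is.null(h_init) && (!is.finite(h_init) || h_init <= 0))
    stop("h_init must be > 0", call. = FALSE)
  structure(
    list(t_out = t_out, eps_a = eps_a, eps_r = eps_r,
         max_steps = as.integer(max_steps), h_init = h_init,
         h_fixed = h_fixed, stiffness_threshold = stiffness_threshold,
         t0 = t0),
    class = "solver_settings"
  )
}

#' Scaled RMS error norm
#'
#' The weighted root-mean-square norm both integrators use to accept or
#' reject a step:
#' \deqn{\sqrt{\frac1N \sum_i \left(\frac{err_i}
#'   {\epsilon_a + \epsilon_r \max(|x^{old}_i|, |x^{new}_i|)}\right)^2}.}
#' A step is accepted iff this norm is at most 1.
#'
#' @param x_old,x_new state before and after the step (length `N`).
#' @param err length-`N` local error estimate.
#' @param settings a [solver_settings()] object.
#' @return non-negative scalar.
#' @export
error_norm <- function(x_old, x_new, err, settings) {
  sc <- settings$eps_a + settings$eps_r * pmax(abs(x_old), abs(x_new))
  sqrt(mean((err / sc)^2))
}

#' Butcher tableau of a Runge-Kutta method
#'
#' Returns the coefficient table (stage abscissae `c`, stage matrix `a`,
#' solution weights `b`, error weights `e`, order) for one of the two
#' integrators. Coefficients are stored as exact rationals (or in terms of
#' `sqrt(6)`) evaluated in double precision. The row-sum consistency
#' condition `sum(a[i, ]) == c[i]` holds to 1e-12.
#'
#' @param method `"dopri5"` or `"radau5"`.
#' @return a list of class `butcher_tableau` with fields `c`, `a`, `b`,
#'   `e` (error-estimate weights; for Radau the embedded-estimate
#'   coefficients), `order`, `method`.
#' @export
butcher_tableau <- function(method = c("dopri5", "radau5")) {
  method <- match.arg(method)
  if (method == "dopri5") {
    a <- matrix(0, 7, 7)
    a[2, 1] <- 1 / 5
    a[3, 1:2] <- c(3 / 40, 9 / 40)
    a[4, 1:3] <- c(44 / 45, -56 / 15, 32 / 9)
    a[5, 1:4] <- c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729)
    a[6, 1:5] <- c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
                   -5103 / 18656)
    b <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
    a[7, ] <- b
    cc <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
    # b - bhat: weights of the embedded order-4 error estimate
    e <- c(71 / 57600, 0, -71 / 16695, 71 / 1920, -17253 / 339200,
           22 / 525, -1 / 40)
    tab <- list(c = cc, a = a, b = b, e = e, order = 5L, method = method)
  } else {
    s6 <- sqrt(6)
    a <- matrix(c(
      (88 - 7 * s6) / 360, (296 - 169 * s6) / 1800, (-2 + 3 * s6) / 225,
      (296 + 169 * s6) / 1800, (88 + 7 * s6) / 360, (-2 - 3 * s6) / 225,
      (16 - s6) / 36, (16 + s6) / 36, 1 / 9
    ), 3, 3, byrow = TRUE)
    cc <- c((4 - s6) / 10, (4 + s6) / 10, 1)
    b <- a[3, ]  # stiffly accurate: solution = last stage
    # embedded-estimate coefficients (applied to the stage increments z_i)
    e <- c(-(13 + 7 * s6) / 3, (-13 + 7 * s6) / 3, -1 / 3)
    tab <- list(c = cc, a = a, b = b, e = e, order = 5L, method = method)
  }
  class(tab) <- "butcher_tableau"
  tab
}

# trajectory status codes used throughout the package
TRAJ_STATUSES <- c("success", "stiffness_detected", "step_limit_exceeded",
                   "step_size_underflow", "invalid_parameters")

new_trajectory <- function(times, states, solver_used, status,
                           n_steps, n_accepted, n_rejected,
                           species = NULL, rho = NA_real_) {
  if (is.null(species)) species <- paste0("S", seq_len(ncol(states)))
  colnames(states) <- species
  structure(
    list(times = times, states = states, solver_used = solver_used,
         status = status, n_steps = n_steps, n_accepted = n_accepted,
         n_rejected = n_rejected, species = species, rho = rho),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s via %s: %d output times x %d species\n",
              x$status, x$solver_used, length(x$times), ncol(x$states)))
  cat(sprintf("  steps: %d (%d accepted, %d rejected)\n",
              x$n_steps, x$n_accepted, x$n_rejected))
  invisible(x)
}

#' Tidy a trajectory into a long tibble
#'
#' @param x a `trajectory` as returned by [dopri5_integrate()],
#'   [radau5_integrate()] or [run_batch()].
#' @param ... unused.
#' @return tibble with columns `time`, `species`, `concentration`.
#' @exportS3Method generics::tidy
tidy.trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$states)) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species",
                        values_to = "concentration")
}

#' One-row summary of a trajectory
#'
#' @inheritParams tidy.trajectory
#' @return one-row tibble with the solver used, termination status and
#'   step counters.
#' @exportS3Method generics::glance
glance.trajectory <- function(x, ...) {
  tibble::tibble(solver_used = x$solver_used, status = x$status,
                 n_steps = x$n_steps, n_accepted = x$n_accepted,
                 n_rejected = x$n_rejected, rho = x$rho)
}

#' Plot a trajectory
#'
#' @param object a `trajectory`.
#' @param species optional character vector restricting the plot.
#' @param ... unused.
#' @return a ggplot object (time on x, concentration on y, one colored
#'   line per species).
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory <- function(object, species = NULL, ...) {
  d <- tidy.trajectory(object)
  if (!is.null(species)) d <- dplyr::filter(d, .data$species %in% !!species)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$concentration,
                                  colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "concentration", colour = NULL)
}
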