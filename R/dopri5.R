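# Normalize the user-supplied system: either an rbm (analytic RHS/Jacobian,
# optionally with replacement kinetics) or a plain function(t, x).
as_system <- function(rhs, k = NULL, jac = NULL) {
  if (inherits(rhs, "rbm")) {
    kk <- if (is.null(k)) rhs$K else as.numeric(k)
    ode <- rhs$ode
    list(
      f = function(t, x) mass_action_rhs_(ode, kk, x),
      jac = function(t, x) mass_action_jac_(ode, kk, x),
      species = rhs$species
    )
  } else if (is.function(rhs)) {
    list(f = rhs, jac = jac, species = NULL)
  } else {
    stop("rhs must be an rbm or a function(t, x)", call. = FALSE)
  }
}

# Automatic initial step (standard magnitude heuristic): a step over which
# an explicit Euler increment stays around 1% of the solution scale.
h_initial <- function(f, t0, y0, f0, t_end, settings, order = 5) {
  sc <- settings$eps_a + settings$eps_r * abs(y0)
  d0 <- sqrt(mean((y0 / sc)^2))
  d1 <- sqrt(mean((f0 / sc)^2))
  h0 <- if (d0 < 1e-10 || d1 < 1e-10) 1e-6 else 0.01 * d0 / d1
  h0 <- min(h0, t_end - t0)
  y1 <- y0 + h0 * f0
  f1 <- f(t0 + h0, y1)
  d2 <- sqrt(mean(((f1 - f0) / sc)^2)) / h0
  h1 <- if (max(d1, d2) <= 1e-15) {
    max(1e-6, h0 * 1e-3)
  } else {
    (0.01 / max(d1, d2))^(1 / order)
  }
  min(100 * h0, h1, t_end - t0)
}

#' Integrate with the explicit Dormand-Prince 5(4) method
#'
#' Adaptive 7-stage explicit Runge-Kutta pair of order 5(4) with the
#' first-same-as-last property, quartic dense output for filling the output
#' grid, and stiffness detection. A step is accepted iff the embedded
#' [error_norm()] is at most 1; the next step is
#' `h * min(10, max(0.2, 0.9 * err^(-1/5)))`. Stiffness is monitored
#' through the scaled Lipschitz estimate `h * rho_tilde` formed from the
#' last two stages; when it exceeds 3.25 on 15 consecutive monitored steps
#' the integration stops with status `"stiffness_detected"` and partial
#' results, signalling the caller to fall back to the implicit solver.
#'
#' @param rhs an [rbm()] object (the mass-action system is derived
#'   automatically) or a function `f(t, x)` returning the derivative.
#' @param x0 initial state vector.
#' @param settings a [solver_settings()] object.
#' @param k optional kinetic-constant override when `rhs` is an `rbm`.
#' @return a `trajectory`; `states` rows not reached before an abnormal
#'   termination are `NA`.
#' @export
dopri5_integrate <- function(rhs, x0, settings, k = NULL) {
  stopifnot(inherits(settings, "solver_settings"))
  sys <- as_system(rhs, k)
  f <- sys$f
  x0 <- as.numeric(x0)
  tab <- butcher_tableau("dopri5")
  a <- tab$a; cc <- tab$c; bw <- tab$b; ew <- tab$e
  # dense-output quartic weights
  d1 <- -12715105075 / 11282082432
  d3 <- 87487479700 / 32700410799
  d4 <- -10690763975 / 1880347072
  d5 <- 701980252875 / 199316789632
  d6 <- -1453857185 / 822651844
  d7 <- 69997945 / 29380423

  t_out <- settings$t_out
  nt <- length(t_out)
  N <- length(x0)
  out <- matrix(NA_real_, nt, N)
  t <- settings$t0
  y <- x0
  iout <- 1L
  while (iout <= nt && t_out[iout] <= t) {
    out[iout, ] <- y
    iout <- iout + 1L
  }
  if (iout > nt) {
    return(new_trajectory(t_out, out, "DOPRI5", "success", 0L, 0L, 0L,
                          sys$species))
  }
  t_end <- t_out[nt]
  fixed <- !is.null(settings$h_fixed)
  k1 <- f(t, y)
  h <- if (fixed) settings$h_fixed else if (!is.null(settings$h_init)) {
    settings$h_init
  } else {
    h_initial(f, t, y, k1, t_end, settings)
  }
  nstep <- naccpt <- nrej <- 0L
  iasti <- 0L; nonsti <- 0L
  status <- "success"

  while (iout <= nt) {
    if (nstep >= settings$max_steps) { status <- "step_limit_exceeded"; break }
    if (!fixed) h <- min(h, t_end - t)
    if (h < .Machine$double.eps * 16 * max(1, abs(t))) {
      status <- "step_size_underflow"; break
    }
    k2 <- f(t + cc[2] * h, y + h * a[2, 1] * k1)
    k3 <- f(t + cc[3] * h, y + h * (a[3, 1] * k1 + a[3, 2] * k2))
    k4 <- f(t + cc[4] * h, y + h * (a[4, 1] * k1 + a[4, 2] * k2 + a[4, 3] * k3))
    k5 <- f(t + cc[5] * h, y + h * (a[5, 1] * k1 + a[5, 2] * k2 + a[5, 3] * k3 +
                                      a[5, 4] * k4))
    ysti <- y + h * (a[6, 1] * k1 + a[6, 2] * k2 + a[6, 3] * k3 +
                       a[6, 4] * k4 + a[6, 5] * k5)
    k6 <- f(t + h, ysti)
    y1 <- y + h * (bw[1] * k1 + bw[3] * k3 + bw[4] * k4 + bw[5] * k5 +
                     bw[6] * k6)
    nstep <- nstep + 1L
    if (!all(is.finite(y1)) || !all(is.finite(k6))) {
      nrej <- nrej + 1L
      h <- h / 2
      next
    }
    k7 <- f(t + h, y1)
    errv <- h * (ew[1] * k1 + ew[3] * k3 + ew[4] * k4 + ew[5] * k5 +
                   ew[6] * k6 + ew[7] * k7)
    err <- if (fixed) 0 else error_norm(y, y1, errv, settings)
    if (err <= 1) {
      naccpt <- naccpt + 1L
      # stiffness monitor: h times the local Lipschitz estimate from the
      # two trailing stages, against 3.25 on 15 consecutive flagged steps;
      # sampled every 1000th accepted step, then every step once flagged
      den <- sum((y1 - ysti)^2)
      if ((naccpt %% 1000L == 0L || iasti > 0L) && den > 0) {
        hlamb <- h * sqrt(sum((k7 - k6)^2) / den)
        if (hlamb > 3.25) {
          nonsti <- 0L
          iasti <- iasti + 1L
        } else if (iasti > 0L) {
          nonsti <- nonsti + 1L
          if (nonsti == 6L) iasti <- 0L
        }
      }
      # dense fill of output points inside (t, t+h]
      if (iout <= nt && t_out[iout] <= t + h + 1e-8 * h) {
        ydiff <- y1 - y
        bspl <- h * k1 - ydiff
        r1 <- y; r2 <- ydiff; r3 <- bspl
        r4 <- ydiff - h * k7 - bspl
        r5 <- h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6 + d7 * k7)
        while (iout <= nt && t_out[iout] <= t + h + 1e-8 * h) {
          th <- (t_out[iout] - t) / h
          if (th >= 1 - 1e-12) {
            out[iout, ] <- y1
          } else {
            th1 <- 1 - th
            out[iout, ] <- r1 + th * (r2 + th1 * (r3 + th * (r4 + th1 * r5)))
          }
          iout <- iout + 1L
        }
      }
      t <- t + h
      y <- y1
      k1 <- k7
      if (iasti == 15L) { status <- "stiffness_detected"; break }
      if (!fixed) h <- h * min(10, max(0.2, 0.9 * err^(-0.2)))
    } else {
      nrej <- nrej + 1L
      h <- h * min(1, max(0.2, 0.9 * err^(-0.2)))
    }
  }
  new_trajectory(t_out, out, "DOPRI5", status, nstep, naccpt, nrej,
                 sys$species)
}
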