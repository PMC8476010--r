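# Finite-difference Jacobian used when the caller supplies a bare rhs
# function without an analytic Jacobian.
fd_jacobian <- function(f, t, y) {
  f0 <- f(t, y)
  N <- length(y)
  J <- matrix(0, N, N)
  for (q in seq_len(N)) {
    hq <- 1e-8 * max(1, abs(y[q]))
    yp <- y; yp[q] <- yp[q] + hq
    J[, q] <- (f(t, yp) - f0) / hq
  }
  J
}

#' Integrate with the implicit 3-stage Radau IIA method of order 5
#'
#' Stiffly accurate collocation Runge-Kutta method: the last stage is the
#' step solution, so the method is strongly A-stable and well suited to
#' stiff mass-action systems. The nonlinear stage equations are solved by
#' simplified Newton iteration (Jacobian frozen at the step start, at most
#' 7 iterations); the `3N x 3N` Newton matrix `I - h (A `\eqn{\otimes}`{(x)}` J)` is
#' factorized once per step attempt and reused across iterations. The
#' local error is estimated through the embedded lower-order combination
#' of the stage increments, smoothed by one solve with the shifted matrix
#' `(gamma/h) I - J`, and controlled by [error_norm()]; the step scale
#' factor is `min(8, max(0.2, 0.9 * err^(-1/5)))`. Output points are
#' filled from the cubic collocation polynomial through the step ends and
#' the two interior abscissae.
#'
#' @param rhs an [rbm()] object or a function `f(t, x)`.
#' @param x0 initial state vector.
#' @param settings a [solver_settings()] object.
#' @param jac optional Jacobian function `jac(t, x)`; derived analytically
#'   when `rhs` is an `rbm`, otherwise approximated by forward differences
#'   if missing.
#' @param k optional kinetic-constant override when `rhs` is an `rbm`.
#' @return a `trajectory` with `solver_used = "RADAU5"`.
#' @export
radau5_integrate <- function(rhs, x0, settings, jac = NULL, k = NULL) {
  stopifnot(inherits(settings, "solver_settings"))
  sys <- as_system(rhs, k, jac)
  f <- sys$f
  jf <- sys$jac
  if (is.null(jf)) jf <- function(t, y) fd_jacobian(f, t, y)
  x0 <- as.numeric(x0)
  tab <- butcher_tableau("radau5")
  a <- tab$a; cc <- tab$c; ee <- tab$e
  # gamma: the real eigenvalue of solve(a); enters the error-estimate solve
  ev <- eigen(solve(a), only.values = TRUE)$values
  gamma <- Re(ev[which.min(abs(Im(ev)))])

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
    return(new_trajectory(t_out, out, "RADAU5", "success", 0L, 0L, 0L,
                          sys$species))
  }
  t_end <- t_out[nt]
  fixed <- !is.null(settings$h_fixed)
  f0 <- f(t, y)
  h <- if (fixed) settings$h_fixed else if (!is.null(settings$h_init)) {
    settings$h_init
  } else {
    min(h_initial(f, t, y, f0, t_end, settings), 1e-2 * (t_end - t))
  }
  fnewt <- max(10 * .Machine$double.eps / settings$eps_r,
               min(0.03, sqrt(settings$eps_r)))
  nstep <- naccpt <- nrej <- 0L
  status <- "success"
  first <- TRUE
  rejected <- FALSE
  I3N <- diag(3 * N)
  idx1 <- seq_len(N); idx2 <- N + idx1; idx3 <- 2L * N + idx1

  while (iout <= nt) {
    if (nstep >= settings$max_steps) { status <- "step_limit_exceeded"; break }
    if (!fixed) h <- min(h, t_end - t)
    if (h < .Machine$double.eps * 16 * max(1, abs(t))) {
      status <- "step_size_underflow"; break
    }
    J <- jf(t, y)
    Mmat <- I3N - h * (a %x% J)
    qrM <- qr(Mmat)
    # simplified Newton on the stacked stage increments Z = (z1, z2, z3)
    Z <- numeric(3 * N)
    sc <- settings$eps_a + settings$eps_r * abs(y)
    sc3 <- rep(sc, 3)
    converged <- FALSE
    dyno_old <- NA_real_
    Fst <- matrix(0, N, 3)
    for (it in seq_len(7L)) {
      for (s in 1:3) {
        Fst[, s] <- f(t + cc[s] * h, y + Z[((s - 1L) * N + 1L):(s * N)])
      }
      if (!all(is.finite(Fst))) break
      G <- h * as.vector(Fst %*% t(a)) - Z
      dZ <- qr.coef(qrM, G)
      if (any(!is.finite(dZ))) break
      Z <- Z + dZ
      dyno <- sqrt(mean((dZ / sc3)^2))
      if (it > 1L) {
        theta <- dyno / dyno_old
        if (theta >= 0.99) break
        if (theta / (1 - theta) * dyno <= fnewt) { converged <- TRUE; break }
      } else if (dyno <= fnewt) {
        converged <- TRUE; break
      }
      dyno_old <- dyno
    }
    nstep <- nstep + 1L
    if (!converged) {
      nrej <- nrej + 1L
      rejected <- TRUE
      if (fixed) { status <- "step_size_underflow"; break }
      h <- h / 2
      next
    }
    z1 <- Z[idx1]; z2 <- Z[idx2]; z3 <- Z[idx3]
    y1 <- y + z3
    if (fixed) {
      err <- 0
    } else {
      emb <- f0 + (ee[1] * z1 + ee[2] * z2 + ee[3] * z3) / h
      E1 <- (gamma / h) * diag(N) - J
      errv <- tryCatch(solve(E1, emb), error = function(e) rep(Inf, N))
      err <- error_norm(y, y1, errv, settings)
      if (err >= 1 && (first || rejected) && all(is.finite(errv))) {
        # refined estimate: re-evaluate f at the perturbed state
        f1 <- f(t, y + errv)
        errv <- tryCatch(
          solve(E1, f1 + (ee[1] * z1 + ee[2] * z2 + ee[3] * z3) / h),
          error = function(e) rep(Inf, N))
        err <- error_norm(y, y1, errv, settings)
      }
    }
    if (err <= 1) {
      naccpt <- naccpt + 1L
      # collocation cubic through (0, y), (c1, y+z1), (c2, y+z2), (1, y+z3)
      if (iout <= nt && t_out[iout] <= t + h + 1e-8 * h) {
        v0 <- y; v1 <- y + z1; v2 <- y + z2; v3 <- y1
        dd1 <- (v1 - v0) / cc[1]
        dd2 <- (v2 - v1) / (cc[2] - cc[1])
        dd3 <- (v3 - v2) / (1 - cc[2])
        e1 <- (dd2 - dd1) / cc[2]
        e2 <- (dd3 - dd2) / (1 - cc[1])
        e3 <- e2 - e1
        while (iout <= nt && t_out[iout] <= t + h + 1e-8 * h) {
          th <- (t_out[iout] - t) / h
          if (th >= 1 - 1e-12) {
            out[iout, ] <- y1
          } else {
            out[iout, ] <- v0 + th * (dd1 + (th - cc[1]) *
                                        (e1 + (th - cc[2]) * e3))
          }
          iout <- iout + 1L
        }
      }
      t <- t + h
      y <- y1
      f0 <- f(t, y)
      first <- FALSE
      rejected <- FALSE
      if (!fixed) h <- h * min(8, max(0.2, 0.9 * err^(-0.2)))
    } else {
      nrej <- nrej + 1L
      rejected <- TRUE
      h <- h * min(1, max(0.2, 0.9 * err^(-0.2)))
    }
  }
  new_trajectory(t_out, out, "RADAU5", status, nstep, naccpt, nrej,
                 sys$species)
}
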