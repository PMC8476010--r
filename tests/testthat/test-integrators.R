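test_that("error norm follows the scaled RMS formula", {
  s <- solver_settings(t_out = 1, eps_a = 1e-12, eps_r = 1e-6)
  expect_equal(error_norm(c(1, 2), c(1, 2), c(0, 0), s), 0)
  # N = 1, x = 0: the scale collapses to eps_a
  expect_equal(error_norm(0, 0, s$eps_a, s), 1)
  set.seed(4)
  xo <- rnorm(5); xn <- rnorm(5); e <- rnorm(5) * 1e-7
  direct <- sqrt(mean((e / (s$eps_a + s$eps_r * pmax(abs(xo), abs(xn))))^2))
  expect_equal(error_norm(xo, xn, e, s), direct)
})

test_that("Butcher tableaus satisfy row-sum consistency and order 5", {
  for (method in c("dopri5", "radau5")) {
    tab <- butcher_tableau(method)
    expect_equal(rowSums(tab$a), tab$c, tolerance = 1e-12)
    expect_identical(tab$order, 5L)
    expect_equal(sum(tab$b), 1, tolerance = 1e-12)
  }
  # stiffly accurate: Radau solution weights are the last stage row
  rad <- butcher_tableau("radau5")
  expect_identical(rad$b, rad$a[3, ])
})

test_that("both solvers reproduce closed-form linear decay", {
  s <- solver_settings(t_out = 1)
  tr <- dopri5_integrate(decay_rbm(k = 1), 1, s)
  expect_equal(tr$status, "success")
  expect_lt(abs(tr$states[1, 1] - exp(-1)), 10 * s$eps_r)
  # stiff decay lambda = 1000 over t = 0.01: e^-10
  s2 <- solver_settings(t_out = 0.01)
  tr2 <- radau5_integrate(decay_rbm(k = 1000), 1, s2)
  expect_equal(tr2$status, "success")
  expect_lt(abs(tr2$states[1, 1] - exp(-10)) / exp(-10), 1e-4)
})

test_that("both solvers reach the symmetric equilibrium of A <-> B", {
  s <- solver_settings(t_out = 20)
  for (f in list(dopri5_integrate, radau5_integrate)) {
    tr <- f(reversible_rbm(), c(1, 0), s)
    expect_equal(tr$status, "success")
    expect_equal(unname(tr$states[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  }
})

test_that("dense output matches the exact solution between steps", {
  s <- solver_settings(t_out = seq(0.1, 2, by = 0.1))
  for (f in list(dopri5_integrate, radau5_integrate)) {
    tr <- f(decay_rbm(), 1, s)
    expect_equal(tr$status, "success")
    expect_lt(max(abs(tr$states[, 1] - exp(-s$t_out))), 1e-5)
  }
})

test_that("global error scales as h^5 with the controller disabled", {
  hs <- c(0.1, 0.05, 0.025, 0.0125)
  for (f in list(dopri5_integrate, radau5_integrate)) {
    errs <- vapply(hs, function(h) {
      s <- solver_settings(t_out = 1, h_fixed = h)
      abs(f(decay_rbm(), 1, s)$states[1, 1] - exp(-1))
    }, numeric(1))
    slope <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
    expect_gt(slope, 4.7)
    expect_lt(slope, 5.3)
  }
})

test_that("tightening the relative tolerance never increases the error", {
  for (f in list(dopri5_integrate, radau5_integrate)) {
    e_loose <- abs(f(decay_rbm(), 1,
                     solver_settings(t_out = 1, eps_r = 1e-4))$states[1, 1] -
                     exp(-1))
    e_tight <- abs(f(decay_rbm(), 1,
                     solver_settings(t_out = 1, eps_r = 1e-8))$states[1, 1] -
                     exp(-1))
    expect_lte(e_tight, e_loose)
  }
})

test_that("linear invariants of a closed model drift below 1e-8 relative", {
  m <- closed_rbm()
  s <- solver_settings(t_out = seq(0.5, 50, by = 0.5))
  tot0 <- sum(m$X0 * c(1, 1, 2))  # (A+C) + (B+C)
  for (f in list(dopri5_integrate, radau5_integrate)) {
    tr <- f(m, m$X0, s)
    expect_equal(tr$status, "success")
    tot <- tr$states %*% c(1, 1, 2)
    expect_lt(max(abs(tot - tot0)) / tot0, 1e-8)
  }
})

test_that("one fixed Radau step reproduces the order-5 stability function", {
  # on y' = -y the stage system is linear, so the simplified Newton
  # iteration is exact and the step must equal R(-h) y0 with
  # R(z) = (1 + 2z/5 + z^2/20) / (1 - 3z/5 + 3z^2/20 - z^3/60);
  # equality also certifies that the returned solution IS the last stage
  h <- 0.37
  z <- -h
  Rz <- (1 + 2 * z / 5 + z^2 / 20) / (1 - 3 * z / 5 + 3 * z^2 / 20 - z^3 / 60)
  tr <- radau5_integrate(decay_rbm(), 1, solver_settings(t_out = h, h_fixed = h))
  expect_equal(unname(tr$states[1, 1]), Rz, tolerance = 1e-12)
})

test_that("the explicit solver gives up on the Robertson stiff problem", {
  m <- robertson_rbm()
  tr <- dopri5_integrate(m, m$X0, solver_settings(t_out = 1e3))
  expect_true(tr$status %in% c("stiffness_detected", "step_limit_exceeded"))
  expect_lte(tr$n_steps, 1e4)
})

test_that("Radau matches an independent stiff reference on Robertson", {
  skip_if_not_installed("deSolve")
  m <- robertson_rbm()
  t_out <- c(1, 1e2, 1e3)
  tr <- radau5_integrate(m, m$X0, solver_settings(t_out = t_out))
  expect_equal(tr$status, "success")
  ref <- deSolve::lsoda(
    y = m$X0, times = c(0, t_out),
    func = function(t, y, p) list(mass_action_rhs(m, y)),
    rtol = 1e-10, atol = 1e-14)
  ref_states <- unname(ref[-1, -1, drop = FALSE])
  rel <- abs(tr$states - ref_states) / pmax(abs(ref_states), 1e-30)
  expect_lt(max(rel), 1e-4)
})

test_that("plain-function systems integrate without an rbm", {
  f <- function(t, x) -2 * x
  s <- solver_settings(t_out = 1)
  expect_equal(unname(dopri5_integrate(f, 1, s)$states[1, 1]), exp(-2),
               tolerance = 1e-5)
  # Radau derives the Jacobian by finite differences when none is given
  expect_equal(unname(radau5_integrate(f, 1, s)$states[1, 1]), exp(-2),
               tolerance = 1e-5)
})

test_that("degenerate grids and counters behave", {
  m <- decay_rbm()
  # t_out = 0 alone returns the initial state with zero steps
  tr <- dopri5_integrate(m, 1, solver_settings(t_out = 0))
  expect_equal(tr$status, "success")
  expect_equal(unname(tr$states[1, 1]), 1)
  expect_equal(tr$n_steps, 0L)
  # step accounting is consistent on a real run
  tr2 <- radau5_integrate(robertson_rbm(), c(1, 0, 0),
                          solver_settings(t_out = c(1, 10)))
  expect_identical(tr2$n_steps, tr2$n_accepted + tr2$n_rejected)
  # trajectory accessors
  expect_s3_class(tidy(tr2), "tbl_df")
  expect_equal(nrow(tidy(tr2)), 2 * 3)
  expect_equal(glance(tr2)$status, "success")
})
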