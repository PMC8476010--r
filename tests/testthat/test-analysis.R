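ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

# closed-form Ishigami first-order indices
ishigami_S1 <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  c(V1 / V, V2 / V, 0)
}

test_that("the Saltelli design has the prescribed row counts and bounds", {
  b11 <- matrix(rep(c(0, 1), 11), ncol = 2, byrow = TRUE)
  X <- saltelli_sample(b11, 512, second_order = TRUE)
  expect_equal(nrow(X), 12288)
  expect_equal(ncol(X), 11)
  X2 <- saltelli_sample(matrix(c(0, 1), 1), 2, second_order = TRUE)
  expect_equal(nrow(X2), 8)
  # row-count law over a range of D and n_base
  for (D in c(1, 4, 16)) {
    for (nb in c(2, 64, 1024)) {
      bnd <- matrix(rep(c(-1, 3), D), ncol = 2, byrow = TRUE)
      expect_equal(nrow(saltelli_sample(bnd, nb, TRUE)), nb * (2 * D + 2))
      expect_equal(nrow(saltelli_sample(bnd, nb, FALSE)), nb * (D + 2))
    }
  }
  # scaled into bounds, spanning each interval
  bnd <- rbind(c(-2, 2), c(10, 30))
  X3 <- saltelli_sample(bnd, 256, second_order = FALSE)
  for (j in 1:2) {
    expect_true(all(X3[, j] >= bnd[j, 1] & X3[, j] <= bnd[j, 2]))
    expect_lt(min(X3[, j]), bnd[j, 1] + 0.1 * diff(bnd[j, ]))
    expect_gt(max(X3[, j]), bnd[j, 2] - 0.1 * diff(bnd[j, ]))
  }
  expect_error(saltelli_sample(rbind(c(1, 0)), 8), "lo < hi")
})

test_that("constant outputs yield zero indices with a degeneracy flag", {
  bnd <- rbind(c(0, 1), c(0, 1))
  X <- saltelli_sample(bnd, 16, second_order = FALSE)
  res <- sobol_indices(rep(3.7, nrow(X)), D = 2, n_base = 16,
                       second_order = FALSE, n_boot = 10)
  expect_true(res$degenerate)
  expect_equal(res$S1, c(0, 0))
  expect_equal(res$ST, c(0, 0))
})

test_that("an additive linear model decomposes its variance exactly", {
  a <- c(1, 2, 0.5)
  bnd <- rbind(c(0, 1), c(0, 1), c(0, 1))
  X <- saltelli_sample(bnd, 1024, second_order = FALSE)
  Y <- drop(X %*% a)
  withr::with_seed(1, {
    res <- sobol_indices(Y, D = 3, n_base = 1024, second_order = FALSE,
                         n_boot = 200)
  })
  expect_gt(sum(res$S1), 0.95)
  expect_lt(sum(res$S1), 1.05)
  expect_true(all(abs(res$ST - res$S1) < 0.05))
  # analytic indices a_j^2 V_j / sum: uniform(0,1) variances are equal
  expect_equal(res$S1, a^2 / sum(a^2), tolerance = 0.05)
  # total order cannot fall below first order beyond CI noise
  expect_true(all(res$ST >= res$S1 - res$S1_conf - res$ST_conf))
})

test_that("Ishigami first-order indices match the closed form within CIs", {
  bnd <- matrix(rep(c(-pi, pi), 3), ncol = 2, byrow = TRUE)
  X <- saltelli_sample(bnd, 1024, second_order = TRUE)
  Y <- ishigami(X)
  withr::with_seed(2, {
    res <- sobol_indices(Y, D = 3, n_base = 1024, second_order = TRUE,
                         n_boot = 500)
  })
  truth <- ishigami_S1()
  expect_true(all(abs(res$S1 - truth) <= pmax(res$S1_conf, 0.02)))
  # x3 has no first-order effect but a strong interaction with x1
  expect_gt(res$ST[3], 0.15)
  d <- tidy(res)
  expect_equal(dim(d), c(3L, 5L))
})

test_that("the SA output statistic is the deviation from the reference", {
  tr <- fake_trajectory(c(0, 1), rbind(c(1, 2), c(0.7, 1.9)))
  expect_equal(sa_output_statistic(tr, 1, 0.7), 0)
  expect_equal(sa_output_statistic(tr, 1, 0.5), 0.2)
  # reference from an unperturbed base run: statistic 0 for that run
  m <- reversible_rbm()
  s <- solver_settings(t_out = c(1, 5))
  base <- dopri5_integrate(m, m$X0, s)
  ref <- base$states[nrow(base$states), 1]
  expect_equal(sa_output_statistic(base, 1, ref), 0)
  bad <- fake_trajectory(c(0, 1), rbind(c(1, 2), c(1, 2)),
                         status = "step_limit_exceeded")
  expect_error(sa_output_statistic(bad, 1, 0), "failed")
})

test_that("sweep grids have the documented shape and orientation", {
  m <- reversible_rbm()
  ax1 <- sweep_axis("x0", 1, lo = 0.5, hi = 2, n = 4)
  ax2 <- sweep_axis("k", 1, lo = 0.1, hi = 10, n = 5, scale = "log")
  plan <- psa_plan(ax1, ax2, batch_size = 7)
  expect_equal(plan$n_parameterizations, 20)
  expect_equal(plan$n_batches, 3L)
  s <- solver_settings(t_out = seq(1, 10, by = 1))
  # summary = total mass, conserved: constant across the k axis
  res <- psa_2d(m, ax1, ax2, s, function(tr) sum(tr$states[1, ]),
                batch_size = 7)
  expect_equal(dim(res$values), c(4L, 5L))
  for (i in 1:4) {
    expect_equal(unname(res$values[i, ]), rep(ax1$points[i], 5),
                 tolerance = 1e-9)
  }
  d <- tidy(res)
  expect_equal(nrow(d), 20)
})

test_that("oscillation amplitude is the mean peak-to-trough drop", {
  tt <- seq(0, 40, length.out = 2001)
  flat <- fake_trajectory(tt, cbind(rep(2, 2001), rep(0, 2001)))
  expect_equal(oscillation_amplitude(flat, 1), 0)
  y <- 0.4 * sin(2 * pi * tt / 4) + 3
  tr <- fake_trajectory(tt, cbind(y, y))
  amp <- oscillation_amplitude(tr, 1, transient_fraction = 0.25)
  expect_equal(amp, 0.8, tolerance = 0.02)
  # damped oscillation has a strictly smaller mean amplitude
  yd <- 0.4 * exp(-tt / 20) * sin(2 * pi * tt / 4) + 3
  ampd <- oscillation_amplitude(fake_trajectory(tt, cbind(yd, yd)), 1,
                                transient_fraction = 0.25)
  expect_lt(ampd, amp)
  expect_gt(ampd, 0)
  expect_error(oscillation_amplitude(tr, 1, transient_fraction = 1), "\\[0, 1\\)")
})

test_that("a swept oscillator shows its bifurcation in the amplitude map", {
  # Brusselator with a = 1: limit cycle iff b > 1 + a^2 = 2
  m <- brusselator_rbm()
  ax1 <- sweep_axis("k", 2, lo = 1, hi = 4, n = 4)       # b in {1, 2, 3, 4}
  ax2 <- sweep_axis("x0", 1, lo = 0.5, hi = 1.5, n = 2)  # initial X
  # integrate tighter than the amplitude cutoff so numerical wiggle in the
  # settled regime stays below the non-oscillation threshold
  s <- solver_settings(t_out = seq(0, 100, length.out = 2001), eps_r = 1e-9)
  res <- psa_2d(m, ax1, ax2, s,
                function(tr) oscillation_amplitude(tr, 1))
  expect_true(all(res$status == "success"))
  # below the Hopf point the dynamics settle: zero amplitude
  expect_equal(unname(res$values[1, ]), c(0, 0))
  # well above it the limit cycle oscillates visibly
  expect_true(all(res$values[3:4, ] > 0.5))
})

test_that("the fitness is zero at an exact match and scales relatively", {
  m <- reversible_rbm()
  s <- solver_settings(t_out = seq(0.5, 3, by = 0.5))
  tr <- dopri5_integrate(m, m$X0, s)
  target <- data.frame(time = s$t_out, S1 = tr$states[, 1],
                       S2 = tr$states[, 2])
  expect_equal(fitness_relative_distance(tr, target), 0)
  # one species, one point: |1.2 - 1| / 1 = 0.2
  one <- fake_trajectory(1, matrix(c(1.2, 0), 1))
  expect_equal(fitness_relative_distance(
    one, data.frame(time = 1, S1 = 1)), 0.2)
  # invariant to species column order
  target_swapped <- target[, c("time", "S2", "S1")]
  off <- radau5_integrate(m, c(0.9, 0.1), s)
  expect_equal(fitness_relative_distance(off, target),
               fitness_relative_distance(off, target_swapped))
  expect_gt(fitness_relative_distance(off, target), 0)
  # failed trajectories are penalized with +Inf
  bad <- fake_trajectory(1, matrix(c(1, 0), 1), status = "stiffness_detected")
  expect_equal(fitness_relative_distance(bad, data.frame(time = 1, S1 = 1)),
               Inf)
})

test_that("free kinetic constants are recoverable through the fitness", {
  m <- reversible_rbm(k1 = 2, k2 = 0.5)
  s <- solver_settings(t_out = seq(0.2, 4, by = 0.2))
  truth <- dopri5_integrate(m, m$X0, s)
  target <- data.frame(time = s$t_out, S1 = truth$states[, 1],
                       S2 = truth$states[, 2])
  fit <- fit_kinetics(m, free = c(1, 2), target, s,
                      start = c(1, 1), solver = "dopri5")
  expect_lt(max(abs(fit$k_hat - c(2, 0.5)) / c(2, 0.5)), 0.1)
  expect_lt(fit$fitness, 1e-3)
})
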