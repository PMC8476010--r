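test_that("a model folder round-trips exactly", {
  m <- generate_rbm(synthetic_spec(8, 8, seed = 13))
  ps <- make_batch(m, R = 4, seed = 2)
  t_out <- seq(0, 2, by = 0.5)
  dir <- withr::local_tempdir()
  write_biosimware(m, dir, params = ps, t_out = t_out,
                   species_to_save = c(1, 3, 8))
  rt <- read_biosimware(dir)
  expect_identical(rt$rbm$A, m$A)
  expect_identical(rt$rbm$B, m$B)
  expect_identical(rt$rbm$K, m$K)
  expect_identical(rt$rbm$X0, m$X0)
  expect_identical(rt$rbm$species, m$species)
  expect_identical(rt$params$X0_batch, ps$X0_batch)
  expect_identical(rt$params$K_batch, ps$K_batch)
  expect_identical(rt$t_out, t_out)
  expect_identical(rt$species_to_save, c(1L, 3L, 8L))
})

test_that("c_vector has one line per reaction and MX_0 one row per simulation", {
  m <- generate_rbm(synthetic_spec(5, 7, seed = 1))
  ps <- make_batch(m, R = 4, seed = 1)
  dir <- withr::local_tempdir()
  write_biosimware(m, dir, params = ps)
  expect_length(readLines(file.path(dir, "c_vector")), 7)
  expect_length(readLines(file.path(dir, "MX_0")), 4)
})

test_that("missing mandatory files are reported by name", {
  m <- generate_rbm(synthetic_spec(4, 4, seed = 1))
  dir <- withr::local_tempdir()
  write_biosimware(m, dir)
  file.remove(file.path(dir, "c_vector"))
  expect_error(read_biosimware(dir), "c_vector")
  expect_error(read_biosimware(file.path(dir, "nope")), "not found")
})

test_that("dimension inconsistencies cite the offending file", {
  m <- generate_rbm(synthetic_spec(4, 4, seed = 1))
  dir <- withr::local_tempdir()
  write_biosimware(m, dir)
  writeLines(c("1 2", "3 4", "5 6"), file.path(dir, "c_vector"))
  expect_error(read_biosimware(dir), "c_vector")
  write_biosimware(m, dir)
  writeLines("not a number", file.path(dir, "M_0"))
  expect_error(read_biosimware(dir), "M_0")
})

test_that("a longhand toy folder parses to its hand-built model", {
  dir <- withr::local_tempdir()
  # A + B -> C ; C -> A ; B -> 0, written out by hand
  writeLines(c("1\t1\t0", "0\t0\t1", "0\t1\t0"), file.path(dir, "left_side"))
  writeLines(c("0\t0\t1", "1\t0\t0", "0\t0\t0"), file.path(dir, "right_side"))
  writeLines(c("0.5", "2", "1e-3"), file.path(dir, "c_vector"))
  writeLines("1\t0.5\t0", file.path(dir, "M_0"))
  rt <- read_biosimware(dir)
  hand <- rbm(A = rbind(c(1, 1, 0), c(0, 0, 1), c(0, 1, 0)),
              B = rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, 0)),
              K = c(0.5, 2, 1e-3), X0 = c(1, 0.5, 0))
  expect_identical(rt$rbm$A, hand$A)
  expect_identical(rt$rbm$K, hand$K)
  expect_identical(rt$rbm$X0, hand$X0)
  expect_identical(rt$species_to_save, 1:3)  # default: save all
})

test_that("dynamics TSVs round-trip the states to high precision", {
  m <- reversible_rbm()
  s <- solver_settings(t_out = seq(0.2, 2, by = 0.2))
  br <- run_batch(m, parameterization_set(matrix(c(1, 0), 1)), s)
  dir <- withr::local_tempdir()
  write_dynamics(br, dir, species_to_save = c(1, 2))
  f <- list.files(dir, pattern = "^dynamics_", full.names = TRUE)
  expect_length(f, 1)
  d <- utils::read.delim(f)
  expect_equal(dim(d), c(10, 3))
  rel <- abs(as.matrix(d[, 2:3]) - br$trajectories[[1]]$states) /
    pmax(abs(br$trajectories[[1]]$states), 1e-300)
  expect_lt(max(rel), 1e-12)
  # summary file carries status and solver
  summ <- utils::read.delim(file.path(dir, "summary.tsv"))
  expect_equal(summ$status, "success")
  # empty selection defaults to all species
  write_dynamics(br, dir, species_to_save = integer(0))
  d2 <- utils::read.delim(list.files(dir, "^dynamics_", full.names = TRUE)[1])
  expect_equal(ncol(d2), 3)
})

test_that("mass-action SBML imports to the equivalent model", {
  f <- withr::local_tempfile(fileext = ".xml")
  sbml_mass_action(f)
  m <- import_sbml(f)
  expect_identical(m$species, c("A", "B"))
  expect_equal(m$A, matrix(c(1, 0), 1), ignore_attr = TRUE)
  expect_equal(m$B, matrix(c(0, 1), 1), ignore_attr = TRUE)
  expect_equal(m$K, 2)
  expect_equal(m$X0, c(3, 5))
})

test_that("reversible reactions split into forward and backward", {
  f <- withr::local_tempfile(fileext = ".xml")
  sbml_reversible(f)
  m <- import_sbml(f)
  expect_equal(nrow(m$A), 2)
  expect_equal(m$K, c(1.5, 0.5))
  expect_equal(m$A, rbind(c(1, 0), c(0, 1)), ignore_attr = TRUE)
  expect_equal(m$B, rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
})

test_that("non-mass-action kinetic laws are rejected with the reaction name", {
  f <- withr::local_tempfile(fileext = ".xml")
  sbml_michaelis_menten(f)
  expect_error(import_sbml(f), "enzymatic")
})
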