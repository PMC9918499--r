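test_that("ensemble validates frame times and spacing", {
  x <- matrix(rnorm(30), 5, 6)
  e <- ensemble(x, sampling_interval = 100)
  expect_identical(e$times, c(0, 100, 200, 300, 400))
  expect_error(ensemble(x, 100, times = c(0, 100, 150, 300, 400)),
               "constant spacing")
  expect_error(ensemble(x[0, , drop = FALSE], 100), "at least one")
})

test_that("fixture structure and trajectory round-trip through files", {
  sim <- quick_sim(20L, seed = 5L)
  dir <- withr::local_tempdir()
  fx <- write_fixture(sim$system, sim$ensemble, dir, sim$truth)
  sys2 <- load_structure(fx$structure, fx$topology)
  expect_identical(nrow(sys2$atoms), nrow(sim$system$atoms))
  expect_identical(range(sys2$dna$bp_index), c(-93L, 93L))
  # PDB coordinates carry 3 decimals
  expect_lt(max(abs(sys2$xyz - sim$system$xyz)), 1e-3 + 1e-9)
  ens2 <- load_trajectory(fx$trajectory, sim$system, 100)
  expect_identical(nrow(ens2$xyz), 20L)
  expect_identical(ens2$times, (0:19) * 100)
  # DCD stores float32
  expect_lt(max(abs(ens2$xyz - sim$ensemble$xyz)), 1e-4)
  tsv <- read.table(fx$truth, header = TRUE, sep = "\t")
  expect_identical(nrow(tsv), 20L)
})

test_that("missing chains in a structure raise a named load error", {
  sim <- quick_sim(2L, seed = 5L)
  dir <- withr::local_tempdir()
  fx <- write_fixture(sim$system, sim$ensemble, dir)
  spec <- read_topology_spec(fx$topology)
  spec$chains$Z <- spec$chains$A
  expect_error(load_structure(fx$structure, spec), "Z")
  # trajectory/system atom-count mismatch
  small <- toy_duplex_system()
  expect_error(load_trajectory(fx$trajectory, small, 100), "atom count")
})

test_that("superposition undoes rigid transforms exactly", {
  sim <- quick_sim(3L, seed = 2L, noise_sigma = 0, rigid_motion = FALSE,
                   core_sigma = c(helix = 0, loop = 0))
  sys <- sim$system
  ref <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  # rotate 90 degrees about z and translate
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  moved <- sweep(ref %*% R, 2L, c(10, -4, 7), `+`)
  ens <- ensemble(matrix(as.numeric(t(moved)), nrow = 1L), 100)
  fit <- superpose(ens, sys)
  expect_lt(fit$rmsd[1L], 1e-6)
  expect_lt(max(abs(fit$xyz[1L, ] - sys$xyz)), 1e-5)
  # identity input: identity transform
  ens0 <- ensemble(matrix(sys$xyz, nrow = 1L), 100)
  fit0 <- superpose(ens0, sys)
  expect_lt(fit0$rmsd[1L], 1e-9)
})

test_that("fit RMSD matches an independent Kabsch oracle under noise", {
  set.seed(42)
  sim <- quick_sim(2L, seed = 2L)
  sys <- sim$system
  sel <- core_ca_selection(sys)[1:10]
  ref <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  for (rep in 1:5) {
    noisy <- ref
    noisy[sel, ] <- noisy[sel, ] + matrix(rnorm(30, 0, 0.5), 10, 3)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    moved <- sweep(noisy %*% R, 2L, runif(3, -5, 5), `+`)
    ens <- ensemble(matrix(as.numeric(t(moved)), nrow = 1L), 100)
    fit <- superpose(ens, sys, selection = sel)
    oracle <- kabsch_rmsd(moved[sel, ], ref[sel, ])
    expect_equal(fit$rmsd[1L], oracle, tolerance = 1e-6)
  }
})

test_that("superposition is idempotent and commutes with trimming", {
  sim <- quick_sim(30L, seed = 9L)
  sys <- sim$system
  once <- superpose(sim$ensemble, sys)
  twice <- superpose(once, sys)
  expect_lt(max(abs(once$xyz - twice$xyz)), 1e-6)
  a <- superpose(trim_equilibration(sim$ensemble, 1), sys)
  b <- trim_equilibration(superpose(sim$ensemble, sys), 1)
  expect_equal(a$xyz, b$xyz, tolerance = 1e-10)
  expect_error(superpose(sim$ensemble, sys, selection = 1:2), "at least 3")
})

test_that("equilibration trimming drops the leading frames only", {
  x <- matrix(rnorm(2100 * 6), 2100, 6)
  e <- ensemble(x, sampling_interval = 100)  # 100 ps spacing
  tr <- trim_equilibration(e, 200)           # 200 ns cut
  expect_identical(nrow(tr$xyz), 2100L - 2000L)
  expect_identical(tr$times[1L], 200000)
  expect_identical(trim_equilibration(e, 0)$xyz, e$xyz)
  small <- ensemble(x[1:10, ], 100)
  expect_error(trim_equilibration(small, 200), "every frame")
  # untrimmed view: the input object is untouched
  expect_identical(nrow(e$xyz), 2100L)
})

test_that("GRO structures load with nm-to-Angstrom conversion", {
  dir <- withr::local_tempdir()
  gro <- file.path(dir, "toy.gro")
  writeLines(c(
    "toy system",
    "    4",
    "    1GLY     CA    1   0.100   0.200   0.300",
    "    2GLY     CA    2   0.400   0.500   0.600",
    "    1DA     C1'    3   0.700   0.800   0.900",
    "    1DA     C1'    4   1.000   1.100   1.200",
    "   5.0   5.0   5.0"), gro)
  at <- read_gro(gro)
  expect_identical(nrow(at), 4L)
  expect_equal(at$x, c(1, 4, 7, 10))
  expect_identical(at$chain[1:2], c("A", "A"))
  expect_identical(at$chain[3:4], c("B", "B"))
})
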