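test_that("bp centers are C1'-C1' midpoints on duplexes, beads otherwise", {
  sys <- toy_duplex_system()
  expect_equal(bp_center(sys$xyz, sys, 0L), c(0, 0, 0))
  expect_equal(bp_center(sys$xyz, sys, -1L), c(-10, 0, 0))
  expect_equal(bp_center(sys$xyz, sys, 1L), c(10, 0, 0))
  expect_error(bp_center(sys$xyz, sys, 5L), "not in system")
  # pseudo-atom system: the bead coordinate itself
  ref <- generate_reference(synthetic_params())
  bead <- matrix(ref$xyz, ncol = 3L, byrow = TRUE)[
    which(ref$atoms$bp_index %in% 0L), ]
  expect_equal(bp_center(ref$xyz, ref, 0L), unname(bead))
})

test_that("unwrapped bp are counted from the DNA ends inward", {
  sys <- generate_reference(synthetic_params())
  ref <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  mk_frame <- function(m) list(time = 0, xyz = as.numeric(t(m)),
                               superposed = TRUE)
  expect_identical(count_unwrapped(mk_frame(ref), sys),
                   c(entry = 0L, exit = 0L))
  # displace entry-side bp -73..-69 by 10 A
  dna_rows <- which(sys$atoms$role == "dna")
  bp <- sys$atoms$bp_index[dna_rows]
  m <- ref
  m[dna_rows[bp %in% -73:-69], 1] <- m[dna_rows[bp %in% -73:-69], 1] + 10
  expect_identical(count_unwrapped(mk_frame(m), sys),
                   c(entry = 5L, exit = 0L))
  # an isolated displaced dyad does not count (end-anchored contiguity)
  m2 <- ref
  m2[dna_rows[bp == 0L], 1] <- m2[dna_rows[bp == 0L], 1] + 10
  expect_identical(count_unwrapped(mk_frame(m2), sys),
                   c(entry = 0L, exit = 0L))
  # linker displacement is ignored
  m3 <- ref
  m3[dna_rows[abs(bp) >= 74L], 1] <- m3[dna_rows[abs(bp) >= 74L], 1] + 50
  expect_identical(count_unwrapped(mk_frame(m3), sys),
                   c(entry = 0L, exit = 0L))
  # unsuperposed frames are rejected
  fr <- mk_frame(ref); fr$superposed <- FALSE
  expect_error(count_unwrapped(fr, sys), "superposed")
})

test_that("unwrap counting is monotone in the threshold", {
  sim <- quick_sim(100L, seed = 4L, epsilon = 0.3)
  ens <- superpose(sim$ensemble, sim$system)
  last <- NULL
  for (th in c(3, 5, 7, 9, 12)) {
    uw <- unwrap_series(ens, sim$system, threshold = th)
    if (!is.null(last)) expect_true(all(uw$total <= last))
    last <- uw$total
  }
})

test_that("per-frame series counting agrees with the single-frame path", {
  sim <- quick_sim(50L, seed = 14L, epsilon = 0.3)
  ens <- superpose(sim$ensemble, sim$system)
  uw <- unwrap_series(ens, sim$system)
  for (f in c(1L, 10L, 37L, 50L)) {
    one <- count_unwrapped(get_frame(ens, f), sim$system)
    expect_identical(unname(one), c(uw$entry[f], uw$exit[f]))
  }
})

test_that("radius of gyration matches closed forms", {
  sys <- toy_duplex_system()
  xyz <- sys$xyz
  expect_identical(radius_of_gyration(xyz, sys, 1L), 0)
  # two equal-mass points 2 A apart -> 1 A (atoms 5 and 6 are 10 A apart)
  two <- c(5L, 6L)
  expect_equal(radius_of_gyration(xyz, sys, two), 5)
  # ring of 1000 unweighted points at radius r
  r <- 17.3
  th <- 2 * pi * (1:1000) / 1000
  ring <- cbind(r * cos(th), r * sin(th), 0)
  expect_equal(radius_of_gyration(as.numeric(t(ring)), sys, 1:1000,
                                  mass_weighted = FALSE), r,
               tolerance = 1e-9)
  # rg_series equals the per-frame computation (independent code path)
  sim <- quick_sim(20L, seed = 3L)
  sel <- which(sim$system$atoms$role == "dna")
  rs <- rg_series(sim$ensemble, sim$system, sel)
  per_frame <- vapply(1:20, function(f)
    radius_of_gyration(sim$ensemble$xyz[f, ], sim$system, sel), numeric(1))
  expect_equal(rs, per_frame, tolerance = 1e-9)
  expect_error(radius_of_gyration(xyz, sys, integer(0)), "empty")
})

test_that("gaping distance obeys axial Pythagoras and rigid invariance", {
  sys <- generate_reference(synthetic_params())
  ref <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  d0 <- gaping_distance(sys$xyz, sys)
  # shift the +gyre axially by 12 A
  dna_rows <- which(sys$atoms$role == "dna")
  bp <- sys$atoms$bp_index[dna_rows]
  m <- ref
  m[dna_rows[bp >= 31L], 3] <- m[dna_rows[bp >= 31L], 3] + 12
  d1 <- gaping_distance(as.numeric(t(m)), sys)
  ip <- sys$meta$gaping_inplane; ax <- sys$meta$gaping_axial0
  expect_equal(d1, sqrt(ip^2 + (ax + 12)^2), tolerance = 1e-9)
  # invariant under a rigid transform of the whole frame
  R <- qr.Q(qr(matrix(c(1, 2, 0, 0, 1, 3, 1, 0, 1), 3)))
  moved <- sweep(m %*% R, 2, c(3, -8, 2), `+`)
  d2 <- gaping_distance(as.numeric(t(moved)), sys)
  expect_equal(d2, d1, tolerance = 1e-9)
  expect_error(gaping_distance(sys$xyz, sys, shl_pair = c(-8, 8)),
               "outside the DNA core")
  # series equals per-frame values
  sim <- quick_sim(25L, seed = 6L)
  gs <- gaping_series(sim$ensemble, sim$system)
  pf <- vapply(1:25, function(f)
    gaping_distance(sim$ensemble$xyz[f, ], sim$system), numeric(1))
  expect_equal(gs$distance, pf, tolerance = 1e-9)
})

test_that("2D projection kills axial motion and shows unwrapping", {
  sim <- quick_sim(60L, seed = 19L, epsilon = 0.2, noise_sigma = 0,
                   rigid_motion = FALSE)
  sys <- sim$system
  fr <- list(time = 0, xyz = sys$xyz, superposed = TRUE)
  pr <- project_dna_2d(fr, sys)
  core <- abs(sys$dna$bp_index) <= 73L
  rad <- sqrt(rowSums(pr[core, ]^2))
  expect_lt(max(abs(rad - 41.9)), 0.5)
  # axial displacement leaves the projection unchanged
  m <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  ax <- sys$plane$axis
  m2 <- sweep(m, 2L, 25 * ax, `+`)
  pr2 <- project_dna_2d(list(time = 0, xyz = as.numeric(t(m2)),
                             superposed = TRUE), sys)
  expect_equal(pr2, pr, tolerance = 1e-9)
  # frames with unwrapped bp project outside the wrapped radius
  k <- which(sim$truth$entry >= 3L)[1L]
  if (!is.na(k)) {
    prk <- project_dna_2d(get_frame(sim$ensemble, k), sys)
    unwrapped <- paste(seq(-73L, -73L + sim$truth$entry[k] - 1L))
    expect_gt(min(sqrt(rowSums(prk[unwrapped, , drop = FALSE]^2))), 45)
  }
  expect_error(project_dna_2d(list(xyz = sys$xyz, superposed = FALSE), sys),
               "superposed")
})
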