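test_that("the contact cutoff is strictly 'less than'", {
  sys <- toy_duplex_system()
  m <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  # place core atom 1 at a controlled distance from DNA atom 5
  m[1, ] <- m[5, ] + c(4.49, 0, 0)
  expect_identical(count_contacts(as.numeric(t(m)), sys, 1L, 5L), 1L)
  m[1, ] <- m[5, ] + c(4.50, 0, 0)
  expect_identical(count_contacts(as.numeric(t(m)), sys, 1L, 5L), 0L)
  expect_identical(count_contacts(sys$xyz, sys, integer(0), 5L), 0L)
  expect_error(count_contacts(sys$xyz, sys, 1:3, 3:5), "overlap")
})

test_that("hydrogens are filtered from contact selections with a warning", {
  sys <- toy_duplex_system()
  sys$atoms$elety[2] <- "HB2"
  m <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  m[1, ] <- m[5, ] + c(1, 0, 0)
  m[2, ] <- m[5, ] + c(1, 0, 0)
  expect_warning(n <- count_contacts(as.numeric(t(m)), sys, 1:2, 5L),
                 "hydrogen")
  expect_identical(n, 1L)
})

test_that("cell-list counting equals the all-pairs oracle", {
  # random 200-atom instances in a 30 A box, split 100/100
  for (s in 1:50) {
    set.seed(s)
    pts <- matrix(runif(600, 0, 30), 200, 3)
    a <- pts[1:100, ]; b <- pts[101:200, ]
    expect_identical(nucdyn:::.contact_count_cpp(a, b, 4.5), brute_contacts(a, b, 4.5))
  }
  # symmetry and monotonicity in the cutoff
  set.seed(1)
  pts <- matrix(runif(600, 0, 20), 200, 3)
  a <- pts[1:100, ]; b <- pts[101:200, ]
  expect_identical(nucdyn:::.contact_count_cpp(a, b, 4.5), nucdyn:::.contact_count_cpp(b, a, 4.5))
  cuts <- c(2, 3, 4.5, 6)
  n <- vapply(cuts, function(cc) nucdyn:::.contact_count_cpp(a, b, cc), integer(1))
  expect_true(all(diff(n) >= 0L))
})

test_that("tail-DNA contacts partition over DNA regions", {
  sim <- quick_sim(30L, seed = 12L)
  sys <- sim$system
  tot <- tail_dna_contact_series(sim$ensemble, sys, "A", "C", "total")
  inner <- tail_dna_contact_series(sim$ensemble, sys, "A", "C", "inner")
  outer <- tail_dna_contact_series(sim$ensemble, sys, "A", "C", "outer")
  linker <- tail_dna_contact_series(sim$ensemble, sys, "A", "C", "linker")
  expect_identical(tot$contacts,
                   inner$contacts + outer$contacts + linker$contacts)
})

test_that("bound tails meet the contact floor and unbound tails make none", {
  sim <- quick_sim(80L, seed = 23L, noise_sigma = 0)
  sys <- sim$system
  cs <- tail_dna_contact_series(sim$ensemble, sys, "B", "N", "total")
  floor_n <- length(tail_atoms(sys, "B", "N"))
  bound <- sim$truth$`bound.B.N` == 1L
  expect_true(all(cs$contacts[bound] >= floor_n))
  expect_identical(unique(cs$contacts[!bound]), 0L)
})

test_that("Savitzky-Golay smoothing reproduces low-degree signals", {
  expect_equal(smooth_series(rep(3, 500)), rep(3, 500))
  lin <- seq(0, 10, length.out = 500)
  expect_equal(smooth_series(lin), lin, tolerance = 1e-9)
  # white noise variance shrinks by the window size at interior points
  set.seed(7)
  x <- rnorm(20000, 0, 2)
  sm <- smooth_series(x)
  interior <- 200:19800
  expect_lt(abs(var(sm[interior]) - 4 / 101), 0.15 * 4 / 101)
  # matches the signal package's filter at interior points
  ref <- signal::sgolayfilt(x[1:1000], p = 1, n = 101)
  expect_equal(smooth_series(x[1:1000])[51:950], ref[51:950],
               tolerance = 1e-8)
  expect_error(smooth_series(rnorm(50)), "shorter")
  expect_error(smooth_series(rnorm(500), window_ns = 0.1, poly_order = 5),
               "window too short")
})

test_that("minimum tail-DNA distance equals the brute-force oracle", {
  sim <- quick_sim(5L, seed = 33L)
  sys <- sim$system
  sel_t <- tail_atoms(sys, "A", "C")
  side <- -1L
  sel_d <- dna_region_atoms(sys, side * 41:75)
  for (f in 1:5) {
    xyz <- sim$ensemble$xyz[f, ]
    m <- matrix(xyz, ncol = 3L, byrow = TRUE)
    expect_equal(tail_dna_min_distance(xyz, sys, "A", "C"),
                 brute_min_dist(m[sel_t, ], m[sel_d, ]), tolerance = 1e-12)
  }
  expect_error(tail_atoms(sys, "C", "C"), "no C-terminal tail")
})

test_that("correlation handles trivial and degenerate cases", {
  x <- rnorm(100)
  expect_equal(series_correlation(x, x), 1)
  expect_equal(series_correlation(x, -x), -1)
  expect_error(series_correlation(x, rep(1, 100)), "zero-variance")
  expect_error(series_correlation(x, x[1:50]), "lengths differ")
})

test_that("tail contacts anti-correlate with unwrapping, scaling with coupling", {
  rs <- sapply(c(0.02, 0.15), function(cpl) {
    sim <- simulate_trajectory(synthetic_params(
      n_frames = 600L, seed = 41L, epsilon = 0.25, bind_coupling = cpl))
    cs <- tail_dna_contact_series(sim$ensemble, sim$system, "A", "C", "total")
    series_correlation(sim$truth$total, cs$contacts)
  })
  expect_true(all(rs < 0))
  expect_gt(abs(rs[2]), abs(rs[1]))
})
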