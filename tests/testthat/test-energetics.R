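RT310 <- 1.987204e-3 * 310

test_that("Boltzmann inversion is zero at the mode, 0.427 at half occupancy", {
  counts <- c(rep(0L, 1000L), rep(1L, 500L), rep(3L, 100L))
  prof <- free_energy_1d(counts, temperature = 310)
  expect_identical(prof$delta_g[prof$i == 0L], 0)
  expect_equal(round(prof$delta_g[prof$i == 1L], 3), 0.427)
  expect_equal(prof$delta_g[prof$i == 1L], -RT310 * log(0.5))
  # unvisited states are undefined, not infinite
  expect_true(is.na(prof$delta_g[prof$i == 2L]))
  expect_true(all(prof$delta_g >= 0, na.rm = TRUE))
  expect_error(free_energy_1d(integer(0)), "empty")
  expect_error(free_energy_1d(c(1L, -2L)), ">= 0")
})

test_that("duplicating modal frames shifts the profile analytically", {
  counts <- c(rep(0L, 800L), rep(1L, 300L), rep(2L, 40L))
  p1 <- free_energy_1d(counts)
  p2 <- free_energy_1d(c(counts, rep(0L, 200L)))
  # dG_i = -RT ln(N_i / N_max): adding modal frames raises every other
  # state by exactly RT ln(1000/800)
  shift <- RT310 * log(1000 / 800)
  expect_equal(p2$delta_g[p2$i == 1L] - p1$delta_g[p1$i == 1L], shift,
               tolerance = 1e-12)
  expect_equal(p2$delta_g[p2$i == 2L] - p1$delta_g[p1$i == 2L], shift,
               tolerance = 1e-12)
})

test_that("profile slope recovers the zipper detachment energy", {
  sim <- simulate_trajectory(
    synthetic_params(epsilon = 0.5, n_frames = 30000L, seed = 61L),
    coordinates = FALSE)
  prof <- free_energy_1d(c(sim$truth$entry, sim$truth$exit))
  expect_lt(abs(profile_slope(prof) - 0.5), 0.05)
})

test_that("cross-profile standard errors follow the n = 6 convention", {
  counts <- c(rep(0L, 500L), rep(1L, 200L))
  base <- free_energy_1d(counts)
  same <- profile_standard_error(list(base, base, base, base, base, base))
  expect_true(all(same$se[same$n_profiles == 6L] == 0))
  # two profiles differing by 2d at i = 1: SE equals the direct two-number
  # standard error sd/sqrt(2)
  d <- 0.35
  pa <- base; pb <- base
  pb$delta_g[pb$i == 1L] <- pb$delta_g[pb$i == 1L] + 2 * d
  two <- profile_standard_error(list(pa, pb))
  g1 <- pa$delta_g[pa$i == 1L]; g2 <- pb$delta_g[pb$i == 1L]
  expect_equal(two$se[two$i == 1L], sd(c(g1, g2)) / sqrt(2))
  expect_equal(two$se[two$i == 1L], d)
  expect_error(profile_standard_error(list(base)), "at least 2")
})

test_that("longer runs shrink the cross-replica profile spread", {
  se_at <- function(nf) {
    profs <- lapply(1:6, function(s) {
      sim <- simulate_trajectory(
        synthetic_params(epsilon = 0.6, n_frames = nf, seed = 100L + s),
        coordinates = FALSE)
      free_energy_1d(c(sim$truth$entry, sim$truth$exit))
    })
    agg <- profile_standard_error(profs)
    mean(agg$se[agg$i %in% 1:3], na.rm = TRUE)
  }
  expect_gt(se_at(800L), se_at(20000L))
})

test_that("2D surfaces invert occupancy and keep empty bins undefined", {
  # all frames in one bin
  s1 <- free_energy_2d(rep(1, 50), rep(2, 50), bins = c(3L, 3L))
  expect_identical(sum(s1$counts), 50L)
  expect_identical(sum(!is.na(s1$delta_g)), 1L)
  expect_identical(s1$delta_g[which(s1$counts == 50L)], 0)
  # 10:1 occupancy in two bins -> 1.418 kcal/mol difference at 310 K
  cv1 <- c(rep(0, 100), rep(10, 10))
  cv2 <- c(rep(0, 100), rep(10, 10))
  s2 <- free_energy_2d(cv1, cv2, bins = c(2L, 2L))
  dg <- sort(s2$delta_g[!is.na(s2$delta_g)])
  expect_equal(round(dg[2] - dg[1], 3), 1.418)
  # uniform occupancy -> all-zero surface
  g <- expand.grid(a = 1:4, b = 1:4)
  s3 <- free_energy_2d(g$a, g$b, bins = c(4L, 4L))
  expect_true(all(s3$delta_g == 0))
  expect_error(free_energy_2d(numeric(0), numeric(0)), "non-empty")
})

test_that("marginalized surfaces match direct 1D inversion exactly", {
  set.seed(5)
  cv1 <- rnorm(2000); cv2 <- rnorm(2000, 3, 2)
  s <- free_energy_2d(cv1, cv2, bins = c(12L, 9L))
  for (margin in 1:2) {
    mp <- marginal_profile(s, margin)
    n <- if (margin == 1L) rowSums(s$counts) else colSums(s$counts)
    direct <- rep(NA_real_, length(n))
    occ <- n > 0
    direct[occ] <- -RT310 * log((n[occ] / sum(n)) / max(n / sum(n)))
    expect_equal(mp$delta_g, direct, tolerance = 1e-12)
    expect_identical(mp$n, n)
  }
})

test_that("barrier differences subtract profiles and are antisymmetric", {
  a <- free_energy_1d(c(rep(0L, 100L), rep(5L, 10L)))
  b <- free_energy_1d(c(rep(0L, 100L), rep(5L, 40L)))
  expect_equal(barrier_difference(a, a, 5L), 0)
  expect_equal(barrier_difference(a, b, 5L), -barrier_difference(b, a, 5L))
  expect_equal(barrier_difference(a, b, 5L), -RT310 * log(10 / 100) +
                 RT310 * log(40 / 100))
  expect_error(barrier_difference(a, b, 3L), "undefined")
})

test_that("zipper runs with different epsilon give the expected barrier gap", {
  prof_for <- function(eps, nf, seed) {
    sim <- simulate_trajectory(
      synthetic_params(epsilon = eps, n_frames = nf, seed = seed),
      coordinates = FALSE)
    free_energy_1d(c(sim$truth$entry, sim$truth$exit))
  }
  pa <- prof_for(0.6, 600000L, 71L)
  pb <- prof_for(0.3, 150000L, 72L)
  expect_lt(abs(barrier_difference(pa, pb, 10L) - 3.0), 0.4)
})
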