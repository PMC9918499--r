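#' Free-energy profile over the unwrapped-bp count by Boltzmann inversion
#'
#' `dG_i = -RT ln(f_i / f_max)` with `f_i = N_i / N_total` the frequency
#' of frames with i unwrapped base pairs and `f_max` the maximum
#' frequency, in kcal/mol with `R = 1.987204e-3 kcal/(mol K)`. The profile
#' is zero at the modal count and undefined (NA) at counts never visited.
#'
#' @param unwrap_counts integer vector of per-frame unwrapped-bp counts
#'   (pooled per run and side)
#' @param temperature Kelvin
#' @return object of class `fe_profile`: data frame with columns `i`,
#'   `delta_g` (kcal/mol), `n` (frames at i); attribute `temperature`
#' @export
free_energy_1d <- function(unwrap_counts, temperature = 310) {
  if (!length(unwrap_counts)) stop("empty unwrap count vector")
  if (any(unwrap_counts < 0)) stop("unwrap counts must be >= 0")
  i <- seq.int(0L, max(unwrap_counts))
  n <- tabulate(unwrap_counts + 1L, nbins = length(i))
  f <- n / sum(n)
  dg <- rep(NA_real_, length(i))
  occ <- n > 0L
  dg[occ] <- -rt_kcal(temperature) * log(f[occ] / max(f)) + 0  # kill -0
  out <- data.frame(i = i, delta_g = dg, n = n)
  attr(out, "temperature") <- temperature
  class(out) <- c("fe_profile", "data.frame")
  out
}

#' @export
print.fe_profile <- function(x, ...) {
  cat("free-energy profile over", nrow(x), "unwrapped-bp states at",
      attr(x, "temperature"), "K\n")
  print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

#' Fitted slope of a free-energy profile
#'
#' Weighted least-squares slope of `delta_g` versus `i` (weights = frame
#' counts), the per-bp unwrapping free energy implied by the profile. For
#' a zipper process this recovers the detachment energy per bp.
#'
#' @param profile [free_energy_1d()] result
#' @return slope in kcal/mol per bp
#' @export
profile_slope <- function(profile) {
  d <- profile[!is.na(profile$delta_g), , drop = FALSE]
  if (nrow(d) < 2L) stop("profile defined at fewer than 2 states")
  unname(coef(lm(delta_g ~ i, data = d, weights = d$n))[2L])
}

#' Cross-run standard errors of free-energy profiles
#'
#' Profiles are computed per run and DNA side, then combined: per
#' unwrapped count i, the mean of the defined values and the sample
#' standard deviation divided by `sqrt(number of profiles defined at i)`.
#' With three runs and two sides this matches the usual n = 6 convention.
#'
#' @param profiles list of [free_energy_1d()] results
#' @return data frame with columns `i`, `delta_g` (mean), `se`, `n_profiles`
#' @export
profile_standard_error <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  imax <- max(vapply(profiles, function(p) max(p$i), numeric(1)))
  grid <- seq.int(0L, imax)
  vals <- sapply(profiles, function(p)
    p$delta_g[match(grid, p$i)])
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  n_def <- rowSums(!is.na(vals))
  mean_g <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1L, sd, na.rm = TRUE)
  se <- ifelse(n_def >= 2L, sdv / sqrt(n_def), NA_real_)
  mean_g[n_def == 0L] <- NA_real_
  data.frame(i = grid, delta_g = mean_g, se = se, n_profiles = n_def)
}

#' Two-dimensional free-energy surface over collective variables
#'
#' Boltzmann inversion of the 2D occupancy histogram of two per-frame
#' collective variables (typically DNA radius of gyration and total
#' DNA-histone contact count): `dG = -RT ln(P / P_max)` per occupied bin,
#' NA for empty bins.
#'
#' @param cv1,cv2 equal-length numeric per-frame series
#' @param bins integer bin counts `c(n1, n2)`
#' @param temperature Kelvin
#' @return object of class `fe_surface`: list with `edges1`, `edges2`,
#'   `counts` (matrix), `delta_g` (matrix, kcal/mol)
#' @export
free_energy_2d <- function(cv1, cv2, bins = c(60L, 40L), temperature = 310) {
  if (!length(cv1) || length(cv1) != length(cv2))
    stop("collective-variable series must be non-empty and equal length")
  if (any(bins < 2L)) stop("need at least 2 bins per axis")
  pad <- function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) r + c(-0.5, 0.5) else r + c(-1, 1) * 1e-9 * diff(r)
  }
  e1 <- seq(pad(cv1)[1L], pad(cv1)[2L], length.out = bins[1L] + 1L)
  e2 <- seq(pad(cv2)[1L], pad(cv2)[2L], length.out = bins[2L] + 1L)
  b1 <- findInterval(cv1, e1, rightmost.closed = TRUE, all.inside = TRUE)
  b2 <- findInterval(cv2, e2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1L], bins[2L])
  tab <- table(factor(b1, levels = seq_len(bins[1L])),
               factor(b2, levels = seq_len(bins[2L])))
  counts[] <- as.integer(tab)
  prob <- counts / sum(counts)
  dg <- matrix(NA_real_, bins[1L], bins[2L])
  occ <- counts > 0L
  dg[occ] <- -rt_kcal(temperature) * log(prob[occ] / max(prob)) + 0
  structure(list(edges1 = e1, edges2 = e2, counts = counts, delta_g = dg,
                 temperature = temperature),
            class = "fe_surface")
}

#' Marginal free-energy profile of a 2D surface
#'
#' Marginalizes the occupancy over one axis and Boltzmann-inverts the
#' marginal, which must agree exactly with a 1D inversion of the same
#' marginal occupancy.
#'
#' @param surface [free_energy_2d()] result
#' @param margin axis kept (1 or 2)
#' @return data frame with bin centers, `delta_g` and counts
#' @export
marginal_profile <- function(surface, margin = 1L) {
  n <- if (margin == 1L) rowSums(surface$counts) else colSums(surface$counts)
  edges <- if (margin == 1L) surface$edges1 else surface$edges2
  p <- n / sum(n)
  dg <- rep(NA_real_, length(n))
  occ <- n > 0
  dg[occ] <- -rt_kcal(surface$temperature) * log(p[occ] / max(p))
  data.frame(center = (head(edges, -1L) + tail(edges, -1L)) / 2,
             delta_g = dg, n = n)
}

#' Free-energy barrier difference between two profiles at a given count
#'
#' @param profile_a,profile_b [free_energy_1d()] results
#' @param i unwrapped-bp count at which to compare
#' @return `dG_a(i) - dG_b(i)` in kcal/mol
#' @export
barrier_difference <- function(profile_a, profile_b, i) {
  ga <- profile_a$delta_g[match(i, profile_a$i)]
  gb <- profile_b$delta_g[match(i, profile_b$i)]
  if (length(ga) != 1L || is.na(ga)) stop("profile_a undefined at i = ", i)
  if (length(gb) != 1L || is.na(gb)) stop("profile_b undefined at i = ", i)
  ga - gb
}
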