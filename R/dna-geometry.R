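#' Base-pair center coordinates for one frame
#'
#' The center of a base pair is the midpoint of the two paired nucleotides'
#' C1' atoms; on pseudo-atom systems (one bead per bp) it is the bead
#' coordinate itself.
#'
#' @param xyz frame coordinates, numeric vector of length 3 * n_atoms
#' @param system [nucleosome_system()]
#' @return numeric matrix `n_bp x 3`, rows ordered as `system$dna`
#' @export
bp_center_matrix <- function(xyz, system) {
  map <- system$bp_atom_map
  if (is.null(map)) stop("system lacks a bp atom map")
  m <- matrix(xyz, ncol = 3L, byrow = TRUE)
  a <- map[, 1L]
  b <- map[, 2L]
  out <- m[a, , drop = FALSE]
  two <- !is.na(b)
  out[two, ] <- (out[two, , drop = FALSE] + m[b[two], , drop = FALSE]) / 2
  rownames(out) <- rownames(map)
  out
}

#' Center of a single base pair
#'
#' @param frame a frame as returned by [get_frame()], or a numeric xyz
#'   vector of length 3 * n_atoms
#' @param system [nucleosome_system()]
#' @param bp_index dyad-centered bp index
#' @return numeric length-3 vector (Angstrom)
#' @export
bp_center <- function(frame, system, bp_index) {
  xyz <- if (is.list(frame)) frame$xyz else frame
  key <- as.character(bp_index)
  if (!key %in% rownames(system$bp_atom_map))
    stop("bp ", bp_index, " not in system")
  ctr <- bp_center_matrix(xyz, system)[key, ]
  if (any(is.na(ctr))) stop("missing atoms for bp ", bp_index)
  ctr
}

#' Count unwrapped base pairs from each DNA end
#'
#' A core base pair is displaced when its center deviates more than
#' `threshold` (7 Angstrom by default) from the corresponding base pair of
#' the reference structure, after superposition on the histone core.
#' Unwrapped base pairs are counted from each end of the nucleosomal
#' (core) DNA inward as the longest contiguous displaced run: counting
#' stops at the first non-displaced bp, so isolated interior displacements
#' do not count. Linker bp are ignored.
#'
#' @param frame a frame from [get_frame()] on a superposed ensemble
#' @param system [nucleosome_system()]
#' @param threshold displacement threshold in Angstrom (> 0)
#' @return integer vector `c(entry = ..., exit = ...)`; entry is the
#'   bp -73 end, exit the bp +73 end
#' @export
count_unwrapped <- function(frame, system, threshold = 7) {
  if (!isTRUE(frame$superposed))
    stop("frame must come from a superposed ensemble; displacement from ",
         "the reference is undefined otherwise")
  stopifnot(threshold > 0)
  disp <- .bp_displacement(frame$xyz, system)
  .count_ends(disp > threshold, system)
}

# per-bp center displacement from reference, core bp only, ordered -73..+73
.bp_displacement <- function(xyz, system) {
  half <- attr(system$dna, "core_half")
  core <- abs(system$dna$bp_index) <= half
  d <- bp_center_matrix(xyz, system)[core, , drop = FALSE] -
    bp_center_matrix(system$xyz, system)[core, , drop = FALSE]
  sqrt(rowSums(d * d))
}

.count_ends <- function(displaced, system) {
  n <- length(displaced)
  entry <- if (displaced[1L]) {
    r <- rle(displaced)
    r$lengths[1L]
  } else 0L
  exit <- if (displaced[n]) {
    r <- rle(rev(displaced))
    r$lengths[1L]
  } else 0L
  half <- (n - 1L) %/% 2L
  c(entry = min(as.integer(entry), half), exit = min(as.integer(exit), half))
}

#' Per-frame unwrapped-bp counts for an ensemble
#'
#' Vectorized application of [count_unwrapped()] to every frame.
#'
#' @param ensemble superposed [ensemble()]
#' @param system [nucleosome_system()]
#' @param threshold displacement threshold, Angstrom
#' @return object of class `unwrap_series`: data frame with columns
#'   `time`, `entry`, `exit`, `total`; attributes `run_id` and `threshold`
#' @export
unwrap_series <- function(ensemble, system, threshold = 7) {
  if (!isTRUE(ensemble$superposed))
    stop("ensemble must be superposed before unwrap analysis")
  stopifnot(threshold > 0)
  half <- attr(system$dna, "core_half")
  core <- abs(system$dna$bp_index) <= half
  map <- system$bp_atom_map[core, , drop = FALSE]
  ref <- bp_center_matrix(system$xyz, system)[core, , drop = FALSE]
  n_core <- nrow(map)
  nf <- nrow(ensemble$xyz)
  # displacement matrix frames x core bp, built columnwise
  a1 <- map[, 1L]; a2 <- map[, 2L]
  D2 <- matrix(0, nf, n_core)
  for (d in 0:2) {
    c1 <- ensemble$xyz[, 3L * (a1 - 1L) + 1L + d, drop = FALSE]
    two <- !is.na(a2)
    if (any(two)) {
      c2 <- ensemble$xyz[, 3L * (a2[two] - 1L) + 1L + d, drop = FALSE]
      c1[, two] <- (c1[, two, drop = FALSE] + c2) / 2
    }
    D2 <- D2 + sweep(c1, 2L, ref[, d + 1L])^2
  }
  disp <- sqrt(D2) > threshold
  # contiguous run from each end: first FALSE position caps the count
  first_false <- max.col(!disp, ties.method = "first")
  entry <- ifelse(rowSums(!disp) == 0L, n_core,
                  ifelse(disp[, 1L], first_false - 1L, 0L))
  rdisp <- disp[, n_core:1L, drop = FALSE]
  first_false_r <- max.col(!rdisp, ties.method = "first")
  exit <- ifelse(rowSums(!rdisp) == 0L, n_core,
                 ifelse(rdisp[, 1L], first_false_r - 1L, 0L))
  # each side is counted from its end up to the dyad at most
  entry <- pmin(entry, (n_core - 1L) %/% 2L)
  exit <- pmin(exit, (n_core - 1L) %/% 2L)
  out <- data.frame(time = ensemble$times,
                    entry = as.integer(entry), exit = as.integer(exit))
  out$total <- out$entry + out$exit
  attr(out, "run_id") <- ensemble$run_id
  attr(out, "threshold") <- threshold
  class(out) <- c("unwrap_series", "data.frame")
  out
}

#' Radius of gyration of a selection
#'
#' `Rg = sqrt( sum w_i |r_i - rbar|^2 / sum w_i )` with weights equal to
#' atomic masses when `mass_weighted = TRUE`, unit weights otherwise.
#'
#' @param frame frame (from [get_frame()]) or xyz numeric vector
#' @param system [nucleosome_system()]
#' @param selection integer atom indices
#' @param mass_weighted use `system$atoms$mass` as weights
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(frame, system, selection,
                               mass_weighted = TRUE) {
  if (length(selection) == 0L) stop("empty selection")
  xyz <- if (is.list(frame)) frame$xyz else frame
  m <- matrix(xyz, ncol = 3L, byrow = TRUE)[selection, , drop = FALSE]
  w <- if (mass_weighted) system$atoms$mass[selection] else
    rep(1, length(selection))
  cen <- colSums(m * w) / sum(w)
  d2 <- rowSums(sweep(m, 2L, cen)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Per-frame DNA radius of gyration
#'
#' @param ensemble [ensemble()]
#' @param system [nucleosome_system()]
#' @param selection atom indices; default all DNA atoms
#' @param mass_weighted weight by atomic mass
#' @return numeric vector, one Rg per frame (Angstrom)
#' @export
rg_series <- function(ensemble, system,
                      selection = which(system$atoms$role == "dna"),
                      mass_weighted = TRUE) {
  if (length(selection) == 0L) stop("empty selection")
  w <- if (mass_weighted) system$atoms$mass[selection] else
    rep(1, length(selection))
  w <- w / sum(w)
  # Rg^2 = sum_d [ E_w(x_d^2) - E_w(x_d)^2 ], vectorized over frames
  rg2 <- 0
  for (d in 0:2) {
    Xd <- ensemble$xyz[, 3L * (selection - 1L) + 1L + d, drop = FALSE]
    m1 <- Xd %*% w
    m2 <- (Xd * Xd) %*% w
    rg2 <- rg2 + (m2 - m1 * m1)
  }
  sqrt(pmax(as.numeric(rg2), 0))
}

#' Gaping distance between opposite superhelical half-turns
#'
#' Euclidean distance between the unweighted centroids of bp centers in
#' the windows `round(10.3 * n) +- window_bp` for the two SHLs of
#' `shl_pair` (default SHL -4 and +4). Gaping separates the two DNA gyres
#' along the superhelix axis, so this distance grows during gaping events.
#'
#' @param frame frame (from [get_frame()]) or xyz vector
#' @param system [nucleosome_system()]
#' @param shl_pair two integer SHLs (default `c(-4, 4)`)
#' @param window_bp window half-width in bp (default 2)
#' @param pitch bp per superhelical turn
#' @return distance in Angstrom
#' @export
gaping_distance <- function(frame, system, shl_pair = c(-4, 4),
                            window_bp = 2L, pitch = 10.3) {
  xyz <- if (is.list(frame)) frame$xyz else frame
  half <- attr(system$dna, "core_half")
  ctr <- bp_center_matrix(xyz, system)
  cents <- lapply(shl_pair, function(n) {
    win <- shl_window(n, pitch, window_bp)
    if (any(abs(win) > half))
      stop("SHL ", n, " window extends outside the DNA core")
    colMeans(ctr[as.character(win), , drop = FALSE])
  })
  sqrt(sum((cents[[1L]] - cents[[2L]])^2))
}

#' Per-frame gaping distances for an ensemble
#'
#' @inheritParams gaping_distance
#' @param ensemble [ensemble()]
#' @return object of class `gaping_series`: data frame with `time` and
#'   `distance`; attributes record the bp windows used
#' @export
gaping_series <- function(ensemble, system, shl_pair = c(-4, 4),
                          window_bp = 2L, pitch = 10.3) {
  half <- attr(system$dna, "core_half")
  wins <- lapply(shl_pair, function(n) {
    win <- shl_window(n, pitch, window_bp)
    if (any(abs(win) > half))
      stop("SHL ", n, " window extends outside the DNA core")
    win
  })
  map <- system$bp_atom_map
  cent_cols <- function(win) {
    # centroid coordinate columns for a bp window, per frame
    keys <- as.character(win)
    a1 <- map[keys, 1L]; a2 <- map[keys, 2L]
    sapply(0:2, function(d) {
      c1 <- ensemble$xyz[, 3L * (a1 - 1L) + 1L + d, drop = FALSE]
      two <- !is.na(a2)
      if (any(two)) {
        c2 <- ensemble$xyz[, 3L * (a2[two] - 1L) + 1L + d, drop = FALSE]
        c1[, two] <- (c1[, two, drop = FALSE] + c2) / 2
      }
      rowMeans(c1)
    })
  }
  d <- cent_cols(wins[[1L]]) - cent_cols(wins[[2L]])
  out <- data.frame(time = ensemble$times, distance = sqrt(rowSums(d * d)))
  attr(out, "windows") <- wins
  class(out) <- c("gaping_series", "data.frame")
  out
}

#' Project DNA base-pair centers onto the reference nucleosome plane
#'
#' The projection plane is fixed from the reference structure (normal =
#' reference superhelix axis through the reference DNA centroid) and is not
#' refit per frame, so unwrapping excursions read as outward motion in the
#' plane.
#'
#' @param frame frame from [get_frame()] on a superposed ensemble
#' @param system [nucleosome_system()]
#' @return matrix `n_bp x 2` of in-plane coordinates (Angstrom), rows
#'   named by bp index
#' @export
project_dna_2d <- function(frame, system) {
  if (!isTRUE(frame$superposed))
    stop("frame must come from a superposed ensemble")
  ctr <- bp_center_matrix(frame$xyz, system)
  rel <- sweep(ctr, 2L, system$plane$center)
  out <- rel %*% system$plane$basis
  colnames(out) <- c("x", "y")
  out
}
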