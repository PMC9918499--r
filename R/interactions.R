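# hydrogen detection from PDB-style atom names: H, 1H.., 2H.., HB2, ...
.is_hydrogen <- function(elety) {
  grepl("^[0-9]*H", trimws(elety))
}

.sel_coords <- function(xyz, selection) {
  matrix(xyz, ncol = 3L, byrow = TRUE)[selection, , drop = FALSE]
}

#' Count heavy-atom contacts between two selections
#'
#' A contact is a pair of non-hydrogen atoms, one from each selection,
#' strictly closer than `cutoff` (4.5 Angstrom by default). Hydrogens in a
#' selection are dropped with a warning. The cell-list accelerated kernel
#' is exactly equivalent to the all-pairs definition.
#'
#' @param frame frame (from [get_frame()]) or xyz numeric vector
#' @param system [nucleosome_system()]
#' @param selection_a,selection_b disjoint integer atom index vectors
#' @param cutoff contact cutoff, Angstrom (strict `<`)
#' @return integer contact count
#' @export
count_contacts <- function(frame, system, selection_a, selection_b,
                           cutoff = 4.5) {
  if (length(intersect(selection_a, selection_b)))
    stop("selections overlap; contacts are defined between disjoint sets")
  h_a <- .is_hydrogen(system$atoms$elety[selection_a])
  h_b <- .is_hydrogen(system$atoms$elety[selection_b])
  if (any(h_a) || any(h_b)) {
    warning("hydrogens removed from contact selections")
    selection_a <- selection_a[!h_a]
    selection_b <- selection_b[!h_b]
  }
  if (!length(selection_a) || !length(selection_b)) return(0L)
  xyz <- if (is.list(frame)) frame$xyz else frame
  .contact_count_cpp(.sel_coords(xyz, selection_a),
                     .sel_coords(xyz, selection_b), cutoff)
}

#' Atom indices of a DNA region
#'
#' @param system [nucleosome_system()]
#' @param region `"total"`, `"inner"`, `"outer"`, `"linker"`, or an
#'   integer vector of bp indices (an explicit bp window)
#' @return integer atom indices
#' @export
dna_region_atoms <- function(system, region = "total") {
  at <- system$atoms
  dna <- at$role == "dna"
  if (is.numeric(region)) return(which(dna & at$bp_index %in% region))
  region <- match.arg(region, c("total", "inner", "outer", "linker"))
  if (region == "total") return(which(dna))
  reg_of <- system$dna$region[match(at$bp_index, system$dna$bp_index)]
  which(dna & reg_of == region)
}

#' Atom indices of a histone tail
#'
#' @param system [nucleosome_system()]
#' @param chain chain identifier
#' @param which `"N"` or `"C"` terminal tail
#' @return integer atom indices
#' @export
tail_atoms <- function(system, chain, which = c("N", "C")) {
  which <- match.arg(which)
  hc <- system$chains[[chain]]
  if (is.null(hc)) stop("unknown chain: ", chain)
  rng <- if (which == "N") hc$n_tail else hc$c_tail
  if (is.null(rng)) stop("chain ", chain, " has no ", which, "-terminal tail")
  at <- system$atoms
  out <- base::which(at$chain == chain & at$role == "tail" &
                       at$resno >= rng[1L] & at$resno <= rng[2L])
  if (!length(out)) stop("empty tail range for chain ", chain)
  out
}

#' Per-frame tail-DNA contact counts
#'
#' @param ensemble [ensemble()]
#' @param system [nucleosome_system()]
#' @param chain histone chain identifier
#' @param which `"N"` or `"C"` tail
#' @param dna_region region name or bp window, see [dna_region_atoms()]
#' @param cutoff contact cutoff, Angstrom
#' @return object of class `contact_series`: data frame with `time` and
#'   `contacts`; attributes record the selections and cutoff
#' @export
tail_dna_contact_series <- function(ensemble, system, chain,
                                    which = c("N", "C"),
                                    dna_region = "total", cutoff = 4.5) {
  which <- match.arg(which)
  sel_t <- tail_atoms(system, chain, which)
  sel_d <- dna_region_atoms(system, dna_region)
  nf <- nrow(ensemble$xyz)
  counts <- integer(nf)
  for (f in seq_len(nf))
    counts[f] <- count_contacts(ensemble$xyz[f, ], system, sel_t, sel_d,
                                cutoff)
  out <- data.frame(time = ensemble$times, contacts = counts)
  attr(out, "tail") <- paste0(chain, ":", which)
  attr(out, "dna_region") <- dna_region
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_series", "data.frame")
  out
}

#' Savitzky-Golay smoothing of an observable time series
#'
#' Local least-squares polynomial smoothing with a window of `window_ns`
#' nanoseconds (101 points for a 10 ns window at 100 ps sampling) and
#' polynomial order `poly_order` (1 by default). Edges are handled by
#' shrinking the window symmetrically, so output length equals input
#' length and a degree-`poly_order` signal is reproduced exactly.
#'
#' @param series numeric vector, or a data frame whose second column is
#'   the observable (e.g. a `contact_series`)
#' @param window_ns window width, ns
#' @param poly_order polynomial order
#' @param sampling_interval ps between points
#' @return smoothed numeric vector (or the input data frame with the
#'   observable column replaced)
#' @export
smooth_series <- function(series, window_ns = 10, poly_order = 1,
                          sampling_interval = 100) {
  if (is.data.frame(series)) {
    out <- series
    out[[2L]] <- smooth_series(series[[2L]], window_ns, poly_order,
                               sampling_interval)
    return(out)
  }
  x <- as.numeric(series)
  n <- length(x)
  k <- round(window_ns * 1000 / sampling_interval / 2)
  npts <- 2L * k + 1L
  if (npts < poly_order + 2L)
    stop("window too short for polynomial order ", poly_order)
  if (n < npts)
    stop("series (", n, " points) shorter than the smoothing window (",
         npts, " points)")
  # convolution weights: first row of (X'X)^-1 X' for the centered window
  sg_weights <- function(h, deg) {
    t <- seq.int(-h, h)
    X <- outer(t, 0:deg, `^`)
    (solve(crossprod(X), t(X)))[1L, ]
  }
  out <- as.numeric(stats::filter(x, sg_weights(k, poly_order),
                                  sides = 2L))
  for (i in seq_len(k)) {
    h <- i - 1L
    deg <- min(poly_order, max(0L, 2L * h - 1L))
    if (h == 0L) {
      out[i] <- x[i]
      out[n - i + 1L] <- x[n - i + 1L]
    } else {
      w <- sg_weights(h, deg)
      out[i] <- sum(w * x[(i - h):(i + h)])
      j <- n - i + 1L
      out[j] <- sum(w * x[(j - h):(j + h)])
    }
  }
  out
}

#' Minimum tail-DNA heavy-atom distance
#'
#' Minimum distance between the heavy atoms of a histone tail and those of
#' a DNA bp window (by default the wrapped-end segment bp 41..75 on the
#' tail copy's proximal side, spanning core and linker).
#'
#' @param frame frame (from [get_frame()]) or xyz vector
#' @param system [nucleosome_system()]
#' @param chain histone chain identifier
#' @param which `"N"` or `"C"` tail
#' @param bp_window integer bp indices; `NULL` picks 41..75 signed by the
#'   proximal side of the tail's copy (copy 1 entry side, copy 2 exit side)
#' @return minimum distance, Angstrom
#' @export
tail_dna_min_distance <- function(frame, system, chain,
                                  which = c("N", "C"), bp_window = NULL) {
  which <- match.arg(which)
  sel_t <- tail_atoms(system, chain, which)
  if (is.null(bp_window)) {
    side <- if (system$chains[[chain]]$copy_index == 1L) -1L else 1L
    bp_window <- side * seq.int(41L, 75L)
  }
  sel_d <- dna_region_atoms(system, bp_window)
  if (!length(sel_d)) stop("empty DNA bp window")
  xyz <- if (is.list(frame)) frame$xyz else frame
  .min_pair_distance_cpp(.sel_coords(xyz, sel_t), .sel_coords(xyz, sel_d))
}

#' Pearson correlation between two observable series
#'
#' Computed on the raw (unsmoothed) series; smoothing is for plots only.
#'
#' @param series_a,series_b numeric vectors (or data frames whose second
#'   column is the observable) of equal length >= 3
#' @return Pearson r
#' @export
series_correlation <- function(series_a, series_b) {
  a <- if (is.data.frame(series_a)) series_a[[2L]] else as.numeric(series_a)
  b <- if (is.data.frame(series_b)) series_b[[2L]] else as.numeric(series_b)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 points")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance series: correlation undefined")
  cor(a, b)
}
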