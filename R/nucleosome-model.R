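#' Default tail ranges for histone variants
#'
#' N- and C-terminal tail residue intervals (1-based, including the
#' initiator methionine) for the histone variants the package knows about.
#' H2A: N-tail 1-16, C-tail 121-130. H2A.Z: N-tail 1-18, C-tail 123-128.
#' Other histone types default to no annotated tails; override via the
#' topology specification.
#'
#' @param variant_id one of "H2A", "H2A.Z", "H2B", "H3", "H3.3", "H4"
#' @return list with elements `n_tail` and `c_tail`, each an integer
#'   interval `c(first, last)` or `NULL`
#' @export
default_tail_ranges <- function(variant_id) {
  switch(variant_id,
    "H2A"   = list(n_tail = c(1L, 16L), c_tail = c(121L, 130L)),
    "H2A.Z" = list(n_tail = c(1L, 18L), c_tail = c(123L, 128L)),
    list(n_tail = NULL, c_tail = NULL)
  )
}

.known_variants <- c("H2A", "H2A.Z", "H2B", "H3", "H3.3", "H4")

#' Construct a histone chain description
#'
#' @param variant_id histone variant, one of `"H2A"`, `"H2A.Z"`, `"H2B"`,
#'   `"H3"`, `"H3.3"`, `"H4"`
#' @param copy_index copy number within the octamer (1 or 2)
#' @param n_residues total residue count of the chain
#' @param n_tail,c_tail residue intervals `c(first, last)` or `NULL`;
#'   defaults from [default_tail_ranges()]
#' @param core_annotations named list of secondary-structure elements
#'   (e.g. `alpha1`, `alpha2`, `alpha3`, `alphaC`, `L1`, `L2`), each a
#'   residue interval `c(first, last)`. Must be disjoint from the tails.
#' @return object of class `histone_chain`
#' @export
histone_chain <- function(variant_id, copy_index, n_residues,
                          n_tail = NULL, c_tail = NULL,
                          core_annotations = list()) {
  if (!variant_id %in% .known_variants)
    stop("unknown histone variant: ", variant_id)
  if (!copy_index %in% c(1L, 2L))
    stop("copy_index must be 1 or 2")
  defaults <- default_tail_ranges(variant_id)
  if (is.null(n_tail)) n_tail <- defaults$n_tail
  if (is.null(c_tail)) c_tail <- defaults$c_tail
  span <- function(r) if (is.null(r)) integer(0) else seq.int(r[1], r[2])
  used <- c(span(n_tail), span(c_tail))
  for (el in names(core_annotations)) {
    r <- span(core_annotations[[el]])
    if (any(r %in% used))
      stop("core element ", el, " overlaps tails or another element")
    used <- c(used, r)
  }
  if (length(used) && (min(used) < 1L || max(used) > n_residues))
    stop("tail/core annotations outside residue span 1..", n_residues)
  structure(
    list(variant_id = variant_id, copy_index = as.integer(copy_index),
         n_residues = as.integer(n_residues),
         n_tail = n_tail, c_tail = c_tail,
         core_annotations = core_annotations),
    class = "histone_chain"
  )
}

#' Construct the nucleosomal DNA duplex description
#'
#' Dyad-centered base-pair indexing: core bp span -73..+73 (147 bp) with the
#' dyad at 0; linker bp occupy +-74..+-93 (20 bp per linker).
#'
#' @param core_bp core base pairs (default 147, must be odd)
#' @param linker_bp base pairs per linker (default 20)
#' @param inner_outer_boundary |bp| at which the `inner` region ends and
#'   `outer` begins (default 37, about SHL 3.5)
#' @param bases optional character vector of base identities for strand 1,
#'   length `core_bp + 2 * linker_bp`, 5' to 3'
#' @return object of class `dna_duplex`: data frame with columns
#'   `bp_index`, `base1`, `base2`, `region`
#' @export
dna_duplex <- function(core_bp = 147L, linker_bp = 20L,
                       inner_outer_boundary = 37L, bases = NULL) {
  if (core_bp %% 2L != 1L) stop("core_bp must be odd (dyad-centered)")
  half <- (core_bp - 1L) %/% 2L
  idx <- seq.int(-half - linker_bp, half + linker_bp)
  n <- length(idx)
  if (is.null(bases)) bases <- rep("N", n)
  if (length(bases) != n) stop("bases must have length ", n)
  comp <- c(A = "T", T = "A", G = "C", C = "G", N = "N")
  region <- classify_region(idx, core_half = half,
                            inner_outer_boundary = inner_outer_boundary,
                            linker_bp = linker_bp)
  out <- data.frame(bp_index = idx, base1 = bases,
                    base2 = unname(comp[bases]), region = region,
                    stringsAsFactors = FALSE)
  attr(out, "core_half") <- half
  attr(out, "linker_bp") <- as.integer(linker_bp)
  attr(out, "inner_outer_boundary") <- as.integer(inner_outer_boundary)
  class(out) <- c("dna_duplex", "data.frame")
  out
}

#' Superhelical location of a base pair
#'
#' Continuous, signed SHL coordinate: the bp index divided by the
#' superhelical pitch (10.3 bp per turn by default). Integer SHL n
#' corresponds to the bp window `round(10.3 * n) +- 2` (see [shl_window()]).
#'
#' @param bp_index integer dyad-centered bp index (vectorized)
#' @param pitch bp per superhelical turn
#' @param span maximum |bp_index| accepted (default 93, core + linkers)
#' @return numeric SHL value(s)
#' @export
#' @examples
#' assign_shl(0)    # 0, the dyad
#' assign_shl(41)   # ~ +4
assign_shl <- function(bp_index, pitch = 10.3, span = 93L) {
  if (any(abs(bp_index) > span))
    stop("bp_index outside DNA span -", span, "..+", span)
  bp_index / pitch
}

#' Base-pair window of an integer superhelical location
#'
#' @param n integer SHL
#' @param pitch bp per turn
#' @param half_width window half-width in bp (default 2)
#' @return integer vector of bp indices `round(pitch * n) +- half_width`
#' @export
shl_window <- function(n, pitch = 10.3, half_width = 2L) {
  ctr <- round(pitch * n)
  seq.int(ctr - half_width, ctr + half_width)
}

#' Classify base pairs into inner, outer and linker DNA regions
#'
#' `linker` for |bp| beyond the core; `outer` for
#' `inner_outer_boundary <= |bp| <= core_half`; `inner` otherwise.
#'
#' @param bp_index integer bp index (vectorized)
#' @param core_half half-width of the core (default 73)
#' @param inner_outer_boundary boundary |bp| between inner and outer
#' @param linker_bp linker length, used only for the span check
#' @return character vector in `c("inner", "outer", "linker")`
#' @export
classify_region <- function(bp_index, core_half = 73L,
                            inner_outer_boundary = 37L, linker_bp = 20L) {
  span <- core_half + linker_bp
  if (any(abs(bp_index) > span))
    stop("bp_index outside DNA span -", span, "..+", span)
  a <- abs(bp_index)
  ifelse(a > core_half, "linker",
         ifelse(a >= inner_outer_boundary, "outer", "inner"))
}

#' Map dyad-centered bp indices to 1-based sequential numbering
#'
#' Sequential position 1 is the first bp of the entry linker (bp -93 for
#' the default duplex).
#' @param bp_index dyad-centered index (vectorized)
#' @param span maximum |bp_index| (93 by default)
#' @return integer sequential position
#' @export
bp_to_seq <- function(bp_index, span = 93L) as.integer(bp_index + span + 1L)

#' @rdname bp_to_seq
#' @param seq_pos 1-based sequential position
#' @export
seq_to_bp <- function(seq_pos, span = 93L) as.integer(seq_pos - span - 1L)

#' Construct a nucleosome system
#'
#' Couples the topology (histone chains and DNA duplex) with reference
#' coordinates and an atom table that maps every atom to either a histone
#' residue or a DNA base pair.
#'
#' @param chains named list of [histone_chain()] objects; names are chain
#'   identifiers as used in coordinate files
#' @param dna [dna_duplex()] object
#' @param atoms data frame with one row per atom and columns `eleno`,
#'   `elety` (atom name), `chain`, `resno`, `role` (`"dna"`, `"core"`,
#'   `"tail"`), `bp_index` (NA for histone atoms), `strand` (1, 2 or NA),
#'   `element` (secondary-structure element for core atoms, NA otherwise)
#'   and `mass`
#' @param xyz reference coordinates, numeric vector of length
#'   `3 * nrow(atoms)` in bio3d order (x1, y1, z1, x2, ...), Angstrom
#' @return object of class `nucleosome_system`
#' @export
nucleosome_system <- function(chains, dna, atoms, xyz) {
  stopifnot(is.list(chains), inherits(dna, "dna_duplex"),
            is.data.frame(atoms))
  need <- c("eleno", "elety", "chain", "resno", "role", "bp_index",
            "strand", "element", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (length(xyz) != 3L * nrow(atoms))
    stop("xyz length ", length(xyz), " != 3 * ", nrow(atoms), " atoms")
  if (any(!is.finite(xyz))) stop("non-finite reference coordinates")
  isdna <- atoms$role == "dna"
  if (any(is.na(atoms$bp_index[isdna])))
    stop("DNA atoms must carry bp_index")
  if (any(!is.na(atoms$bp_index) & !isdna))
    stop("non-DNA atoms must not carry bp_index")
  bad <- setdiff(atoms$chain[!isdna], names(chains))
  if (length(bad)) stop("atoms reference unknown histone chain(s): ",
                        paste(unique(bad), collapse = ", "))
  sys <- structure(
    list(chains = chains, dna = dna, atoms = atoms, xyz = as.numeric(xyz)),
    class = "nucleosome_system"
  )
  sys$bp_atom_map <- .bp_atom_map(sys)
  sys$plane <- .reference_plane(sys)
  sys
}

#' @export
print.nucleosome_system <- function(x, ...) {
  cat("nucleosome_system:", length(x$chains), "histone chains,",
      nrow(x$dna), "bp duplex,", nrow(x$atoms), "atoms\n")
  invisible(x)
}

# For each bp, the atom indices used for its center: one bead, or the two
# C1' atoms of the paired nucleotides.
.bp_atom_map <- function(sys) {
  at <- sys$atoms
  dna <- which(at$role == "dna")
  map <- matrix(NA_integer_, nrow = nrow(sys$dna), ncol = 2L)
  rownames(map) <- as.character(sys$dna$bp_index)
  for (k in dna) {
    key <- as.character(at$bp_index[k])
    s <- at$strand[k]
    col <- if (!is.na(s) && s == 2L) 2L else 1L
    cur <- map[key, col]
    # prefer the C1' atom for the bp center; fall back to any bead/atom
    if (is.na(cur) || isTRUE(at$elety[k] %in% c("C1'", "C1*")))
      map[key, col] <- k
  }
  map
}

# Reference nucleosome plane: the plane normal (superhelix axis) is the
# smallest principal axis of the core bp-center cloud; the in-plane origin
# is the axis position, recovered by a least-squares (Kasa) circle fit of
# the projected core bp centers, so projected radial distances read as
# distances from the superhelix axis.
.reference_plane <- function(sys) {
  ctr <- bp_center_matrix(sys$xyz, sys)
  core <- abs(sys$dna$bp_index) <= attr(sys$dna, "core_half")
  p <- ctr[core, , drop = FALSE]
  p <- p[stats::complete.cases(p), , drop = FALSE]
  cen <- colMeans(p)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  circle_fit <- function(uv) {
    A <- cbind(2 * uv[, 1L], 2 * uv[, 2L], 1)
    tryCatch(qr.solve(A, rowSums(uv^2))[1:2], error = function(e) c(0, 0))
  }
  plane_of <- function(u) {
    u <- u / sqrt(sum(u^2))
    qr.Q(qr(cbind(u, diag(3))))[, 2:3, drop = FALSE]
  }
  # PCA gives a biased axis for a non-integer number of turns; refine by a
  # cylinder fit (minimal spread of radial distances about the fitted circle)
  base <- ev$vectors
  radial_spread <- function(ab) {
    w <- sqrt(max(1 - sum(ab^2), 1e-6))
    u <- as.numeric(base %*% c(ab[1L], ab[2L], w))
    B <- plane_of(u)
    uv <- sweep(p, 2L, cen) %*% B
    ctr2 <- circle_fit(uv)
    r <- sqrt((uv[, 1L] - ctr2[1L])^2 + (uv[, 2L] - ctr2[2L])^2)
    sum((r - mean(r))^2)
  }
  ab <- c(0, 0)
  if (nrow(p) >= 6L)
    ab <- stats::optim(c(0, 0), radial_spread, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 500))$par
  w <- sqrt(max(1 - sum(ab^2), 1e-6))
  axis <- as.numeric(base %*% c(ab[1L], ab[2L], w))
  axis <- axis / sqrt(sum(axis^2))
  basis <- plane_of(axis)
  uv <- sweep(p, 2L, cen) %*% basis
  ctr2 <- circle_fit(uv)
  list(center = cen + as.numeric(basis %*% ctr2), axis = axis,
       basis = basis)
}

#' Read a topology specification file
#'
#' YAML key-value file describing chains (variant, copy, tail ranges,
#' core-element intervals) and the DNA duplex (chain ids, bp count, dyad
#' position in sequential numbering). Used by [load_structure()] to
#' interpret coordinate files, including non-default constructs such as
#' tail-swapped histones.
#'
#' @param path file path
#' @return list with components `chains` and `dna`
#' @export
read_topology_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$chains) || is.null(spec$dna))
    stop("topology spec must define 'chains' and 'dna'")
  spec
}

#' Write a topology specification file
#' @param spec list as returned by [read_topology_spec()]
#' @param path file path
#' @export
write_topology_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}
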