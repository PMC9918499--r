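#' Construct an ensemble of trajectory frames
#'
#' Frames are stored bio3d-style as a numeric matrix with one row per frame
#' and columns `(x1, y1, z1, x2, ...)`.
#'
#' @param xyz numeric matrix `n_frames x 3*n_atoms`
#' @param sampling_interval time between frames, ps
#' @param times frame times in ps; defaults to
#'   `0, sampling_interval, 2*sampling_interval, ...`
#' @param run_id label for the run
#' @param superposed whether frames are already expressed in the reference
#'   frame of the system
#' @return object of class `ensemble`
#' @export
ensemble <- function(xyz, sampling_interval, times = NULL, run_id = "run1",
                     superposed = FALSE) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) < 1L) stop("ensemble needs at least one frame")
  if (ncol(xyz) %% 3L != 0L) stop("xyz columns must be a multiple of 3")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1L) * sampling_interval
  if (length(times) != nrow(xyz)) stop("times length != frame count")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || any(abs(dt - dt[1L]) > 1e-6)))
    stop("frame times must increase with constant spacing")
  structure(
    list(xyz = xyz, times = as.numeric(times),
         sampling_interval = sampling_interval, run_id = run_id,
         superposed = superposed, fit_selection = NULL, rmsd = NULL),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble '%s': %d frames x %d atoms, dt = %g ps%s\n",
              x$run_id, nrow(x$xyz), ncol(x$xyz) %/% 3L,
              x$sampling_interval,
              if (isTRUE(x$superposed)) " (superposed)" else ""))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble [ensemble()]
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame of an ensemble
#'
#' @param ensemble [ensemble()]
#' @param i frame number
#' @return list with `time`, `xyz` (length 3*n_atoms) and `superposed`
#' @export
get_frame <- function(ensemble, i) {
  if (i < 1L || i > nrow(ensemble$xyz)) stop("frame index out of range")
  list(time = ensemble$times[i], xyz = ensemble$xyz[i, ],
       superposed = isTRUE(ensemble$superposed))
}

#' Load a nucleosome structure from a PDB or GRO file
#'
#' The topology specification maps file chains to histone variants and
#' identifies the DNA chain(s); 1-based sequential bp numbering in the file
#' is converted to dyad-centered indices.
#'
#' @param path PDB (`.pdb`) or GRO (`.gro`) file
#' @param topology_spec list (or path to a YAML file) as documented in
#'   [read_topology_spec()]
#' @return [nucleosome_system()]
#' @export
load_structure <- function(path, topology_spec) {
  if (is.character(topology_spec)) topology_spec <- read_topology_spec(topology_spec)
  ext <- tolower(tools::file_ext(path))
  at <- switch(ext,
    pdb = {
      pdb <- bio3d::read.pdb(path)
      data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                 resid = pdb$atom$resid, chain = pdb$atom$chain,
                 resno = pdb$atom$resno,
                 x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
                 stringsAsFactors = FALSE)
    },
    gro = read_gro(path),
    stop("unsupported structure format: .", ext)
  )
  .system_from_atoms(at, topology_spec)
}

.system_from_atoms <- function(at, spec) {
  dna_chains <- spec$dna$chains
  n_bp <- spec$dna$n_bp
  linker_bp <- if (!is.null(spec$dna$linker_bp)) spec$dna$linker_bp else 20L
  core_bp <- n_bp - 2L * linker_bp
  span <- (core_bp - 1L) %/% 2L + linker_bp
  boundary <- if (!is.null(spec$dna$inner_outer_boundary))
    spec$dna$inner_outer_boundary else 37L

  file_chains <- unique(at$chain)
  need <- c(names(spec$chains), dna_chains)
  missing_ch <- setdiff(need, file_chains)
  if (length(missing_ch))
    stop("structure file is missing chain(s): ",
         paste(missing_ch, collapse = ", "))

  chains <- list()
  rows <- list()
  for (ch in names(spec$chains)) {
    cs <- spec$chains[[ch]]
    sel <- at[at$chain == ch, , drop = FALSE]
    n_res <- max(sel$resno)
    ann <- lapply(cs$elements, function(r) as.integer(r))
    hc <- histone_chain(cs$variant, cs$copy, n_res,
                        n_tail = if (!is.null(cs$n_tail)) as.integer(cs$n_tail),
                        c_tail = if (!is.null(cs$c_tail)) as.integer(cs$c_tail),
                        core_annotations = ann)
    role <- rep("core", nrow(sel))
    in_range <- function(x, r) !is.null(r) && x >= r[1] & x <= r[2]
    if (!is.null(hc$n_tail))
      role[sel$resno >= hc$n_tail[1] & sel$resno <= hc$n_tail[2]] <- "tail"
    if (!is.null(hc$c_tail))
      role[sel$resno >= hc$c_tail[1] & sel$resno <= hc$c_tail[2]] <- "tail"
    element <- rep(NA_character_, nrow(sel))
    for (el in names(ann))
      element[sel$resno >= ann[[el]][1] & sel$resno <= ann[[el]][2]] <- el
    rows[[ch]] <- data.frame(
      eleno = sel$eleno, elety = sel$elety, chain = ch, resno = sel$resno,
      role = role, bp_index = NA_integer_, strand = NA_integer_,
      element = element, mass = 12.0, x = sel$x, y = sel$y, z = sel$z,
      stringsAsFactors = FALSE)
    chains[[ch]] <- hc
  }

  # DNA: one chain of beads (one atom/bp) or two antiparallel strands
  dyad_seq <- if (!is.null(spec$dna$dyad_seq)) spec$dna$dyad_seq else span + 1L
  for (k in seq_along(dna_chains)) {
    ch <- dna_chains[k]
    sel <- at[at$chain == ch, , drop = FALSE]
    seq_pos <- sel$resno
    if (k == 2L) seq_pos <- n_bp + 1L - seq_pos  # antiparallel partner strand
    bp <- as.integer(seq_pos - dyad_seq)
    if (any(abs(bp) > span))
      stop("DNA chain ", ch, " has residues outside the ", n_bp, " bp duplex")
    rows[[ch]] <- data.frame(
      eleno = sel$eleno, elety = sel$elety, chain = ch, resno = sel$resno,
      role = "dna", bp_index = bp, strand = as.integer(k),
      element = NA_character_, mass = 325.0, x = sel$x, y = sel$y, z = sel$z,
      stringsAsFactors = FALSE)
  }

  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$eleno), , drop = FALSE]
  rownames(atoms) <- NULL
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  atoms <- atoms[, setdiff(names(atoms), c("x", "y", "z"))]
  got_bp <- sort(unique(atoms$bp_index[atoms$role == "dna"]))
  want_bp <- seq.int(-span, span)
  if (!identical(got_bp, want_bp))
    stop("DNA bp indices incomplete: expected -", span, "..+", span)
  dna <- dna_duplex(core_bp = core_bp, linker_bp = linker_bp,
                    inner_outer_boundary = boundary)
  nucleosome_system(chains, dna, atoms, xyz)
}

#' Load a trajectory file into an ensemble
#'
#' Supported formats: DCD (CHARMM/NAMD style, read via bio3d) and
#' multi-model PDB. Times are assigned from `sampling_interval`; if the
#' file carries its own time metadata that disagrees, the file times win
#' with a warning.
#'
#' @param path trajectory file (`.dcd` or multi-model `.pdb`)
#' @param system [nucleosome_system()] the frames must match
#' @param sampling_interval time between frames, ps
#' @param run_id label for the run
#' @return [ensemble()]
#' @export
load_trajectory <- function(path, system, sampling_interval,
                            run_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  xyz <- switch(ext,
    dcd = unclass(bio3d::read.dcd(path, verbose = FALSE)),
    pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE)
      m <- pdb$xyz
      if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
      unclass(m)
    },
    stop("unsupported trajectory format: .", ext)
  )
  n_atoms <- nrow(system$atoms)
  if (ncol(xyz) != 3L * n_atoms)
    stop("trajectory atom count ", ncol(xyz) %/% 3L,
         " does not match system atom count ", n_atoms)
  ensemble(xyz, sampling_interval, run_id = run_id)
}

# Core C-alpha fit selection: atom indices of core atoms named CA on all
# histone chains, excluding the L1/L2 loops by default.
#' Default superposition selection: histone-core C-alpha atoms
#'
#' @param system [nucleosome_system()]
#' @param exclude_loops drop atoms annotated as L1/L2 loop elements
#' @return integer atom indices
#' @export
core_ca_selection <- function(system, exclude_loops = TRUE) {
  at <- system$atoms
  sel <- at$role == "core" & at$elety %in% c("CA", "CA ")
  if (exclude_loops)
    sel <- sel & !(at$element %in% c("L1", "L2"))
  which(sel)
}

#' Superpose ensemble frames on the reference structure
#'
#' Each frame is rigidly transformed (least-squares fit) to minimize the
#' RMSD of the selection against the reference coordinates, following the
#' usual histone-core C-alpha fitting convention.
#'
#' @param ensemble [ensemble()]
#' @param system [nucleosome_system()]
#' @param selection integer atom indices; defaults to
#'   [core_ca_selection()] of all histone chains
#' @return superposed [ensemble()] with per-frame fit RMSD in `$rmsd`
#' @export
superpose <- function(ensemble, system, selection = NULL) {
  if (is.null(selection)) selection <- core_ca_selection(system)
  if (length(selection) < 3L)
    stop("superposition needs at least 3 selection atoms")
  inds <- bio3d::atom2xyz(selection)
  fitted <- bio3d::fit.xyz(fixed = system$xyz, mobile = ensemble$xyz,
                           fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  d <- sweep(fitted[, inds, drop = FALSE], 2L, system$xyz[inds])
  rmsd <- sqrt(rowSums(d * d) / length(selection))
  out <- ensemble
  out$xyz <- unclass(fitted)
  out$superposed <- TRUE
  out$fit_selection <- selection
  out$rmsd <- as.numeric(rmsd)
  out
}

#' Remove equilibration frames from the start of an ensemble
#'
#' Frames with `time < t_cut_ns` are dropped. The input ensemble is left
#' untouched, so the untrimmed view remains available for time-evolution
#' plots.
#'
#' @param ensemble [ensemble()]
#' @param t_cut_ns equilibration cut, ns (default 200)
#' @return trimmed [ensemble()]
#' @export
trim_equilibration <- function(ensemble, t_cut_ns = 200) {
  if (t_cut_ns < 0) stop("t_cut_ns must be >= 0")
  keep <- ensemble$times >= t_cut_ns * 1000
  if (!any(keep))
    stop("t_cut_ns = ", t_cut_ns, " ns removes every frame")
  out <- ensemble
  out$xyz <- ensemble$xyz[keep, , drop = FALSE]
  out$times <- ensemble$times[keep]
  if (!is.null(out$rmsd)) out$rmsd <- out$rmsd[keep]
  out
}
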