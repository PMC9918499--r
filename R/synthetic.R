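#' Parameters for the synthetic nucleosome generator
#'
#' The generator builds a pseudo-atom nucleosome (one bead per DNA bp,
#' C-alpha-like beads for histone core elements, bead-string tails) and
#' evolves it with simple stochastic processes whose stationary behavior
#' is known exactly: a zipper model for end unwrapping (per-bp detachment
#' free energy `epsilon`, so the unwrapped count i is geometric with
#' `P(i) ~ exp(-i * epsilon / RT)`), a mean-reverting AR(1) gaping mode,
#' per-element harmonic jitter of core beads, and two-state tail binding
#' whose bound probability decreases with the unwrapped count.
#'
#' @param superhelix_radius superhelix radius, Angstrom
#' @param superhelix_pitch axial rise per superhelical turn, Angstrom
#' @param total_turns superhelical turns over the 147 bp core
#' @param core_bp,linker_bp DNA layout (147 core, 20 per linker)
#' @param bp_spacing bead spacing along the linkers, Angstrom; default is
#'   the core helical arc length per bp
#' @param epsilon per-bp unwrapping free energy, kcal/mol
#' @param temperature Kelvin
#' @param gaping_mean,gaping_amplitude,gaping_relaxation stationary mean
#'   (Angstrom), stationary standard deviation (Angstrom) and relaxation
#'   time (frames) of the AR(1) gaping distance
#' @param gaping_max_shift bound on the per-bp axial displacement of the
#'   gaping mode, Angstrom; kept below the 7 Angstrom unwrap threshold so
#'   that gaping never masquerades as unwrapping (rare AR(1) excursions
#'   are truncated and the truncated distance is recorded as ground truth)
#' @param core_sigma named per-element jitter (Angstrom per coordinate),
#'   names `helix` and `loop`
#' @param bind_p0,bind_coupling bound-state probability of a tail is
#'   `clamp(bind_p0 - bind_coupling * i, 0.05, 0.95)` with i the total
#'   unwrapped count
#' @param tail_bind_prob optional function of the total unwrapped count
#'   overriding the linear form above
#' @param bind_distance distance from a bound tail bead to its anchor DNA
#'   bead, Angstrom (must stay under the contact cutoff)
#' @param unwrap_displacement radial displacement of an unwrapped bp from
#'   its wrapped position, Angstrom (> 10 so labels are unambiguous)
#' @param noise_sigma isotropic Gaussian noise added to every coordinate
#'   after ground truth is recorded, Angstrom
#' @param n_frames number of frames
#' @param sampling_interval ps between frames (frames are abstract time)
#' @param rigid_motion apply a random rigid transform to every frame so
#'   that superposition is exercised
#' @param h2a_variant `"H2A"` or `"H2A.Z"` for the two H2A-family copies
#' @param seed integer seed fixing the full random stream
#' @return list of class `synthetic_params`
#' @export
synthetic_params <- function(superhelix_radius = 41.9,
                             superhelix_pitch = 25.9,
                             total_turns = 1.65,
                             core_bp = 147L, linker_bp = 20L,
                             bp_spacing = NULL,
                             epsilon = 0.5, temperature = 310,
                             gaping_mean = 27, gaping_amplitude = 1.5,
                             gaping_relaxation = 50,
                             gaping_max_shift = 5,
                             core_sigma = c(helix = 0.5, loop = 1.0),
                             bind_p0 = 0.9, bind_coupling = 0.08,
                             tail_bind_prob = NULL,
                             bind_distance = 3.5,
                             unwrap_displacement = 12,
                             noise_sigma = 0.5,
                             n_frames = 1000L,
                             sampling_interval = 100,
                             rigid_motion = TRUE,
                             h2a_variant = c("H2A", "H2A.Z"),
                             seed = 1L) {
  h2a_variant <- match.arg(h2a_variant)
  stopifnot(superhelix_radius > 0, superhelix_pitch > 0, total_turns > 0,
            gaping_mean > 0, gaping_amplitude > 0, gaping_relaxation > 0,
            bind_distance > 0, unwrap_displacement > 10, noise_sigma >= 0,
            gaping_max_shift > 0,
            epsilon >= 0, temperature > 0,
            bind_p0 >= 0, bind_p0 <= 1)
  if (is.null(bp_spacing)) {
    dtheta <- 2 * pi * total_turns / (core_bp - 1L)
    bp_spacing <- sqrt((superhelix_radius * dtheta)^2 +
                         (superhelix_pitch * dtheta / (2 * pi))^2)
  }
  if (is.null(tail_bind_prob))
    tail_bind_prob <- function(i) pmin(0.95, pmax(0.05, bind_p0 - bind_coupling * i))
  structure(as.list(environment()), class = "synthetic_params")
}

# chain layout: variant, residue spans of tails and core elements
.synthetic_chain_plan <- function(h2a_variant) {
  elements_from <- function(start) {
    list(alpha1 = c(start, start + 7L),
         L1 = c(start + 8L, start + 11L),
         alpha2 = c(start + 12L, start + 23L),
         L2 = c(start + 24L, start + 27L),
         alpha3 = c(start + 28L, start + 35L),
         alphaC = c(start + 36L, start + 39L))
  }
  plan <- list()
  ids <- c("A", "B", "C", "D", "E", "F", "G", "H")
  variants <- c(h2a_variant, h2a_variant, "H2B", "H2B", "H3", "H3", "H4", "H4")
  copies <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  for (k in seq_along(ids)) {
    v <- variants[k]
    tails <- default_tail_ranges(v)
    core_start <- if (is.null(tails$n_tail)) 31L else tails$n_tail[2L] + 1L
    n_res <- switch(v, "H2A" = 130L, "H2A.Z" = 128L, "H2B" = 126L,
                    "H3" = 136L, "H4" = 103L)
    plan[[ids[k]]] <- list(variant = v, copy = copies[k], n_res = n_res,
                           n_tail = tails$n_tail, c_tail = tails$c_tail,
                           elements = elements_from(core_start))
  }
  plan
}

#' Generate a pseudo-atom nucleosome reference structure
#'
#' DNA beads (one per bp) lie on a left-handed superhelix of
#' `total_turns` turns over the 147 bp core, with two straight 20-bp
#' linkers leaving tangentially. Core histone beads sit on an inner
#' cylinder, grouped into annotated helix/loop elements; H2A-family tail
#' beads are anchored near the DNA in a bound conformation (C-tails at the
#' DNA ends near SHL +-6.5, N-tails near SHL +-3.7).
#'
#' @param params [synthetic_params()]
#' @return [nucleosome_system()] with generator metadata in `$meta`
#' @export
generate_reference <- function(params) {
  p <- params
  half <- (p$core_bp - 1L) %/% 2L
  span <- half + p$linker_bp
  dtheta <- 2 * pi * p$total_turns / (p$core_bp - 1L)
  bp_index <- seq.int(-span, span)
  n_bp <- length(bp_index)

  dna <- matrix(NA_real_, n_bp, 3L)
  core_mask <- abs(bp_index) <= half
  th <- bp_index[core_mask] * dtheta
  dna[core_mask, ] <- cbind(p$superhelix_radius * cos(th),
                            -p$superhelix_radius * sin(th),
                            p$superhelix_pitch * th / (2 * pi))
  tangent_at <- function(i) {
    t <- i * dtheta
    v <- c(-p$superhelix_radius * sin(t),
           -p$superhelix_radius * cos(t),
           p$superhelix_pitch / (2 * pi))
    s <- sign(i)
    v <- v * s
    v / sqrt(sum(v^2))
  }
  for (side in c(-1, 1)) {
    tangent <- tangent_at(side * half)
    base <- dna[match(side * half, bp_index), ]
    for (k in seq_len(p$linker_bp)) {
      dna[match(side * (half + k), bp_index), ] <-
        base + k * p$bp_spacing * tangent
    }
  }

  plan <- .synthetic_chain_plan(p$h2a_variant)
  chains <- list()
  rows <- list()
  xyz_rows <- list()
  eleno <- 0L
  # anchors for bound tails, one per H2A-family tail
  anchor_for <- function(copy, which) {
    side <- if (copy == 1L) -1L else 1L
    if (which == "C") side * 67L else side * 38L
  }
  tail_meta <- list()
  for (k in seq_along(plan)) {
    ch <- names(plan)[k]
    cs <- plan[[k]]
    ann <- cs$elements
    hc <- histone_chain(cs$variant, cs$copy, cs$n_res,
                        n_tail = cs$n_tail, c_tail = cs$c_tail,
                        core_annotations = ann)
    chains[[ch]] <- hc
    phi <- 2 * pi * (k - 1) / length(plan) + 0.3
    core_res <- unlist(lapply(ann, function(r) seq.int(r[1L], r[2L])))
    core_res <- sort(core_res)
    m <- length(core_res)
    ang <- phi + 0.06 * seq_len(m)
    zz <- seq(-8, 8, length.out = m)
    core_xyz <- cbind(30 * cos(ang), -30 * sin(ang), zz)
    element <- rep(NA_character_, m)
    for (el in names(ann))
      element[core_res >= ann[[el]][1L] & core_res <= ann[[el]][2L]] <- el
    res_list <- data.frame(resno = core_res, role = "core",
                           element = element, stringsAsFactors = FALSE)
    xyz_list <- core_xyz
    is_h2a_family <- cs$variant %in% c("H2A", "H2A.Z")
    for (which in c("N", "C")) {
      rng <- if (which == "N") cs$n_tail else cs$c_tail
      if (is.null(rng) || !is_h2a_family) next
      res <- seq.int(rng[1L], rng[2L])
      L <- length(res)
      a0 <- anchor_for(cs$copy, which)
      step <- if (a0 < 0) 1L else -1L  # walk inward along the DNA
      abp <- a0 + step * (seq_len(L) - 1L)
      apos <- dna[match(abp, bp_index), , drop = FALSE]
      radial <- apos
      radial[, 3L] <- 0
      radial <- radial / sqrt(rowSums(radial^2))
      tail_xyz <- apos + p$bind_distance * radial
      res_list <- rbind(res_list,
                        data.frame(resno = res, role = "tail",
                                   element = NA_character_,
                                   stringsAsFactors = FALSE))
      xyz_list <- rbind(xyz_list, tail_xyz)
      tail_meta[[paste0(ch, ".", which)]] <-
        list(chain = ch, which = which, anchor_bp = abp,
             resno = res)
    }
    n_at <- nrow(res_list)
    rows[[ch]] <- data.frame(
      eleno = eleno + seq_len(n_at), elety = "CA", chain = ch,
      resno = res_list$resno, role = res_list$role,
      bp_index = NA_integer_, strand = NA_integer_,
      element = res_list$element, mass = 12.0, stringsAsFactors = FALSE)
    xyz_rows[[ch]] <- xyz_list
    eleno <- eleno + n_at
  }
  rows[["I"]] <- data.frame(
    eleno = eleno + seq_len(n_bp), elety = "C1'", chain = "I",
    resno = seq_len(n_bp), role = "dna", bp_index = bp_index,
    strand = 1L, element = NA_character_, mass = 325.0,
    stringsAsFactors = FALSE)
  xyz_rows[["I"]] <- dna

  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  xyz <- as.numeric(t(do.call(rbind, xyz_rows)))
  duplex <- dna_duplex(core_bp = p$core_bp, linker_bp = p$linker_bp)
  sys <- nucleosome_system(chains, duplex, atoms, xyz)

  # gaping geometry bookkeeping: in-plane and axial separation of the
  # SHL -4 / +4 measurement windows in the reference
  ctr <- bp_center_matrix(sys$xyz, sys)
  wctr <- function(n) colMeans(ctr[as.character(shl_window(n)), ])
  cm <- wctr(-4); cp <- wctr(4)
  inplane <- sqrt(sum((cm[1:2] - cp[1:2])^2))
  axial0 <- abs(cm[3] - cp[3])
  sys$meta <- list(params = p, tails = tail_meta,
                   gaping_inplane = inplane, gaping_axial0 = axial0,
                   gaping_bp_min = 31L, dna_atom_offset = eleno,
                   bp_index = bp_index, plan = plan)
  sys
}

# one Metropolis sweep of a zipper chain: propose i +- 1, accept detachment
# with probability exp(-epsilon/RT); stationary law P(i) ~ exp(-i eps/RT)
.zipper_step <- function(i, q, imax, u_prop, u_acc) {
  di <- if (u_prop < 0.5) 1L else -1L
  j <- i + di
  if (j < 0L || j > imax) return(i)
  if (di == 1L && u_acc >= q) return(i)
  j
}

#' Simulate a synthetic nucleosome trajectory with known ground truth
#'
#' Per frame: both DNA ends evolve by single-bp Metropolis zipper moves
#' (stationary law `P(i) ~ exp(-i*epsilon/RT)`); unwrapped bp leave the
#' superhelix radially by more than 10 Angstrom; the gaping distance
#' follows a mean-reverting AR(1) process realized as a rigid axial
#' displacement of the two outer half-turn regions; core beads jitter with
#' per-element sigma; tails toggle between a bound conformation (beads
#' within contact range of their anchor DNA beads) and an unbound one,
#' with bound probability coupled to the unwrapped count. Ground truth is
#' recorded before noise is added.
#'
#' @param params [synthetic_params()]
#' @param coordinates build frame coordinates (set `FALSE` for long runs
#'   where only the ground-truth observables are needed)
#' @return list with components `system` ([nucleosome_system()]),
#'   `ensemble` ([ensemble()] or `NULL` when `coordinates = FALSE`) and
#'   `truth` (`ground_truth` data frame, one row per frame)
#' @export
simulate_trajectory <- function(params, coordinates = TRUE) {
  p <- params
  if (p$n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(p$seed)
  sys <- generate_reference(p)
  half <- (p$core_bp - 1L) %/% 2L
  RT <- rt_kcal(p$temperature)
  q <- exp(-p$epsilon / RT)
  nf <- p$n_frames

  # zipper states for the two ends
  entry <- integer(nf); exit <- integer(nf)
  u1 <- runif(nf); a1 <- runif(nf); u2 <- runif(nf); a2 <- runif(nf)
  ie <- 0L; ix <- 0L
  for (f in seq_len(nf)) {
    ie <- .zipper_step(ie, q, half, u1[f], a1[f])
    ix <- .zipper_step(ix, q, half, u2[f], a2[f])
    entry[f] <- ie; exit[f] <- ix
  }

  # AR(1) gaping distance, clamped above the in-plane window separation
  phi <- exp(-1 / p$gaping_relaxation)
  innov <- rnorm(nf, 0, p$gaping_amplitude * sqrt(1 - phi^2))
  g <- numeric(nf)
  gmin <- sys$meta$gaping_inplane + 0.5
  gcur <- max(rnorm(1, p$gaping_mean, p$gaping_amplitude), gmin)
  for (f in seq_len(nf)) {
    gcur <- p$gaping_mean + phi * (gcur - p$gaping_mean) + innov[f]
    if (gcur < gmin) gcur <- gmin
    g[f] <- gcur
  }
  # realize gaping as a rigid axial shift bounded below the unwrap
  # threshold; the realized (possibly truncated) distance is ground truth
  ip2_ <- sys$meta$gaping_inplane^2
  delta_all <- sqrt(pmax(g^2 - ip2_, 0)) - sys$meta$gaping_axial0
  delta_all <- pmin(pmax(delta_all, -2 * p$gaping_max_shift),
                    2 * p$gaping_max_shift)
  g <- sqrt(ip2_ + (sys$meta$gaping_axial0 + delta_all)^2)

  # tail binding states
  tails <- sys$meta$tails
  nt <- length(tails)
  total <- entry + exit
  pbind <- p$tail_bind_prob(total)
  bound <- matrix(rbinom(nf * nt, 1L, rep(pbind, nt)), nf, nt)
  colnames(bound) <- names(tails)
  tail_len <- vapply(tails, function(t) length(t$resno), integer(1))
  contacts_floor <- sweep(bound, 2L, tail_len, `*`)

  # core jitter sigmas per atom
  at <- sys$atoms
  is_core <- at$role == "core"
  sig_el <- ifelse(at$element[is_core] %in% c("L1", "L2"),
                   p$core_sigma[["loop"]], p$core_sigma[["helix"]])
  elements <- unique(at$element[is_core])
  core_rms <- matrix(NA_real_, nf, length(elements),
                     dimnames = list(NULL, elements))

  truth <- data.frame(frame = seq_len(nf),
                      time = (seq_len(nf) - 1L) * p$sampling_interval,
                      entry = entry, exit = exit, total = total,
                      gaping = g)
  for (j in seq_len(nt))
    truth[[paste0("bound.", colnames(bound)[j])]] <- bound[, j]
  for (j in seq_len(nt))
    truth[[paste0("contacts.", colnames(bound)[j])]] <- contacts_floor[, j]
  class(truth) <- c("ground_truth", "data.frame")

  if (!coordinates) {
    attr(truth, "params") <- p
    return(list(system = sys, ensemble = NULL, truth = truth))
  }

  ref <- matrix(sys$xyz, ncol = 3L, byrow = TRUE)
  n_at <- nrow(ref)
  dna_rows <- which(at$role == "dna")
  bp_of_row <- at$bp_index[dna_rows]
  gap_plus <- dna_rows[bp_of_row >= sys$meta$gaping_bp_min]
  gap_minus <- dna_rows[bp_of_row <= -sys$meta$gaping_bp_min]
  radial_unit <- ref[dna_rows, ]
  radial_unit[, 3L] <- 0
  radial_unit <- radial_unit / sqrt(rowSums(radial_unit^2))
  core_rows <- which(is_core)
  tail_rows <- lapply(names(tails), function(nm) {
    t <- tails[[nm]]
    which(at$chain == t$chain & at$role == "tail" &
            at$resno %in% t$resno)
  })
  names(tail_rows) <- names(tails)
  anchor_rows <- lapply(tails, function(t)
    dna_rows[match(t$anchor_bp, bp_of_row)])

  X <- matrix(NA_real_, nf, 3L * n_at)
  for (f in seq_len(nf)) {
    fr <- ref
    # gaping: symmetric axial displacement of the two half-turn sets
    delta <- delta_all[f]
    fr[gap_plus, 3L] <- fr[gap_plus, 3L] + delta / 2
    fr[gap_minus, 3L] <- fr[gap_minus, 3L] - delta / 2
    # end unwrapping: radial displacement of the released core bp
    if (entry[f] > 0L) {
      rel <- which(bp_of_row >= -half & bp_of_row < -half + entry[f])
      fr[dna_rows[rel], ] <- fr[dna_rows[rel], , drop = FALSE] +
        p$unwrap_displacement * radial_unit[rel, , drop = FALSE]
    }
    if (exit[f] > 0L) {
      rel <- which(bp_of_row <= half & bp_of_row > half - exit[f])
      fr[dna_rows[rel], ] <- fr[dna_rows[rel], , drop = FALSE] +
        p$unwrap_displacement * radial_unit[rel, , drop = FALSE]
    }
    # core plasticity jitter (part of the signal, not the noise)
    jit <- matrix(rnorm(3L * length(core_rows), 0, rep(sig_el, 3L)),
                  ncol = 3L)
    fr[core_rows, ] <- fr[core_rows, ] + jit
    # tails: bound beads track their anchor DNA beads, unbound protrude
    for (j in seq_len(nt)) {
      tr <- tail_rows[[j]]
      ar <- anchor_rows[[j]]
      ru <- radial_unit[match(ar, dna_rows), , drop = FALSE]
      pos <- fr[ar, , drop = FALSE] + p$bind_distance * ru
      if (!bound[f, j]) pos <- pos + 25 * ru
      fr[tr, ] <- pos
    }
    # ground truth recorded above; noise goes on top
    if (p$noise_sigma > 0)
      fr <- fr + rnorm(3L * n_at, 0, p$noise_sigma)
    if (p$rigid_motion) {
      rot <- qr.Q(qr(matrix(rnorm(9L), 3L)))
      if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
      fr <- fr %*% rot
      fr <- sweep(fr, 2L, runif(3L, -20, 20), `+`)
    }
    X[f, ] <- as.numeric(t(fr))
  }
  # per-element RMS of the applied core jitter is reported as a summary
  for (el in elements) {
    idx <- at$element[core_rows] == el
    core_rms[, el] <- ifelse(el %in% c("L1", "L2"),
                             p$core_sigma[["loop"]], p$core_sigma[["helix"]])
  }
  attr(truth, "core_sigma") <- core_rms[1L, ]
  attr(truth, "params") <- p

  ens <- ensemble(X, p$sampling_interval, run_id = sprintf("seed%d", p$seed),
                  superposed = !p$rigid_motion)
  list(system = sys, ensemble = ens, truth = truth)
}

#' Write a synthetic system, trajectory and ground truth to files
#'
#' Writes the reference structure as PDB, the trajectory as DCD, a YAML
#' topology specification (so [load_structure()] can rebuild the system)
#' and the ground-truth table as TSV.
#'
#' @param system [nucleosome_system()] from [generate_reference()]
#' @param ensemble [ensemble()]
#' @param dir output directory (created if needed)
#' @param truth optional `ground_truth` data frame
#' @return named list of file paths
#' @export
write_fixture <- function(system, ensemble, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- system$atoms
  pdb_path <- file.path(dir, "structure.pdb")
  resid <- ifelse(at$role == "dna", "DA", "GLY")
  bio3d::write.pdb(file = pdb_path, xyz = system$xyz, resno = at$resno,
                   chain = at$chain, resid = resid, eleno = at$eleno,
                   elety = at$elety)
  top_path <- file.path(dir, "topology.yaml")
  plan <- system$meta$plan
  spec <- list(
    chains = lapply(plan, function(cs) {
      out <- list(variant = cs$variant, copy = cs$copy,
                  elements = lapply(cs$elements, as.integer))
      if (!is.null(cs$n_tail)) out$n_tail <- as.integer(cs$n_tail)
      if (!is.null(cs$c_tail)) out$c_tail <- as.integer(cs$c_tail)
      out
    }),
    dna = list(chains = "I", n_bp = nrow(system$dna),
               linker_bp = attr(system$dna, "linker_bp"),
               dyad_seq = attr(system$dna, "core_half") +
                 attr(system$dna, "linker_bp") + 1L)
  )
  write_topology_spec(spec, top_path)
  dcd_path <- file.path(dir, "trajectory.dcd")
  write_dcd(ensemble, dcd_path)
  paths <- list(structure = pdb_path, topology = top_path,
                trajectory = dcd_path)
  if (!is.null(truth)) {
    tsv <- file.path(dir, "ground_truth.tsv")
    write.table(truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truth <- tsv
  }
  paths
}
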