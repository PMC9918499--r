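#' Root-mean-square fluctuation of selected atoms
#'
#' Per-atom RMSF about the time-averaged position, computed on a
#' superposed ensemble: `RMSF_j = sqrt( mean_t |r_j(t) - <r_j>|^2 )`.
#' The reference is the ensemble mean structure, not the first frame.
#'
#' @param ensemble superposed [ensemble()] with at least 2 frames
#' @param system [nucleosome_system()]
#' @param selection integer atom indices; default: core C-alpha atoms of
#'   all histone chains (tails excluded, as for a globular-core analysis)
#' @return data frame with columns `atom`, `chain`, `resno`, `element`,
#'   `rmsf` (Angstrom)
#' @export
rmsf <- function(ensemble, system, selection = NULL) {
  if (!isTRUE(ensemble$superposed))
    stop("ensemble must be superposed before RMSF analysis")
  if (nrow(ensemble$xyz) < 2L) stop("RMSF needs at least 2 frames")
  if (is.null(selection))
    selection <- core_ca_selection(system, exclude_loops = FALSE)
  if (!length(selection)) stop("empty selection")
  msf <- 0
  for (d in 0:2) {
    Xd <- ensemble$xyz[, 3L * (selection - 1L) + 1L + d, drop = FALSE]
    mu <- colMeans(Xd)
    msf <- msf + colMeans(sweep(Xd, 2L, mu)^2)
  }
  at <- system$atoms
  data.frame(atom = selection, chain = at$chain[selection],
             resno = at$resno[selection], element = at$element[selection],
             rmsf = sqrt(as.numeric(msf)))
}

#' Aggregate RMSF series across copies and runs
#'
#' Aligns per-copy/per-run RMSF results on residue position and reports
#' the per-position mean and standard error `sd / sqrt(n)` over the
#' series (n = copies x runs, e.g. n = 6 for two copies in three runs).
#'
#' @param results list of [rmsf()] results with identical residue grids
#'   (the `resno` column)
#' @return data frame with `resno`, `mean_rmsf`, `se`, `n`
#' @export
aggregate_rmsf <- function(results) {
  if (length(results) < 2L) stop("need at least 2 RMSF results")
  grid <- results[[1L]]$resno
  for (r in results[-1L])
    if (!identical(r$resno, grid))
      stop("residue grids differ between RMSF results")
  m <- sapply(results, `[[`, "rmsf")
  data.frame(resno = grid,
             mean_rmsf = rowMeans(m),
             se = apply(m, 1L, sd) / sqrt(ncol(m)),
             n = ncol(m))
}
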