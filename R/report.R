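#' Analysis configuration
#'
#' Bundles the analysis constants: unwrap displacement threshold (7
#' Angstrom), heavy-atom contact cutoff (4.5 Angstrom), temperature
#' (310 K), equilibration trim (200 ns), Savitzky-Golay smoothing (10 ns
#' window, order 1), superhelical pitch (10.3 bp/turn), inner/outer DNA
#' boundary (|bp| = 37), 2D histogram bins and the gaping measurement
#' windows.
#'
#' @param unwrap_threshold Angstrom
#' @param contact_cutoff Angstrom
#' @param temperature Kelvin
#' @param trim_ns equilibration cut, ns
#' @param smooth_ns,smooth_order Savitzky-Golay window (ns) and order
#' @param shl_pitch bp per superhelical turn
#' @param inner_outer_boundary |bp| boundary between inner and outer DNA
#' @param fe2d_bins 2D free-energy histogram bins `c(n1, n2)`
#' @param gaping_shl SHL pair for the gaping distance
#' @param gaping_window window half-width, bp
#' @param seed integer seed recorded for provenance
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(unwrap_threshold = 7, contact_cutoff = 4.5,
                            temperature = 310, trim_ns = 200,
                            smooth_ns = 10, smooth_order = 1,
                            shl_pitch = 10.3, inner_outer_boundary = 37L,
                            fe2d_bins = c(60L, 40L),
                            gaping_shl = c(-4L, 4L), gaping_window = 2L,
                            seed = 1L) {
  stopifnot(unwrap_threshold > 0, contact_cutoff > 0, temperature > 0,
            trim_ns >= 0, smooth_ns > 0)
  structure(as.list(environment()), class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file
#' @return [analysis_config()]
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config [analysis_config()]
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable hash of a configuration for output provenance
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_analysis_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' One-shot analysis report over one or more trajectories
#'
#' Runs the full pipeline on each trajectory: equilibration trimming,
#' histone-core superposition, per-frame unwrapping, gaping, DNA radius of
#' gyration, H2A-family tail-DNA contacts, and RMSF; then pools per-run-
#' and-side free-energy profiles with cross-run standard errors and a 2D
#' free-energy surface over (Rg, total DNA-histone contacts). Per-run
#' tables are written as TSV and headline numbers as a machine-readable
#' JSON summary. Deterministic given inputs and configuration.
#'
#' @param system [nucleosome_system()]
#' @param ensembles list of [ensemble()] objects (one per run), or paths
#'   to trajectory files loadable by [load_trajectory()]
#' @param config [analysis_config()]
#' @param out_dir output directory
#' @param sampling_interval ps, used when `ensembles` are file paths
#' @param contact_series also compute per-frame tail and total contact
#'   series (the slowest stage; disable for quick looks)
#' @return invisibly, the summary list written to `summary.json`
#' @export
run_report <- function(system, ensembles, config = analysis_config(),
                       out_dir, sampling_interval = 100,
                       contact_series = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!length(ensembles)) stop("need at least one trajectory")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  profiles <- list()
  summary <- list(config_hash = config_hash(config), runs = list())
  max_total <- 0L
  gaping_all <- numeric(0)
  rmsf_by_copy <- list()
  h2a_chains <- names(Filter(function(c)
    c$variant_id %in% c("H2A", "H2A.Z"), system$chains))

  for (k in seq_along(ensembles)) {
    ens <- ensembles[[k]]
    if (is.character(ens))
      ens <- stage("load_trajectory",
                   load_trajectory(ens, system, sampling_interval))
    run <- ens$run_id
    ens <- stage("trim_equilibration",
                 trim_equilibration(ens, config$trim_ns))
    ens <- stage("superpose", superpose(ens, system))

    uw <- stage("unwrap_series",
                unwrap_series(ens, system, config$unwrap_threshold))
    gp <- stage("gaping_series",
                gaping_series(ens, system, config$gaping_shl,
                              config$gaping_window, config$shl_pitch))
    rg <- stage("rg_series", rg_series(ens, system))
    tbl <- data.frame(time = uw$time, entry = uw$entry, exit = uw$exit,
                      total = uw$total, gaping = gp$distance, rg_dna = rg)

    contact_summ <- NULL
    if (contact_series) {
      dna_sel <- dna_region_atoms(system, "total")
      hist_sel <- which(system$atoms$role != "dna")
      total_contacts <- stage("count_contacts", vapply(
        seq_len(nrow(ens$xyz)), function(f)
          count_contacts(ens$xyz[f, ], system, hist_sel, dna_sel,
                         config$contact_cutoff), integer(1)))
      tbl$dna_histone_contacts <- total_contacts
      for (ch in h2a_chains) {
        for (side in c("N", "C")) {
          rng <- if (side == "N") system$chains[[ch]]$n_tail else
            system$chains[[ch]]$c_tail
          if (is.null(rng)) next
          cs <- stage("tail_dna_contact_series",
                      tail_dna_contact_series(ens, system, ch, side,
                                              "total",
                                              config$contact_cutoff))
          tbl[[paste0("contacts_", ch, "_", side)]] <- cs$contacts
        }
      }
      fes2 <- stage("free_energy_2d",
                    free_energy_2d(rg, total_contacts, config$fe2d_bins,
                                   config$temperature))
      .write_surface(fes2, file.path(out_dir,
                                     sprintf("fes2d_%s.tsv", run)))
    }
    write.table(tbl, file.path(out_dir, sprintf("series_%s.tsv", run)),
                sep = "\t", quote = FALSE, row.names = FALSE)

    profiles[[paste0(run, ".entry")]] <-
      free_energy_1d(uw$entry, config$temperature)
    profiles[[paste0(run, ".exit")]] <-
      free_energy_1d(uw$exit, config$temperature)

    for (ch in h2a_chains) {
      sel <- core_ca_selection(system, exclude_loops = FALSE)
      sel <- sel[system$atoms$chain[sel] == ch]
      r <- stage("rmsf", rmsf(ens, system, sel))
      rmsf_by_copy[[paste0(run, ".", ch)]] <- r
    }

    max_total <- max(max_total, max(uw$total))
    gaping_all <- c(gaping_all, gp$distance)
    summary$runs[[run]] <- list(
      n_frames = nrow(ens$xyz),
      max_total_unwrapped_bp = max(uw$total),
      mean_fit_rmsd = mean(ens$rmsd))
  }

  pooled <- profile_standard_error(profiles)
  write.table(pooled, file.path(out_dir, "fes1d.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(rmsf_by_copy) >= 2L) {
    agg <- stage("aggregate_rmsf", aggregate_rmsf(rmsf_by_copy))
    write.table(agg, file.path(out_dir, "rmsf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  gh <- hist_mode(gaping_all)
  summary$max_total_unwrapped_bp <- max_total
  summary$gaping_mode_A <- gh
  summary$fe_profile_slope_kcal_per_bp <-
    profile_slope(free_energy_1d(
      unlist(lapply(profiles, function(p)
        rep(p$i, p$n))), config$temperature))
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}

#' Histogram mode of a distance distribution
#'
#' Mode of a fixed-bin-width histogram with bin centers aligned on
#' multiples of the bin width (0.5 Angstrom by default), the estimator
#' used for gaping-distance distribution peaks.
#'
#' @param x numeric sample
#' @param binwidth bin width
#' @return center of the most occupied bin
#' @export
hist_mode <- function(x, binwidth = 0.5) {
  if (!length(x)) return(NA_real_)
  br <- seq(floor(min(x)) - binwidth / 2, ceiling(max(x)) + binwidth,
            by = binwidth)
  h <- hist(x, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

.write_surface <- function(surface, path) {
  g <- expand.grid(i1 = seq_len(nrow(surface$delta_g)),
                   i2 = seq_len(ncol(surface$delta_g)))
  out <- data.frame(
    cv1_lo = surface$edges1[g$i1], cv1_hi = surface$edges1[g$i1 + 1L],
    cv2_lo = surface$edges2[g$i2], cv2_hi = surface$edges2[g$i2 + 1L],
    count = as.integer(surface$counts[cbind(g$i1, g$i2)]),
    delta_g = surface$delta_g[cbind(g$i1, g$i2)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
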