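## Run configuration and the two end-to-end workflows:
## simulate_compare (array simulation + remodeling + per-density
## autocorrelogram comparison) and decode (synthetic molecules -> HMM
## decoding -> footprints -> fiber statistics), plus enrich (cluster x
## domain enrichment testing from label tables).

#' Build a run configuration
#'
#' Central parameter block for [run_workflow()]. Defaults follow the
#' package's standard analysis settings: expected HMM run length
#' `L = 1000` bp, accessibility threshold 0.5, Leiden resolution 0.4 with
#' the 5% cumulative cluster-size filter, clamp visibility 183 nt,
#' ruler / flank cutoffs of 20 and 48 nt, mixture tolerance `1e-6`, and
#' q-value cutoff 0.05.
#'
#' @param workflow `"simulate_compare"`, `"decode"` or `"enrich"`.
#' @param seed Master seed; every stochastic stage draws its own substream
#'   from it.
#' @param output_dir Directory for result tables (created if needed).
#' @param ... Overrides for individual parameters (see Details in the
#'   package vignette); unknown names are an error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(workflow = c("simulate_compare", "decode", "enrich"),
                       seed = 1L, output_dir = tempfile("chromfiber_run_"),
                       ...) {
  workflow <- match.arg(workflow)
  cfg <- list(
    workflow = workflow, seed = as.integer(seed), output_dir = output_dir,
    ## arraysim
    template_length = 2712L, n_fibers = 200L, densities = 5:12,
    min_linker = 10L, ruler = 20L, ruler_sd = 0, visibility = 183L,
    flank_cutoff = 48L, step = 1L, n_sweeps = 500L,
    ## synthdata / decode
    n_molecules = 200L, adenine_fraction = 0.5,
    acc_beta = c(8, 12), inacc_beta = c(2, 98),
    expected_run_length = 1000, accessibility_threshold = 0.5,
    mixture_tol = 1e-6,
    ## fiberstats
    max_lag = 1000L, peak_window = c(100L, 500L), resolution = 0.4,
    min_total_frac = 0.05,
    ## enrichstats
    q_cutoff = 0.05,
    ## enrich inputs (per-molecule label vectors)
    cluster_labels = NULL, domain_labels = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Run a configured workflow
#'
#' Executes the stage chain for the configured workflow, writes all
#' intermediate tables under `config$output_dir`, and returns a manifest
#' (parameters, seeds, output paths and headline results). Identical
#' configurations produce identical outputs; each stochastic stage consumes
#' a stage-specific substream derived from the master seed.
#'
#' @param config A [run_config()].
#' @return A manifest list (invisible file side effects under
#'   `output_dir`); for `simulate_compare` it contains the per-density peak
#'   tables and peak-density correlations for both remodeling modes, for
#'   `decode` the footprint/density/autocorrelogram tables, for `enrich`
#'   the enrichment matrices.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- switch(config$workflow,
                     simulate_compare = run_simulate_compare(config),
                     decode = run_decode(config),
                     enrich = run_enrich(config))
  manifest$config <- unclass(config)
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "objects")],
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

run_simulate_compare <- function(cfg) {
  seeds <- stage_seeds(cfg$seed, 4L)
  ens <- simulate_fiber_ensemble(cfg$n_fibers, cfg$densities,
                                 cfg$template_length, cfg$min_linker,
                                 seed = seeds[1L])
  clamp_cfg <- remodel_config("clamp", ruler = cfg$ruler,
                              ruler_sd = cfg$ruler_sd,
                              visibility = cfg$visibility)
  ls_cfg <- remodel_config("length_sensing", flank_cutoff = cfg$flank_cutoff,
                           step = cfg$step, n_sweeps = cfg$n_sweeps)
  clamp_seeds <- stage_seeds(seeds[2L], length(ens$fibers))
  ls_seeds <- stage_seeds(seeds[3L], length(ens$fibers))
  clamp_fibers <- mapply(remodel_clamp, ens$fibers, seed = clamp_seeds,
                         MoreArgs = list(config = clamp_cfg), SIMPLIFY = FALSE)
  ls_fibers <- mapply(remodel_length_sensing, ens$fibers, seed = ls_seeds,
                      MoreArgs = list(config = ls_cfg), SIMPLIFY = FALSE)
  prof <- lapply(list(clamp = clamp_fibers, length_sensing = ls_fibers),
                 function(fibers)
                   per_density_profiles(lapply(fibers, occupancy_track),
                                        ens$density, cfg$peak_window,
                                        cfg$max_lag))
  for (mode in names(prof))
    write.table(prof[[mode]]$profiles,
                file.path(cfg$output_dir, paste0("profiles_", mode, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_fiber_bed(clamp_fibers, file.path(cfg$output_dir, "fibers_clamp.bed"))
  write_fiber_bed(ls_fibers,
                  file.path(cfg$output_dir, "fibers_length_sensing.bed"))
  corr <- lapply(prof, function(p)
    tryCatch(density_peak_correlation(p), error = function(e) NULL))
  list(workflow = "simulate_compare",
       profiles = lapply(prof, `[[`, "profiles"),
       peak_density_correlation = corr,
       objects = list(ensemble = ens, clamp = clamp_fibers,
                      length_sensing = ls_fibers, profiles = prof),
       outputs = file.path(cfg$output_dir,
                           c("profiles_clamp.tsv",
                             "profiles_length_sensing.tsv",
                             "fibers_clamp.bed", "fibers_length_sensing.bed",
                             "manifest.json")))
}

run_decode <- function(cfg) {
  seeds <- stage_seeds(cfg$seed, 3L)
  rates <- make_rate_map(cfg$template_length, cfg$adenine_fraction,
                         cfg$acc_beta, cfg$inacc_beta, seed = seeds[1L])
  dens <- rep(cfg$densities, length.out = cfg$n_molecules)
  fib_seeds <- stage_seeds(seeds[2L], cfg$n_molecules)
  mol_seeds <- stage_seeds(seeds[3L], cfg$n_molecules)
  hmm <- build_hmm(rates, cfg$expected_run_length)
  fibers <- tracks <- vector("list", cfg$n_molecules)
  fps <- vector("list", cfg$n_molecules)
  for (i in seq_len(cfg$n_molecules)) {
    fibers[[i]] <- place_nucleosomes(cfg$template_length, dens[i],
                                     cfg$min_linker, seed = fib_seeds[i])
    calls <- simulate_molecule(fibers[[i]], rates, seed = mol_seeds[i],
                               molecule_id = sprintf("mol_%05d", i))
    tracks[[i]] <- decode_molecule(hmm, calls, cfg$template_length)
    fps[[i]] <- count_nucleosomes(
      call_inaccessible_regions(tracks[[i]], cfg$accessibility_threshold,
                                sprintf("mol_%05d", i)))
  }
  density_tab <- data.frame(
    molecule_id = sprintf("mol_%05d", seq_len(cfg$n_molecules)),
    planted_nucleosomes = dens,
    called_nucleosomes = vapply(fps, function(f) sum(f$nuc_count), integer(1L)),
    density_per_kbp = vapply(fps, fiber_density, 0,
                             template_length = cfg$template_length))
  acm <- autocorrelogram_matrix(tracks, cfg$max_lag)
  fp_all <- do.call(rbind, fps)
  write.table(fp_all, file.path(cfg$output_dir, "footprints.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(density_tab, file.path(cfg$output_dir, "density.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(molecule_id = density_tab$molecule_id,
                    as.data.frame(acm)),
              file.path(cfg$output_dir, "autocorrelograms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(workflow = "decode", density = density_tab,
       objects = list(rates = rates, hmm = hmm, fibers = fibers,
                      tracks = tracks, footprints = fps, ac_matrix = acm),
       outputs = file.path(cfg$output_dir,
                           c("footprints.bed", "density.tsv",
                             "autocorrelograms.tsv", "manifest.json")))
}

run_enrich <- function(cfg) {
  if (is.null(cfg$cluster_labels) || is.null(cfg$domain_labels))
    stop("enrich workflow needs cluster_labels and domain_labels in the config")
  res <- fisher_enrichment(cfg$cluster_labels, cfg$domain_labels,
                           cfg$q_cutoff)
  for (nm in c("odds_ratio", "p_value", "q_value"))
    write.table(res[[nm]], file.path(cfg$output_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE)
  list(workflow = "enrich",
       n_significant = sum(res$significant, na.rm = TRUE),
       objects = list(enrichment = res),
       outputs = file.path(cfg$output_dir,
                           c("odds_ratio.tsv", "p_value.tsv", "q_value.tsv",
                             "manifest.json")))
}
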