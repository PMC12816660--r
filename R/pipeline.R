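#' Read and validate a pipeline configuration
#'
#' Single YAML file with per-stage sections (`seed`, `lesion`, `connectome`,
#' `stim`, `resection`, `svrlsm`); unknown keys are rejected. Parsing then
#' serializing then parsing is the identity.
#'
#' @param path YAML file, or a list already in memory.
#' @return validated config list of class `convergemap_config`.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  known <- c("seed", "lesion", "connectome", "stim", "resection", "svrlsm",
             "stages", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 7L
  structure(cfg, class = "convergemap_config")
}

#' Write a configuration back to YAML
#' @param cfg config list.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full synthetic pipeline and emit a convergence report
#'
#' Generates the synthetic cohorts, runs SVR-LSM on the lesion cohort,
#' consensus-hub connectomics and TDI on the connectome cohort, disconnection
#' modelling on the resection scenarios, and PDE mapping of the stimulation
#' sites; the report joins the stages through the spatial overlap (Dice) of
#' the PDE mask, the SVR-LSM significant cluster, and the TDI core.
#'
#' @param config a `convergemap_config`, a YAML path, or NULL for defaults.
#' @param stages character subset of
#'   c("svrlsm", "connectome", "disconnect", "stim") (default all).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print stage progress.
#' @return list of class `run_manifest` holding per-stage results, the
#'   convergence report, seeds and timing.
#' @export
run_pipeline <- function(config = NULL, stages = c("svrlsm", "connectome",
                                                   "disconnect", "stim"),
                         out_dir = NULL, verbose = TRUE) {
  cfg <- if (is.null(config)) read_config(list()) else read_config(config)
  spec <- synth_spec(seed = cfg$seed,
                     lesion = if (is.null(cfg$lesion)) list() else cfg$lesion,
                     connectome = if (is.null(cfg$connectome)) list() else cfg$connectome,
                     stim = if (is.null(cfg$stim)) list() else cfg$stim,
                     resection = if (is.null(cfg$resection)) list() else cfg$resection)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  res <- list(spec = spec)

  if ("svrlsm" %in% stages) {
    say("[svrlsm] generating lesion cohort and fitting (seed %d)", spec$seed)
    cohort <- make_lesion_cohort(spec)
    sv_args <- if (is.null(cfg$svrlsm)) list() else cfg$svrlsm
    sv_cfg <- do.call(svrlsm_config, c(sv_args, list(seed = spec$seed)))
    hyper <- sv_args$hyperparameters
    res$svrlsm <- svrlsm(cohort$masks,
                         cohort$behaviour$delta_asymmetry_cont,
                         covariates = cohort$behaviour[, c("age", "education", "grade")],
                         config = sv_cfg, hyperparameters = hyper)
    res$lesion_cohort <- cohort
    res$svrlsm_dice <- convergence_overlap(res$svrlsm$significant_cluster_mask,
                                           cohort$planted_mask)$dice
  }
  if ("connectome" %in% stages) {
    say("[connectome] generating cohort, building FBC matrices")
    ccoh <- make_connectome_cohort(spec)
    fbcs <- lapply(ccoh$sets, build_fbc, atlas = ccoh$atlas)
    hubs <- composite_hubs(fbcs)
    edges <- consensus_top_edges(fbcs, hubs$hubs)
    res$connectome <- list(cohort = ccoh, fbcs = fbcs, hubs = hubs,
                           edges = edges)
  }
  if ("disconnect" %in% stages) {
    say("[disconnect] simulating resections (n = %d)",
        spec$resection$n_patients)
    rc <- make_resection_scenarios(spec)
    dt <- disconnection_table(rc$scenarios, rc$test_edges, rc$atlas)
    res$disconnection <- list(cohort = rc, table = dt,
                              correlation = edgewise_correlation(
                                dt, m = nrow(rc$test_edges)))
  }
  if ("stim" %in% stages) {
    say("[stim] generating stimulation sites and PDE map")
    sc <- make_stim_sites(spec)
    grid <- voxel_image(array(0L, spec$stim$world_shape))
    res$stim <- list(cohort = sc,
                     pde = pde(as.matrix(sc$sites[, c("x", "y", "z")]), grid),
                     hemifield = hemifield_error_summary(
                       sc$omitted_positions,
                       rep("all", length(sc$omitted_positions))))
  }
  report <- list()
  if (!is.null(res$svrlsm) && !is.null(res$stim)) {
    # convergence on the lesion grid: site coordinates are rescaled from the
    # stimulation world frame onto the lesion grid before the PDE is
    # re-evaluated there, so the masks share a grid
    lsm_grid <- res$svrlsm$significant_cluster_mask
    scale_f <- dim(lsm_grid$data) / spec$stim$world_shape
    sites <- as.matrix(res$stim$cohort$sites[, c("x", "y", "z")])
    sites_scaled <- sweep(sites, 2, scale_f, "*")
    pde_on_lsm <- pde(sites_scaled, lsm_grid,
                      bandwidth = 5 * min(scale_f))
    report$pde_vs_lsm_dice <- suppressWarnings(
      convergence_overlap(pde_on_lsm$mask, lsm_grid)$dice)
    report$svrlsm_planted_dice <- res$svrlsm_dice
  }
  manifest <- structure(list(
    config = unclass(cfg), seed = spec$seed, results = res,
    report = report,
    version = as.character(utils::packageVersion("convergemap")),
    elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "run_manifest")
  if (!is.null(out_dir)) save_manifest(manifest, out_dir)
  manifest
}

save_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- manifest$results
  if (!is.null(res$svrlsm)) {
    write_volume(res$svrlsm$beta_map, file.path(out_dir, "svrlsm_beta.nii.gz"))
    write_volume(res$svrlsm$significant_cluster_mask,
                 file.path(out_dir, "svrlsm_cluster.nii.gz"))
    jsonlite::write_json(list(hyperparameters = res$svrlsm$hyperparameters,
                              critical_p = res$svrlsm$critical_p,
                              clusters = res$svrlsm$cluster_table),
                         file.path(out_dir, "svrlsm_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(res$disconnection)) {
    utils::write.csv(res$disconnection$correlation,
                     file.path(out_dir, "disconnection_correlation.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(c(manifest$report,
                         list(seed = manifest$seed,
                              version = manifest$version)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, %.1f s\n", x$seed, x$elapsed_s))
  for (nm in names(x$report))
    cat(sprintf("  %s: %.3f\n", nm, x$report[[nm]]))
  invisible(x)
}

#' Recompute the worked-example statistics from their printed inputs
#'
#' Reference checks connecting the statistical helpers to the values such
#' studies report: partial eta squared from F ratios, Cohen's d_z from a
#' paired t, the Spearman companion t, and Bonferroni-adjusted Spearman
#' p-values.
#'
#' @return data frame with `quantity`, `input`, `value`.
#' @export
verify_paper_examples <- function() {
  rows <- list(
    data.frame(quantity = "partial_eta_sq", input = "F(1,161)=54.23",
               value = partial_eta_sq(54.23, 1, 161)),
    data.frame(quantity = "partial_eta_sq", input = "F(1,161)=24.92",
               value = partial_eta_sq(24.92, 1, 161)),
    data.frame(quantity = "partial_eta_sq", input = "F(1,45)=0.10",
               value = partial_eta_sq(0.10, 1, 45)),
    data.frame(quantity = "cohens_dz", input = "t(81)=-5.272, n=82",
               value = cohens_dz_from_t(-5.272, 82)),
    data.frame(quantity = "spearman_t", input = "rho=0.770, n=82",
               value = spearman_t(0.770, 82)),
    data.frame(quantity = "bonferroni_p", input = "rho=0.826, n=15, m=39",
               value = spearman_p_bonferroni(0.826, 15, 39)$p_adjusted),
    data.frame(quantity = "bonferroni_p", input = "rho=0.8178, n=15, m=39",
               value = spearman_p_bonferroni(0.8178, 15, 39)$p_adjusted),
    data.frame(quantity = "bonferroni_p", input = "rho=0.78911, n=15, m=39",
               value = spearman_p_bonferroni(0.78911, 15, 39)$p_adjusted))
  do.call(rbind, rows)
}
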