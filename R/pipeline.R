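#' Pipeline configuration
#'
#' Bundles the analysis parameters of the full pipeline. All defaults are
#' the study values: edge FDR q = 0.05, mu = 5 randomized references,
#' 10-mm FWHM metric-map smoothing, 3-voxel cube edge, 50-voxel cluster
#' extent, height p < .05 (FWE) in conservative mode and p < .001
#' (uncorrected) in exploratory mode. A configuration can also be read
#' from a YAML file with the same field names (a `simulation` block is
#' passed to [simulation_config()]).
#'
#' @param q edge FDR level.
#' @param mu randomized references per subject.
#' @param fwhm_mm metric-map smoothing FWHM (mm).
#' @param cube_edge_voxels cube edge (voxels).
#' @param extent_voxels cluster extent threshold.
#' @param height_p_fwe,height_p_uncorrected height thresholds per mode.
#' @param n_perm permutations for FWE correction.
#' @param n_null empirical-null samples per subject.
#' @param metrics nodal metrics to map (subset of `k`, `c`, `L`, `BC`).
#' @param seed master seed.
#' @param simulation a [simulation_config()] (or list of its arguments).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(q = 0.05, mu = 5L, fwhm_mm = 10,
                            cube_edge_voxels = 3L, extent_voxels = 50L,
                            height_p_fwe = 0.05,
                            height_p_uncorrected = 0.001,
                            n_perm = 500L, n_null = 10000L,
                            metrics = c("k", "c"),
                            seed = 1L, simulation = simulation_config()) {
  if (is.list(simulation) && !inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, simulation)
  structure(list(q = q, mu = mu, fwhm_mm = fwhm_mm,
                 cube_edge_voxels = as.integer(cube_edge_voxels),
                 extent_voxels = as.integer(extent_voxels),
                 height_p_fwe = height_p_fwe,
                 height_p_uncorrected = height_p_uncorrected,
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 metrics = metrics, seed = as.integer(seed),
                 simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  args <- yaml::read_yaml(path)
  if (!is.null(args$simulation$edge_block_specs))
    args$simulation$edge_block_specs <-
      lapply(args$simulation$edge_block_specs, function(s)
        list(origin = unlist(s$origin), size = unlist(s$size),
             strength = s$strength))
  do.call(pipeline_config, args)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> extract -> metrics -> maps -> stats and writes all
#' stage outputs plus a JSON run manifest (package version, parameters,
#' seeds, and an MD5 hash per output file) to `out_dir`. Re-running with
#' the same configuration reproduces the outputs bit-identically.
#'
#' Stage outputs: per-subject gray-matter volumes and covariate table
#' (simulate); per-subject global-metrics rows (`global_metrics.csv`);
#' per-subject smoothed metric maps (maps); ANCOVA of gamma/lambda/sigma
#' on group, partial correlations of the global metrics with SUVR per
#' group, voxel-wise group-difference and per-group SUVR-regression
#' cluster tables in conservative (permutation FWE) and exploratory
#' (uncorrected height) modes (stats).
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "extract", "maps", "stats")`;
#'   later stages require earlier ones in the same call.
#' @return The manifest (also written to `manifest.json`), invisibly the
#'   full results list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "extract", "maps", "stats")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)

  results <- list(config = config)

  if ("simulate" %in% stages) {
    results$cohort <- generate_cohort(config$simulation,
                                      out_dir = file.path(out_dir, "volumes"))
  } else stop("missing inputs for stage 'extract': run 'simulate' first")

  cohort <- results$cohort
  nsub <- nrow(cohort$table)

  if ("extract" %in% stages) {
    nets <- vector("list", nsub)
    for (i in seq_len(nsub)) {
      nets[[i]] <- gm_network(cohort$volumes[[i]], cohort$mask,
                              q = config$q, mu = config$mu,
                              n_null = config$n_null,
                              seed = child_seed(config$seed, i),
                              include_betweenness = "BC" %in% config$metrics)
    }
    results$networks <- nets
    gm <- do.call(rbind, lapply(seq_len(nsub), function(i) {
      g <- nets[[i]]$global
      data.frame(subject_id = cohort$table$subject_id[i],
                 C_network = g$C_network, L_network = g$L_network,
                 gamma = g$gamma, lambda = g$lambda, sigma = g$sigma,
                 mu = g$mu, seed = nets[[i]]$seed)
    }))
    results$global_metrics <- gm
    write.csv(gm, file.path(out_dir, "global_metrics.csv"), row.names = FALSE)
  }

  if ("maps" %in% stages) {
    if (is.null(results$networks)) stop("missing inputs for stage 'maps'")
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    results$maps <- lapply(seq_len(nsub), function(i) {
      mm <- metric_maps(results$networks[[i]], metrics = config$metrics,
                        fwhm_mm = config$fwhm_mm)
      for (mn in names(mm))
        write_volume(mm[[mn]], file.path(
          map_dir, paste0(cohort$table$subject_id[i], "_", mn, ".nii.gz")))
      mm
    })
  }

  if ("stats" %in% stages) {
    if (is.null(results$maps)) stop("missing inputs for stage 'stats'")
    tab <- cohort$table
    gm <- results$global_metrics
    results$stats <- list()

    results$stats$demographics <- list(
      age = compare_groups_scalar(tab$age, tab$group),
      sex = compare_groups_categorical(tab$sex, tab$group),
      suvr = compare_groups_scalar(tab$suvr, tab$group))

    results$stats$ancova <- lapply(
      c(gamma = "gamma", lambda = "lambda", sigma = "sigma"),
      function(v) ancova_global(gm[[v]], tab$group, tab$age, tab$sex))

    results$stats$partial_cor <- lapply(
      c(control = "control", patient = "patient"), function(g) {
        sel <- tab$group == g
        lapply(c(gamma = "gamma", lambda = "lambda", sigma = "sigma"),
               function(v) partial_correlation(
                 gm[[v]][sel], tab$suvr[sel],
                 data.frame(age = tab$age[sel], sex = factor(tab$sex[sel]))))
      })

    cluster_tabs <- list()
    for (mn in config$metrics) {
      maps_m <- lapply(results$maps, `[[`, mn)
      des_grp <- data.frame(group = factor(tab$group), age = tab$age,
                            sex = factor(tab$sex))
      fit <- voxelwise_glm(maps_m, des_grp, "group")
      # grouppatient indicator: positive t = patient > control; the
      # patient-deficit direction is the negated map
      for (dir in c("control_gt_patient", "patient_gt_control")) {
        tm <- if (dir == "control_gt_patient") -fit$t else fit$t
        cluster_tabs[[paste0(mn, "_group_", dir, "_exploratory")]] <-
          cluster_extent(tm, height_p = config$height_p_uncorrected,
                         df = fit$df, extent_voxels = config$extent_voxels,
                         affine = cohort$mask$affine)
      }
      pf <- permutation_fwe(maps_m, des_grp, "group",
                            n_perm = config$n_perm,
                            seed = child_seed(config$seed, 1000L))
      cluster_tabs[[paste0(mn, "_group_fwe")]] <-
        cluster_extent(abs(pf$t), t_threshold = pf$t_fwe05,
                       extent_voxels = config$extent_voxels,
                       affine = cohort$mask$affine)
      for (g in c("control", "patient")) {
        sel <- tab$group == g
        des_s <- data.frame(suvr = tab$suvr[sel], age = tab$age[sel],
                            sex = factor(tab$sex[sel]))
        if (sum(sel) <= ncol(model_matrix_covariates(des_s)) + 1L) {
          message("group '", g, "' too small for the per-group SUVR ",
                  "regression; skipped")
          next
        }
        fit_s <- voxelwise_glm(maps_m[sel], des_s, "suvr")
        for (dir in c("positive_corr", "negative_corr")) {
          tm <- if (dir == "negative_corr") -fit_s$t else fit_s$t
          cluster_tabs[[paste0(mn, "_suvr_", g, "_", dir, "_exploratory")]] <-
            cluster_extent(tm, height_p = config$height_p_uncorrected,
                           df = fit_s$df,
                           extent_voxels = config$extent_voxels,
                           affine = cohort$mask$affine)
        }
      }
    }
    results$stats$clusters <- cluster_tabs
    ct <- do.call(rbind, lapply(names(cluster_tabs), function(nm) {
      d <- cluster_tabs[[nm]]
      if (nrow(d) == 0) return(NULL)
      cbind(analysis = nm, d)
    }))
    if (is.null(ct))
      ct <- data.frame(analysis = character(0), cluster_size = integer(0),
                       peak_t = numeric(0))
    write.csv(ct, file.path(out_dir, "cluster_table.csv"), row.names = FALSE)
    results$cluster_table <- ct
  }

  rel_files <- setdiff(list.files(out_dir, recursive = TRUE),
                       "manifest.json")
  hashes <- unname(tools::md5sum(file.path(out_dir, rel_files)))
  manifest <- list(
    package = "graynet",
    version = as.character(utils::packageVersion("graynet")),
    seed = config$seed,
    parameters = config[c("q", "mu", "fwhm_mm", "cube_edge_voxels",
                          "extent_voxels", "height_p_fwe",
                          "height_p_uncorrected", "n_perm", "n_null",
                          "metrics")],
    simulation = unclass(config$simulation)[
      c("grid_shape", "voxel_size_mm", "n_per_group", "smoothness_fwhm_mm",
        "group_effect", "covariate_coupling", "seed")],
    stages = stages,
    file_hashes = as.list(stats::setNames(hashes, rel_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
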