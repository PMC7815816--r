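#' Configuration of a synthetic cohort simulation
#'
#' Defines the study conditions for a simulated two-group cohort of
#' gray-matter-density volumes with planted network structure. Spatial
#' autocorrelation is produced by Gaussian-smoothing white noise to
#' `smoothness_fwhm_mm` and squashing the field affinely to \[0, 1\]; true
#' edges are planted by mixing a shared latent 27-vector into every cube of
#' a designated region, giving an inter-cube texture correlation equal to
#' the region's `strength`; the patient group has that strength multiplied
#' by `1 - group_effect` inside planted regions (degraded local
#' connectivity); and an SUVR-like scalar covariate is coupled, with a
#' per-group sign, to each subject's latent connectivity factor.
#'
#' Demographic defaults (age distributions, SUVR means/SDs per group)
#' follow the cohorts the method targets: controls aged 68.1 +/- 6.5 with
#' SUVR 1.14 +/- 0.17, patients aged 69.5 +/- 8.7 with SUVR 1.49 +/- 0.43,
#' with the covariate coupling positive in controls and negative in
#' patients. Age and sex are generated independent of the planted effects
#' unless `confound_covariates` is set, which links age to the latent
#' connectivity factor so nuisance regression can be exercised.
#'
#' @param grid_shape voxels per axis (each >= 12, i.e. >= 4 cube edges).
#' @param voxel_size_mm voxel edge in mm (default 2: 6-mm cube side).
#' @param n_per_group subjects per group (>= 3; default 15).
#' @param smoothness_fwhm_mm FWHM of the spatial autocorrelation (mm).
#' @param local_texture_corr nearest-neighbour cube texture correlation of
#'   the background latent texture field, in \[0, 0.9\] (default 0.85).
#'   This is what makes neighbouring cubes genuinely similar and the
#'   resulting single-subject networks lattice-like (small-world).
#' @param smooth_intensity_share variance share of the voxel-level smooth
#'   intensity field within each cube (default 0.15); the remainder is the
#'   cube-level texture field.
#' @param edge_block_specs list of planted regions; each a list with
#'   `origin` (1-based cube-grid indices), `size` (cubes per axis) and
#'   `strength` (inter-cube texture correlation in \[0, 1\]).
#' @param group_effect fractional reduction of planted strength in the
#'   patient group, in \[0, 1\].
#' @param covariate_coupling named length-2 vector (`control`, `patient`)
#'   in \[-1, 1\]: correlation between the SUVR-like covariate and the
#'   subject's latent connectivity factor.
#' @param subject_strength_sd SD of the multiplicative subject-level
#'   modulation of planted strength (default 0.25; 0 disables modulation).
#' @param age_mean,age_sd,suvr_mean,suvr_sd named length-2 vectors
#'   (`control`, `patient`).
#' @param confound_covariates couple age to the latent connectivity factor
#'   (default `FALSE`).
#' @param seed cohort master seed.
#' @return Object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(grid_shape = c(24, 24, 24),
                              voxel_size_mm = 2,
                              n_per_group = 15L,
                              smoothness_fwhm_mm = 6,
                              local_texture_corr = 0.85,
                              smooth_intensity_share = 0.15,
                              edge_block_specs = list(
                                list(origin = c(3, 3, 3), size = c(3, 3, 3),
                                     strength = 0.8)),
                              group_effect = 0.5,
                              covariate_coupling = c(control = 0.6,
                                                     patient = -0.6),
                              subject_strength_sd = 0.25,
                              age_mean = c(control = 68.1, patient = 69.5),
                              age_sd = c(control = 6.5, patient = 8.7),
                              suvr_mean = c(control = 1.14, patient = 1.49),
                              suvr_sd = c(control = 0.17, patient = 0.43),
                              confound_covariates = FALSE,
                              seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 12L))
    stop("configuration error: each grid axis must span at least 4 cube edges (12 voxels)")
  if (n_per_group < 3L) stop("`n_per_group` must be >= 3")
  if (group_effect < 0 || group_effect > 1)
    stop("`group_effect` must be in [0, 1]")
  if (local_texture_corr < 0 || local_texture_corr > 0.9)
    stop("`local_texture_corr` must be in [0, 0.9]")
  if (smooth_intensity_share < 0 || smooth_intensity_share > 1)
    stop("`smooth_intensity_share` must be in [0, 1]")
  if (length(covariate_coupling) != 2L || any(abs(covariate_coupling) > 1))
    stop("`covariate_coupling` must be two values in [-1, 1]")
  names(covariate_coupling) <- c("control", "patient")
  for (nm in c("age_mean", "age_sd", "suvr_mean", "suvr_sd")) {
    v <- get(nm)
    if (length(v) != 2L || (grepl("sd", nm) && any(v < 0)))
      stop("`", nm, "` must be two values (control, patient)")
    names(v) <- c("control", "patient")
    assign(nm, v)
  }
  ncube <- grid_shape %/% 3L
  for (spec in edge_block_specs) {
    stopifnot(is.list(spec), all(c("origin", "size", "strength") %in% names(spec)))
    if (spec$strength < 0 || spec$strength > 1)
      stop("planted `strength` must be in [0, 1]")
    if (any(spec$origin < 1L) || any(spec$origin + spec$size - 1L > ncube))
      stop("edge block exceeds the cube grid (", paste(ncube, collapse = "x"), ")")
  }
  cfg <- list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
              n_per_group = as.integer(n_per_group),
              smoothness_fwhm_mm = smoothness_fwhm_mm,
              local_texture_corr = local_texture_corr,
              smooth_intensity_share = smooth_intensity_share,
              edge_block_specs = edge_block_specs,
              group_effect = group_effect,
              covariate_coupling = covariate_coupling,
              subject_strength_sd = subject_strength_sd,
              age_mean = age_mean, age_sd = age_sd,
              suvr_mean = suvr_mean, suvr_sd = suvr_sd,
              confound_covariates = confound_covariates,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# cube-grid geometry shared by the simulator and the parcellation of a
# full (all-ones) mask: raster order over cube origins, first axis fastest
cube_grid_ids <- function(grid_shape) {
  nc <- grid_shape %/% 3L
  list(ncube = nc, n_nodes = prod(nc))
}

region_cube_ids <- function(spec, ncube) {
  ax <- lapply(1:3, function(a) spec$origin[a]:(spec$origin[a] + spec$size[a] - 1L))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  sort(g[, 1] + (g[, 2] - 1L) * ncube[1] + (g[, 3] - 1L) * ncube[1] * ncube[2])
}

#' Ground-truth structure of a simulation
#'
#' @param config a [simulation_config()].
#' @return List with `true_edges` (2-column matrix of node ids joined by a
#'   planted edge), `region_cube_ids` (list per planted region),
#'   `planted_region_mask` ([density_volume()] marking planted cubes) and
#'   `ncube`.
#' @export
simulation_ground_truth <- function(config) {
  nc <- cube_grid_ids(config$grid_shape)$ncube
  regions <- lapply(config$edge_block_specs, region_cube_ids, ncube = nc)
  edges <- do.call(rbind, lapply(regions, function(ids) {
    if (length(ids) < 2) return(NULL)
    t(utils::combn(ids, 2))
  }))
  mask <- array(0, config$grid_shape)
  for (ids in regions)
    for (id in ids) {
      a <- (id - 1L) %% nc[1]
      b <- ((id - 1L) %/% nc[1]) %% nc[2]
      c3 <- (id - 1L) %/% (nc[1] * nc[2])
      o <- c(a, b, c3) * 3L + 1L
      mask[o[1]:(o[1] + 2L), o[2]:(o[2] + 2L), o[3]:(o[3] + 2L)] <- 1
    }
  list(true_edges = edges, region_cube_ids = regions,
       planted_region_mask = density_volume(mask, config$voxel_size_mm),
       ncube = nc)
}

# 1D Gaussian kernel width (in cube units) whose moving average of white
# noise has lag-1 autocorrelation c0; radius fixed at 6 cubes.
texture_kernel <- function(c0, radius = 6L) {
  off <- (-radius):radius
  if (c0 <= 0) return(list(off = off, g = as.numeric(off == 0L)))
  f <- function(tau) {
    g <- exp(-off^2 / (2 * tau^2))
    sum(g[-1] * g[-length(g)]) / sum(g^2) - c0
  }
  tau <- uniroot(f, c(0.02, 50))$root
  list(off = off, g = exp(-off^2 / (2 * tau^2)))
}

# Moving-average smoothing of a 3D array along each axis with weights g
# (zero padding), then global re-standardization.
smooth_cube_field <- function(arr, kern) {
  for (axis in 1:3) {
    n <- dim(arr)[axis]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) for (t in seq_along(kern$off)) {
      j <- i + kern$off[t]
      if (j >= 1 && j <= n) K[i, j] <- kern$g[t]
    }
    arr <- apply_axis(arr, axis, K)
  }
  arr / sd(arr)
}

#' Simulate one subject's gray-matter density volume
#'
#' Each cube's 27 values are a variance-weighted mix of (a) a cube-level
#' latent texture field — 27 independent white-noise fields on the cube
#' grid, moving-average-smoothed so that neighbouring cubes' textures
#' correlate at `local_texture_corr` — and (b) a voxel-level random field
#' Gaussian-smoothed to `smoothness_fwhm_mm`. The texture field is what
#' carries true local edges (it survives only when spatial correspondence
#' is intact); the smooth field adds realistic intensity autocorrelation.
#' Inside each planted region a shared latent 27-vector is mixed into
#' every cube at the region's strength (reduced by `group_effect` for
#' patients and modulated by the subject's latent connectivity factor),
#' planting a clique of true edges. The final field is squashed affinely
#' to \[0, 1\], which leaves all Pearson correlations untouched. The
#' subject's SUVR-like covariate (coupled to the latent factor with the
#' group's sign) and age are drawn last. Deterministic given
#' `subject_seed`.
#'
#' @param config a [simulation_config()].
#' @param group `"control"` or `"patient"`.
#' @param subject_seed integer seed for this subject.
#' @return List with `volume` ([density_volume()]), `suvr`, `age`,
#'   `latent_factor`, `planted_strength` (per region, after group and
#'   subject modulation) and `ground_truth` (see
#'   [simulation_ground_truth()]).
#' @export
generate_subject <- function(config, group = c("control", "patient"),
                             subject_seed) {
  stopifnot(inherits(config, "simulation_config"))
  group <- match.arg(group)
  gt <- simulation_ground_truth(config)
  dm <- config$grid_shape
  vz <- config$voxel_size_mm

  res <- with_seed(subject_seed, {
    f <- rnorm(1)
    nc <- gt$ncube
    kern <- texture_kernel(config$local_texture_corr)
    Tf <- array(0, c(nc, 27))
    for (k in 1:27)
      Tf[, , , k] <- smooth_cube_field(array(rnorm(prod(nc)), nc), kern)

    smooth_f <- array(rnorm(prod(dm)), dm)
    smooth_f <- smooth_volume(density_volume(smooth_f, vz),
                              fwhm_mm = config$smoothness_fwhm_mm,
                              boundary = "nearest")$data

    a_s <- config$smooth_intensity_share
    field <- array(0, dm)
    for (a in seq_len(nc[1])) for (b in seq_len(nc[2]))
      for (c3 in seq_len(nc[3])) {
        o <- (c(a, b, c3) - 1L) * 3L + 1L
        sl <- lapply(o, function(x) x:(x + 2L))
        sc <- smooth_f[sl[[1]], sl[[2]], sl[[3]]]
        scs <- sd(sc)
        sc <- if (scs > 0) (sc - mean(sc)) / scs else sc * 0
        v <- sqrt(a_s) * as.vector(sc) + sqrt(1 - a_s) * Tf[a, b, c3, ]
        field[sl[[1]], sl[[2]], sl[[3]]] <- array(v, c(3, 3, 3))
      }

    strengths <- numeric(length(config$edge_block_specs))
    for (ri in seq_along(config$edge_block_specs)) {
      spec <- config$edge_block_specs[[ri]]
      s <- spec$strength
      if (group == "patient") s <- s * (1 - config$group_effect)
      s <- s * (1 + config$subject_strength_sd * f)
      s <- min(max(s, 0), 1)
      strengths[ri] <- s
      if (s > 0) {
        z <- rnorm(27)
        z <- (z - mean(z)) / sd(z)
        for (id in gt$region_cube_ids[[ri]]) {
          a <- (id - 1L) %% gt$ncube[1]
          b <- ((id - 1L) %/% gt$ncube[1]) %% gt$ncube[2]
          c3 <- (id - 1L) %/% (gt$ncube[1] * gt$ncube[2])
          o <- c(a, b, c3) * 3L + 1L
          sl <- lapply(o, function(x) x:(x + 2L))
          cube <- field[sl[[1]], sl[[2]], sl[[3]]]
          cs <- sd(cube)
          cube <- if (cs > 0) (cube - mean(cube)) / cs else cube * 0
          mixed <- sqrt(s) * z + sqrt(1 - s) * as.vector(cube)
          field[sl[[1]], sl[[2]], sl[[3]]] <- array(mixed, c(3, 3, 3))
        }
      }
    }

    rho <- unname(config$covariate_coupling[group])
    suvr_z <- rho * f + sqrt(1 - rho^2) * rnorm(1)
    suvr <- max(config$suvr_mean[group] + config$suvr_sd[group] * suvr_z, 0.05)
    age <- config$age_mean[group] + config$age_sd[group] * rnorm(1)
    if (config$confound_covariates) age <- age + 3 * f
    age <- max(age, 40)
    list(field = field, f = f, strengths = strengths,
         suvr = unname(suvr), age = unname(age))
  })

  rng <- range(res$field)
  vol01 <- (res$field - rng[1]) / (rng[2] - rng[1]) # affine: correlations kept
  list(volume = density_volume(vol01, vz),
       suvr = res$suvr, age = res$age, latent_factor = res$f,
       planted_strength = res$strengths, ground_truth = gt)
}

#' Simulate a full two-group cohort
#'
#' Generates `2 * n_per_group` subjects (controls then patients) with
#' per-subject seeds derived from the cohort seed, a balanced sex
#' assignment, and the covariate table. Optionally writes per-subject
#' NIfTI volumes, the all-ones analysis mask, the covariate CSV and a JSON
#' ground-truth sidecar to `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory, or `NULL` (in-memory only).
#' @return List with `table` (data.frame: subject_id, group, age, sex,
#'   suvr, latent_factor, volume_path), `volumes` (list of
#'   [density_volume()]), `mask`, `ground_truth`, `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_per_group
  groups <- rep(c("control", "patient"), each = n)
  seeds <- with_seed(config$seed, sample.int(2147483646L, 2L * n))
  sex <- c(rep_len(c("F", "M"), n), rep_len(c("F", "M"), n))
  ids <- sprintf("sub-%s%02d", ifelse(groups == "control", "c", "p"),
                 c(seq_len(n), seq_len(n)))

  subs <- vector("list", 2L * n)
  for (i in seq_along(subs))
    subs[[i]] <- generate_subject(config, groups[i], seeds[i])

  gt <- subs[[1]]$ground_truth
  mask <- density_volume(array(1, config$grid_shape), config$voxel_size_mm)
  tab <- data.frame(subject_id = ids, group = groups,
                    age = vapply(subs, `[[`, numeric(1), "age"),
                    sex = sex,
                    suvr = vapply(subs, `[[`, numeric(1), "suvr"),
                    latent_factor = vapply(subs, `[[`, numeric(1),
                                           "latent_factor"),
                    subject_seed = seeds,
                    volume_path = NA_character_,
                    stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
    for (i in seq_along(subs)) {
      p <- file.path(out_dir, paste0(ids[i], "_gm.nii.gz"))
      write_volume(subs[[i]]$volume, p)
      tab$volume_path[i] <- p
    }
    write_volume(mask, file.path(out_dir, "mask.nii.gz"))
    tab_csv <- tab
    tab_csv$volume_path <- basename(tab$volume_path) # run-reproducible CSV
    write.csv(tab_csv, file.path(out_dir, "covariates.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(true_edges = gt$true_edges,
           region_cube_ids = gt$region_cube_ids,
           ncube = gt$ncube,
           seed = config$seed,
           subject_seeds = seeds),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }

  list(table = tab, volumes = lapply(subs, `[[`, "volume"), mask = mask,
       ground_truth = gt, config = config)
}
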