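#' Standardized uptake value ratio (SUVR)
#'
#' Mean of the positive voxels of a PET volume inside the target ROI,
#' divided by the mean of the positive voxels inside the reference ROI
#' (e.g. cerebellar gray matter). Negative reconstruction-noise voxels are
#' excluded from both means.
#'
#' @param pet PET uptake volume ([density_volume()] or 3D array).
#' @param target_roi,reference_roi binary masks on the PET grid.
#' @return SUVR scalar.
#' @export
compute_suvr <- function(pet, target_roi, reference_roi) {
  pet <- as_density_volume(pet)$data
  t_roi <- as_density_volume(target_roi)$data != 0
  r_roi <- as_density_volume(reference_roi)$data != 0
  if (!any(t_roi) || !any(r_roi)) stop("empty ROI on the PET grid")
  ref_vals <- pet[r_roi & pet > 0]
  if (length(ref_vals) == 0 || mean(ref_vals) <= 0)
    stop("reference ROI has non-positive mean uptake")
  tgt_vals <- pet[t_roi & pet > 0]
  if (length(tgt_vals) == 0) return(0)
  mean(tgt_vals) / mean(ref_vals)
}

#' Two-sample comparison of a scalar across groups
#'
#' Unpaired t-test (pooled variance by default) of a scalar per-subject
#' quantity between two groups.
#'
#' @param values numeric vector.
#' @param groups factor/vector with exactly two levels.
#' @param var_equal pooled-variance t (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return List with `t`, `df`, `p`, and the two group `means`.
#' @export
compare_groups_scalar <- function(values, groups, var_equal = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  tt <- t.test(values ~ groups, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = tt$estimate)
}

#' Pearson chi-square test of a categorical variable across groups
#'
#' Pearson's chi-square on the 2-way contingency table, without continuity
#' correction. Used for demographic sex-by-group tables.
#'
#' @param x categorical vector.
#' @param groups group labels.
#' @return List with `chisq`, `df`, `p` and the `table`.
#' @export
compare_groups_categorical <- function(x, groups) {
  tab <- table(x, groups)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' ANCOVA on a global network metric
#'
#' Linear model `metric ~ group + age + sex`; reports the test of the
#' group effect adjusted for the age and sex nuisance covariates.
#'
#' @param values per-subject metric (e.g. gamma, lambda or sigma).
#' @param group two-level group labels.
#' @param age,sex nuisance covariates (sex may be a factor or binary).
#' @return List with `t`, `F` (= t^2), `df`, `p`, `estimate` (adjusted
#'   group difference) and the fitted `model`.
#' @export
ancova_global <- function(values, group, age, sex) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("`group` must have exactly two levels")
  dat <- data.frame(y = values, group = group, age = age, sex = factor(sex))
  fit <- lm(y ~ group + age + sex, data = dat)
  co <- summary(fit)$coefficients
  row <- grep("^group", rownames(co))[1]
  list(t = co[row, "t value"], F = co[row, "t value"]^2,
       df = fit$df.residual, p = co[row, "Pr(>|t|)"],
       estimate = co[row, "Estimate"], model = fit)
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' the covariates; the p-value uses a t-distribution with
#' `n - 2 - n_covariates` degrees of freedom. With no covariates this is
#' the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates, or `NULL`.
#' @return List with `r`, `df`, `t`, `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    rx <- x - mean(x)
    ry <- y - mean(y)
    k <- 0L
  } else {
    Z <- model_matrix_covariates(covariates)
    stopifnot(nrow(Z) == n)
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
    k <- ncol(Z) - 1L # intercept not counted as a covariate
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, df = df, t = tval, p = p)
}

# intercept + numeric columns; factors become indicator columns
model_matrix_covariates <- function(covariates) {
  d <- as.data.frame(covariates)
  stats::model.matrix(~ ., data = d)
}

# Stack metric volumes / arrays into a subjects x voxels matrix.
stack_maps <- function(maps) {
  arrs <- lapply(maps, function(m) as_density_volume(m)$data)
  dm <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) all(dim(a) == dm), logical(1))))
    stop("all maps must share one grid")
  Y <- t(vapply(arrs, as.vector, numeric(prod(dm))))
  attr(Y, "grid_dim") <- dm
  Y
}

#' Voxel-wise general linear model
#'
#' Ordinary-least-squares fit of each voxel's values across subjects on a
#' design matrix, with a t statistic for one contrast. Voxels with zero
#' variance across subjects (or outside `mask`) are excluded (`NA` in the
#' t-map). Supports the study designs: two-sample group difference with
#' age/sex nuisances, and per-group multiple regression on a covariate of
#' interest (e.g. SUVR) with age/sex nuisances.
#'
#' @param maps list of per-subject `metric_volume`s (or 3D arrays), or a
#'   subjects x voxels matrix.
#' @param design data.frame of per-subject covariates (factors allowed) or
#'   a full design matrix including an intercept.
#' @param contrast name of the design column of interest, or a numeric
#'   contrast vector over the design-matrix columns.
#' @param mask optional binary volume restricting the analysis.
#' @return List with `t` (3D t-map array, `NA` outside the analysis mask),
#'   `df` (residual degrees of freedom), `contrast_name`, `grid_dim`, and
#'   `X` (the design matrix used).
#' @export
voxelwise_glm <- function(maps, design, contrast, mask = NULL) {
  Y <- if (is.matrix(maps) && is.null(attr(maps, "grid_dim"))) maps
       else if (is.matrix(maps)) maps else stack_maps(maps)
  grid_dim <- attr(Y, "grid_dim")
  X <- if (is.matrix(design)) design else model_matrix_covariates(design)
  n <- nrow(X)
  if (nrow(Y) != n) stop("number of maps must match design rows")
  if (n <= ncol(X) + 1L) stop("need n > number of predictors + 1")
  cc <- contrast_vector(contrast, X)

  keep <- apply(Y, 2, var) > 0
  if (!is.null(mask)) {
    mk <- as_density_volume(mask)$data != 0
    keep <- keep & as.vector(mk)
  }
  tvals <- rep(NA_real_, ncol(Y))
  df <- n - ncol(X)
  if (any(keep)) {
    XtXi <- chol2inv(chol(crossprod(X)))
    Yk <- Y[, keep, drop = FALSE]
    B <- XtXi %*% crossprod(X, Yk)
    res <- Yk - X %*% B
    sigma2 <- colSums(res^2) / df
    se <- sqrt(pmax(sigma2, 0) * drop(t(cc) %*% XtXi %*% cc))
    tk <- drop(crossprod(cc, B)) / se
    tk[se == 0] <- NA_real_
    tvals[keep] <- tk
  }
  tmap <- if (is.null(grid_dim)) tvals else array(tvals, grid_dim)
  list(t = tmap, df = df,
       contrast_name = if (is.character(contrast)) contrast else "contrast",
       grid_dim = grid_dim, X = X)
}

contrast_vector <- function(contrast, X) {
  if (is.character(contrast)) {
    hit <- grep(paste0("^", contrast), colnames(X))
    if (length(hit) == 0) stop("contrast column not found: ", contrast)
    cc <- rep(0, ncol(X))
    cc[hit[1]] <- 1
    cc
  } else {
    stopifnot(length(contrast) == ncol(X))
    as.numeric(contrast)
  }
}

#' Cluster-extent thresholding of a t-map
#'
#' Thresholds a t-map at the height corresponding to the chosen threshold
#' (one-sided, positive direction: negate the map for the negative
#' direction), labels the supra-threshold voxels into 26-connected
#' components, and discards clusters smaller than the extent threshold
#' (default 50 voxels). The height can be given directly (`t_threshold`,
#' e.g. from a permutation max-t distribution for family-wise error
#' control) or as an uncorrected parametric height p-value (`height_p`
#' with `df`, e.g. the exploratory p < .001 mode).
#'
#' @param tmap 3D array of t statistics (`NA` = outside analysis mask).
#' @param t_threshold height threshold on the t statistic.
#' @param height_p uncorrected height p-value (used when `t_threshold` is
#'   missing; requires `df`).
#' @param df residual degrees of freedom for `height_p`.
#' @param extent_voxels minimum cluster size in voxels (default 50).
#' @param connectivity 6, 18 or 26 (default 26; SPM convention).
#' @param affine optional voxel-to-world matrix for peak mm coordinates.
#' @return `data.frame` with one row per surviving cluster: `cluster_size`,
#'   `peak_t`, `peak_i/j/k` (0-based voxel), `peak_x/y/z_mm` (when affine
#'   given), sorted by decreasing size.
#' @export
cluster_extent <- function(tmap, t_threshold = NULL, height_p = NULL,
                           df = NULL, extent_voxels = 50L,
                           connectivity = 26L, affine = NULL) {
  if (inherits(tmap, "density_volume")) {
    if (is.null(affine)) affine <- tmap$affine
    tmap <- tmap$data
  }
  stopifnot(length(dim(tmap)) == 3L)
  if (is.null(t_threshold)) {
    if (is.null(height_p) || is.null(df))
      stop("give `t_threshold`, or `height_p` together with `df`")
    t_threshold <- qt(1 - height_p, df)
  }
  supra <- !is.na(tmap) & tmap > t_threshold
  empty <- data.frame(cluster_size = integer(0), peak_t = numeric(0),
                      peak_i = integer(0), peak_j = integer(0),
                      peak_k = integer(0))
  if (!any(supra)) return(empty)
  lab <- array(cpp_label_components(as.vector(supra), dim(tmap),
                                    as.integer(connectivity)), dim(tmap))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= extent_voxels)
  if (length(keep) == 0) return(empty)
  rows <- lapply(keep, function(cl) {
    vox <- which(lab == cl)
    peak <- vox[which.max(tmap[vox])]
    ijk <- arrayInd(peak, dim(tmap)) - 1L
    data.frame(cluster_size = sizes[cl], peak_t = tmap[peak],
               peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$cluster_size), , drop = FALSE]
  if (!is.null(affine)) {
    mm <- voxel_to_world(as.matrix(out[, c("peak_i", "peak_j", "peak_k")]),
                         affine)
    out$peak_x_mm <- mm[, 1]; out$peak_y_mm <- mm[, 2]; out$peak_z_mm <- mm[, 3]
  }
  rownames(out) <- NULL
  out
}

#' Permutation-based family-wise error correction (max statistic)
#'
#' Freedman-Lane permutation for one contrast of a voxel-wise GLM: the
#' outcome maps are residualized on the nuisance part of the design, the
#' residual rows are permuted, the nuisance fit is added back, and the full
#' model is refit; the maximum statistic over voxels is recorded for each
#' permutation. The corrected p-value of a voxel is the rank of its
#' observed statistic within the max-statistic distribution (with
#' (r+1)/(n+1) smoothing). Exact under exchangeability, and free of the
#' smoothness assumptions of random-field theory.
#'
#' @inheritParams voxelwise_glm
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed RNG seed (restored on exit).
#' @param alternative `"two.sided"` (max |t|, default), `"greater"` or
#'   `"less"`.
#' @return List with `t` (observed t-map), `p_fwe` (corrected p-map),
#'   `max_dist` (permutation max-statistic distribution),
#'   `t_fwe05` (the 95th percentile of `max_dist`: the FWE-corrected
#'   height threshold at alpha = .05), and `df`.
#' @export
permutation_fwe <- function(maps, design, contrast, n_perm = 1000L,
                            seed = 1L, mask = NULL,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) warning("fewer than 100 permutations")
  Y <- if (is.matrix(maps)) maps else stack_maps(maps)
  grid_dim <- attr(Y, "grid_dim")
  X <- if (is.matrix(design)) design else model_matrix_covariates(design)
  cc <- contrast_vector(contrast, X)
  n <- nrow(X)

  obs <- voxelwise_glm(Y, X, cc, mask = mask)
  stat_of <- function(tv) switch(alternative,
                                 two.sided = abs(tv),
                                 greater = tv,
                                 less = -tv)
  obs_stat <- stat_of(obs$t)

  # nuisance-only model (columns not involved in the contrast)
  nuis_cols <- which(cc == 0)
  Z <- X[, nuis_cols, drop = FALSE]
  if (ncol(Z) == 0) Z <- matrix(1, n, 1)
  Zq <- qr(Z)
  fitted_Z <- qr.fitted(Zq, Y)
  resid_Z <- Y - fitted_Z

  max_dist <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pe <- sample.int(n)
      Yb <- fitted_Z + resid_Z[pe, , drop = FALSE]
      attr(Yb, "grid_dim") <- NULL
      tb <- voxelwise_glm(Yb, X, cc)$t
      mx <- suppressWarnings(max(stat_of(tb), na.rm = TRUE))
      if (!is.finite(mx)) 0 else mx
    }, numeric(1))
  })

  flat_obs <- as.vector(obs_stat)
  p <- rep(NA_real_, length(flat_obs))
  ok <- !is.na(flat_obs)
  srt <- sort(max_dist)
  p[ok] <- (length(srt) - findInterval(flat_obs[ok], srt, left.open = TRUE) + 1) /
    (n_perm + 1)
  p_map <- if (is.null(grid_dim)) p else array(p, grid_dim)
  list(t = obs$t, p_fwe = p_map, max_dist = max_dist,
       t_fwe05 = quantile(max_dist, 0.95, names = FALSE, type = 1),
       df = obs$df)
}
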