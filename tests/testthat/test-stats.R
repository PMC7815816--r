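test_that("SUVR is the ratio of positive-voxel ROI means", {
  dm <- c(4, 4, 4)
  ones <- array(1, dm)
  pet2 <- array(2, dm)
  tgt <- array(0, dm); tgt[1:2, , ] <- 1
  ref <- array(0, dm); ref[3:4, , ] <- 1
  expect_equal(compute_suvr(pet2, tgt, ref), 1)

  pet <- array(0, dm)
  pet[1:2, , ] <- 3
  pet[3:4, , ] <- 2
  expect_equal(compute_suvr(pet, tgt, ref), 1.5)

  # hand computation on a 4-voxel toy: negatives excluded from both means
  pet_neg <- array(0, c(4, 1, 1))
  pet_neg[, 1, 1] <- c(3, -1, 2, -0.5)
  t4 <- array(c(1, 1, 0, 0), c(4, 1, 1))
  r4 <- array(c(0, 0, 1, 1), c(4, 1, 1))
  expect_equal(compute_suvr(pet_neg, t4, r4), 3 / 2) # mean(3)/mean(2)

  neg_ref <- array(-1, dm)
  neg_ref[1:2, , ] <- 2
  expect_error(compute_suvr(neg_ref, tgt, ref), "non-positive")
  expect_error(compute_suvr(pet2, array(0, dm), ref), "empty ROI")
})

test_that("two-sample t matches the closed form and degenerates correctly", {
  res <- compare_groups_scalar(c(1, 2, 3, 4, 5, 6),
                               rep(c("a", "b"), each = 3))
  # pooled t for {1,2,3} vs {4,5,6}: diff -3, s_p = 1, se = sqrt(2/3)
  expect_equal(res$t, -3 / sqrt(2 / 3))
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4))

  same <- compare_groups_scalar(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("label-permutation p agrees with the parametric two-sample p", {
  set.seed(10)
  x <- c(rnorm(12), rnorm(12, mean = 1.2))
  g <- rep(c("a", "b"), each = 12)
  t_obs <- abs(compare_groups_scalar(x, g)$t)
  perm_t <- replicate(2000, abs(compare_groups_scalar(x, sample(g))$t))
  p_perm <- (sum(perm_t >= t_obs) + 1) / 2001
  p_par <- compare_groups_scalar(x, g)$p
  expect_equal(p_perm, p_par, tolerance = 0.02)
})

test_that("Pearson chi-square without continuity correction", {
  sex <- c(rep("F", 12), rep("M", 6), rep("F", 20), rep("M", 10))
  grp <- c(rep("patient", 18), rep("control", 30))
  res <- compare_groups_categorical(sex, grp)
  oracle <- suppressWarnings(chisq.test(table(sex, grp), correct = FALSE))
  expect_equal(res$chisq, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  # perfectly balanced 2:1 ratios are independent of group
  expect_equal(res$chisq, 0)
})

test_that("ANCOVA group test equals the model-comparison F test", {
  set.seed(20)
  n <- 30
  grp <- rep(c("control", "patient"), each = n / 2)
  age <- rnorm(n, 68, 6)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  y <- 1.5 - 0.1 * (grp == "patient") + 0.002 * age + rnorm(n, 0, 0.05)
  res <- ancova_global(y, grp, age, sex)
  full <- lm(y ~ factor(grp) + age + factor(sex))
  red <- lm(y ~ age + factor(sex))
  an <- anova(red, full)
  expect_equal(res$F, an$F[2])
  expect_equal(res$p, an$`Pr(>F)`[2])
  expect_equal(res$df, full$df.residual)
})

test_that("ANCOVA detects a planted group shift in sigma with high power", {
  set.seed(30)
  n <- 15
  rejections <- vapply(1:40, function(r) {
    grp <- rep(c("control", "patient"), each = n)
    age <- rnorm(2 * n, 68, 7)
    sex <- rep_len(c("F", "M"), 2 * n)
    # shift comparable to the reported group difference (~0.1, sd ~0.08)
    sigma <- 1.46 - 0.1 * (grp == "patient") + rnorm(2 * n, 0, 0.08)
    ancova_global(sigma, grp, age, sex)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("partial correlation reduces to Pearson and removes shared covariates", {
  set.seed(40)
  x <- rnorm(25)
  y <- 2 * x + rnorm(25)
  no_cov <- partial_correlation(x, y)
  expect_equal(no_cov$r, cor(x, y))
  expect_equal(no_cov$p, cor.test(x, y)$p.value)
  expect_equal(partial_correlation(x, x)$r, 1)

  # x and y linear in age + independent noise: raw r large, partial r ~ 0
  raw_r <- partial_r <- numeric(30)
  for (r in 1:30) {
    age <- rnorm(40, 70, 8)
    x <- 0.1 * age + rnorm(40)
    y <- -0.08 * age + rnorm(40)
    raw_r[r] <- cor(x, y)
    partial_r[r] <- partial_correlation(x, y, data.frame(age = age))$r
  }
  expect_lt(abs(mean(partial_r)), 0.08)
  expect_gt(abs(mean(raw_r)), 0.3)
})

test_that("voxelwise GLM equals per-voxel lm fits", {
  set.seed(50)
  n <- 12
  V <- 40
  Y <- matrix(rnorm(n * V), n, V)
  Y[, 3] <- 1 # zero variance voxel
  des <- data.frame(suvr = rnorm(n, 1.2, 0.2), age = rnorm(n, 68, 5),
                    sex = factor(rep_len(c("F", "M"), n)))
  fit <- voxelwise_glm(Y, des, "suvr")
  expect_true(is.na(fit$t[3]))
  for (v in c(1, 2, 10, 40)) {
    lmv <- summary(lm(Y[, v] ~ suvr + age + sex, data = des))$coefficients
    expect_equal(fit$t[v], lmv["suvr", "t value"])
  }
  expect_equal(fit$df, n - 4)
})

test_that("cluster extent thresholding keeps only big supra-threshold components", {
  tm <- array(0, c(12, 12, 12))
  expect_equal(nrow(cluster_extent(tm, t_threshold = 3)), 0L)

  # one 60-voxel blob above threshold -> a single cluster of size 60
  tm[3:7, 3:6, 3:5] <- 5 # 5*4*3 = 60
  res <- cluster_extent(tm, t_threshold = 3, extent_voxels = 50)
  expect_equal(nrow(res), 1L)
  expect_equal(res$cluster_size, 60L)
  expect_equal(res$peak_t, 5)

  # a 40-voxel blob dies at the 50-voxel extent threshold
  tm40 <- array(0, c(12, 12, 12))
  tm40[3:7, 3:6, 3:4] <- 5 # 40
  expect_equal(nrow(cluster_extent(tm40, t_threshold = 3,
                                   extent_voxels = 50)), 0L)
  expect_equal(cluster_extent(tm40, t_threshold = 3,
                              extent_voxels = 40)$cluster_size, 40L)

  # height from an uncorrected p: threshold at qt(1 - p, df)
  tm_p <- array(0, c(8, 8, 8))
  tm_p[2:6, 2:6, 2:5] <- 5 # 100 voxels at t = 5 > qt(.999, 10) = 4.14
  res_p <- cluster_extent(tm_p, height_p = 0.001, df = 10,
                          extent_voxels = 50)
  expect_equal(nrow(res_p), 1L)
  expect_equal(nrow(cluster_extent(tm_p, height_p = 1e-6, df = 10,
                                   extent_voxels = 50)), 0L)
  expect_error(cluster_extent(tm_p, height_p = 0.001), "df")
})

test_that("corner-touching voxels merge under 26- but not 6-connectivity", {
  tm <- array(0, c(6, 6, 6))
  tm[1:3, 1:3, 1:3] <- 5
  tm[4:6, 4:6, 4:6] <- 5 # touches only at the (3,3,3)/(4,4,4) corner
  r26 <- cluster_extent(tm, t_threshold = 1, extent_voxels = 1,
                        connectivity = 26)
  r6 <- cluster_extent(tm, t_threshold = 1, extent_voxels = 1,
                       connectivity = 6)
  expect_equal(nrow(r26), 1L)
  expect_equal(r26$cluster_size, 54L)
  expect_equal(nrow(r6), 2L)
})

test_that("peak world coordinates follow the affine", {
  tm <- array(0, c(6, 6, 6))
  tm[4, 5, 2] <- 9
  tm[4, 5, 3] <- 8
  res <- cluster_extent(tm, t_threshold = 1, extent_voxels = 1,
                        affine = diag(c(2, 2, 2, 1)))
  expect_equal(res$cluster_size, 2L)
  expect_equal(c(res$peak_i, res$peak_j, res$peak_k), c(3, 4, 1))
  expect_equal(c(res$peak_x_mm, res$peak_y_mm, res$peak_z_mm), c(6, 8, 2))
})

test_that("permutation FWE is seed-deterministic and flags a huge effect", {
  set.seed(60)
  n <- 16
  V <- 30
  covar <- rnorm(n)
  Y <- matrix(rnorm(n * V), n, V)
  Y[, 7] <- 3 * covar + rnorm(n, 0, 0.3) # massive effect at voxel 7
  des <- data.frame(covar = covar, age = rnorm(n, 68, 5))
  p1 <- permutation_fwe(Y, des, "covar", n_perm = 300, seed = 5)
  p2 <- permutation_fwe(Y, des, "covar", n_perm = 300, seed = 5)
  expect_identical(p1$p_fwe, p2$p_fwe)
  expect_lt(p1$p_fwe[7], 0.05)
  expect_gt(min(p1$p_fwe[-7]), 0.2)
  expect_warning(permutation_fwe(Y, des, "covar", n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("permutation FWE p-values are valid under the null", {
  # observed t replaced into its own permutation distribution: p ~ U with
  # discrete support; check the corrected p at a null voxel is not tiny
  set.seed(70)
  n <- 14
  Y <- matrix(rnorm(n * 20), n, 20)
  des <- data.frame(covar = rnorm(n), age = rnorm(n))
  res <- permutation_fwe(Y, des, "covar", n_perm = 200, seed = 9)
  expect_gt(min(res$p_fwe), 1 / 201)
  expect_true(all(res$p_fwe <= 1))
})
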