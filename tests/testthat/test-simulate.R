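test_that("configuration invariants are enforced", {
  expect_error(simulation_config(grid_shape = c(11, 12, 12)), "4 cube edges")
  expect_error(simulation_config(n_per_group = 2), ">= 3")
  expect_error(simulation_config(group_effect = 1.2), "group_effect")
  expect_error(simulation_config(covariate_coupling = c(1.5, -0.6)),
               "covariate_coupling")
  expect_error(simulation_config(
    grid_shape = c(12, 12, 12),
    edge_block_specs = list(list(origin = c(3, 3, 3), size = c(3, 3, 3),
                                 strength = 0.8))),
    "exceeds the cube grid")
  expect_error(simulation_config(
    edge_block_specs = list(list(origin = c(1, 1, 1), size = c(2, 2, 2),
                                 strength = 1.4))),
    "strength")
})

test_that("subject simulation is bit-deterministic and bounded in [0, 1]", {
  cfg <- simulation_config(grid_shape = c(15, 15, 15), n_per_group = 3,
                           edge_block_specs = list(
                             list(origin = c(2, 2, 2), size = c(2, 2, 2),
                                  strength = 0.8)))
  a <- generate_subject(cfg, "control", subject_seed = 7)
  b <- generate_subject(cfg, "control", subject_seed = 7)
  c2 <- generate_subject(cfg, "control", subject_seed = 8)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$suvr, b$suvr)
  expect_false(identical(a$volume$data, c2$volume$data))
  expect_true(all(a$volume$data >= 0 & a$volume$data <= 1))
})

test_that("strength-1 planting yields exact orientation-maximized similarity 1", {
  cfg <- simulation_config(grid_shape = c(15, 15, 15), n_per_group = 3,
                           subject_strength_sd = 0,
                           edge_block_specs = list(
                             list(origin = c(2, 2, 2), size = c(2, 2, 2),
                                  strength = 1)))
  sub <- generate_subject(cfg, "control", subject_seed = 3)
  nodes <- parcellate_cubes(sub$volume)
  ids <- sub$ground_truth$region_cube_ids[[1]]
  S <- similarity_matrix(nodes)
  expect_equal(unname(S[ids, ids]),
               matrix(1, length(ids), length(ids)))
})

test_that("every true edge joins two retained cube nodes", {
  cfg <- simulation_config(grid_shape = c(15, 15, 15), n_per_group = 3,
                           edge_block_specs = list(
                             list(origin = c(2, 2, 2), size = c(3, 3, 3),
                                  strength = 0.8)))
  gt <- simulation_ground_truth(cfg)
  nodes <- parcellate_cubes(generate_subject(cfg, "control", 1)$volume)
  n_nodes <- nrow(nodes$values)
  expect_true(all(gt$true_edges >= 1 & gt$true_edges <= n_nodes))
  expect_equal(nrow(gt$true_edges), choose(27, 2))
  # the planted mask marks exactly the region's cubes
  expect_equal(sum(gt$planted_region_mask$data), 27 * 27)
})

test_that("patient-group planted strength is reduced by the group effect", {
  cfg <- simulation_config(grid_shape = c(15, 15, 15), n_per_group = 3,
                           group_effect = 0.5, subject_strength_sd = 0,
                           edge_block_specs = list(
                             list(origin = c(2, 2, 2), size = c(2, 2, 2),
                                  strength = 0.8)))
  ctl <- generate_subject(cfg, "control", 5)
  pat <- generate_subject(cfg, "patient", 5)
  expect_equal(ctl$planted_strength, 0.8)
  expect_equal(pat$planted_strength, 0.4)
})

test_that("planted degradation lowers patient clustering inside the region", {
  # paired replicates: same seeds, the two groups differ only in the
  # planted-strength reduction; compare mean clustering over the region
  cfg <- simulation_config(grid_shape = c(15, 15, 15), n_per_group = 3,
                           group_effect = 0.5, subject_strength_sd = 0,
                           edge_block_specs = list(
                             list(origin = c(2, 2, 2), size = c(3, 3, 3),
                                  strength = 0.8)))
  ids <- simulation_ground_truth(cfg)$region_cube_ids[[1]]
  diffs <- vapply(1:20, function(r) {
    creg <- vapply(c("control", "patient"), function(g) {
      sub <- generate_subject(cfg, g, subject_seed = 1000 + r)
      net <- gm_network(sub$volume, n_null = 2000, seed = r, mu = 1,
                        include_betweenness = FALSE)
      mean(net$node_metrics$c[ids])
    }, numeric(1))
    creg["control"] - creg["patient"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("cohort generation is reproducible, balanced, and writes its files", {
  cfg <- simulation_config(grid_shape = c(12, 12, 12), n_per_group = 4,
                           edge_block_specs = list(
                             list(origin = c(1, 1, 1), size = c(2, 2, 2),
                                  strength = 0.8)),
                           seed = 99)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$table, co2$table)
  expect_identical(co1$volumes[[3]]$data, co2$volumes[[3]]$data)
  expect_equal(nrow(co1$table), 8L)
  expect_equal(as.vector(table(co1$table$group)), c(4L, 4L))
  expect_equal(as.vector(table(co1$table$sex, co1$table$group)),
               rep(2L, 4))
  expect_true(all(co1$table$suvr > 0))
  expect_true(all(co1$table$age > 0))

  out <- file.path(tempdir(), "graynet-cohort-test")
  on.exit(unlink(out, recursive = TRUE))
  co3 <- generate_cohort(cfg, out_dir = out)
  expect_true(all(file.exists(co3$table$volume_path)))
  expect_true(file.exists(file.path(out, "mask.nii.gz")))
  expect_true(file.exists(file.path(out, "covariates.csv")))
  gt_json <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                                 simplifyVector = TRUE)
  expect_equal(gt_json$seed, 99)
  expect_equal(nrow(gt_json$true_edges), choose(8, 2))
  # a written volume reads back to the same field (single precision)
  rb <- read_volume(co3$table$volume_path[1])
  expect_equal(rb$data, co3$volumes[[1]]$data, tolerance = 1e-6)
})

test_that("SUVR couples to the latent connectivity factor with the group sign", {
  cfg <- simulation_config(grid_shape = c(12, 12, 12), n_per_group = 60,
                           edge_block_specs = list(),
                           covariate_coupling = c(control = 0.6,
                                                  patient = -0.6),
                           seed = 7)
  co <- generate_cohort(cfg)
  ctl <- co$table$group == "control"
  r_ctl <- cor(co$table$latent_factor[ctl], co$table$suvr[ctl])
  r_pat <- cor(co$table$latent_factor[!ctl], co$table$suvr[!ctl])
  expect_gt(r_ctl, 0.3)
  expect_lt(r_pat, -0.3)
  # age and sex are independent of the factor by default
  expect_lt(abs(cor(co$table$latent_factor, co$table$age)), 0.25)
})
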