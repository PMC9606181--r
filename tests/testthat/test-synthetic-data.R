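test_that("target correlation handles independence, blocks and the hub cap", {
  regions <- paste0("R", 1:6)
  # independence: one module with zero internal correlation
  p0 <- planted_structure(setNames(rep(1L, 6), regions),
                          within_module_r = 0, between_module_r = 0)
  expect_equal(build_target_correlation(p0),
               diag(6) + 0, ignore_attr = TRUE)

  # two modules of three regions: exact block structure, PSD by direct
  # eigendecomposition
  p2 <- planted_structure(setNames(rep(1:2, each = 3), regions),
                          within_module_r = 0.8, between_module_r = 0)
  tc <- build_target_correlation(p2)
  expect_equal(unname(diag(tc)), rep(1, 6))
  expect_equal(unname(tc[1, 2]), 0.8)
  expect_equal(unname(tc[1, 4]), 0)
  expect_true(min(eigen(tc, symmetric = TRUE)$values) >= -1e-12)

  # hub boost capped below 1
  ph <- planted_structure(setNames(rep(1L, 6), regions),
                          within_module_r = 0.9, between_module_r = 0,
                          hub_regions = "R1", hub_extra_r = 0.5)
  raw_target <- 0.9 + 0.5
  expect_gt(raw_target, 1)  # cap must engage
  tch <- build_target_correlation(ph)
  expect_true(all(tch[upper.tri(tch)] <= 0.99 + 1e-12))

  # invalid parameters rejected
  expect_error(planted_structure(setNames(rep(1L, 6), regions),
                                 within_module_r = 1), "within_module_r")
  expect_error(planted_structure(setNames(rep(1L, 6), regions),
                                 within_module_r = 0.5,
                                 between_module_r = 0.6), "between_module_r")
})

test_that("PSD repair clips negative eigenvalues and restores unit diagonal", {
  # an intentionally indefinite 'correlation' pattern
  m <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(m, symmetric = TRUE)$values), 0)
  fixed <- fosnet:::repair_psd(m)
  expect_true(min(eigen(fixed, symmetric = TRUE)$values) >= -1e-12)
  expect_equal(unname(diag(fixed)), rep(1, 3))
  expect_equal(fixed, t(fixed))
})

test_that("zero-noise cohorts hit group means exactly and densities stay positive", {
  regions <- paste0("R", 1:5)
  pl <- planted_structure(setNames(rep(1L, 5), regions),
                          within_module_r = 0.5, between_module_r = 0,
                          base_mean = setNames(c(30, 100, 300, 600, 900),
                                               regions),
                          noise_cv = 0,
                          group_effects = list(
                            WT_vehicle_naive = list(R1 = 2)))
  des <- study_design(genotypes = "WT", treatments = "vehicle",
                      stress_conditions = c("naive", "PST"),
                      n_per_cell = 4L, region_names = regions, seed = 3)
  tabs <- generate_cohort(des, pl)
  expect_equal(unname(tabs$WT_vehicle_naive$values[1, ]),
               c(60, 100, 300, 600, 900), tolerance = 1e-12)
  expect_equal(unname(tabs$WT_vehicle_PST$values[3, ]),
               c(30, 100, 300, 600, 900), tolerance = 1e-12)

  # positivity under heavy noise
  pl2 <- planted_structure(setNames(rep(1L, 5), regions),
                           within_module_r = 0.5, between_module_r = 0,
                           base_mean = 50, noise_cv = 1.5)
  tabs2 <- generate_cohort(des, pl2)
  expect_true(all(sapply(tabs2, function(t) all(t$values > 0))))
})

test_that("cohort generation is seed-deterministic and group-stable", {
  regions <- paste0("R", 1:6)
  pl <- planted_structure(setNames(rep(1:2, each = 3), regions),
                          within_module_r = 0.6, between_module_r = 0.1)
  d1 <- study_design(region_names = regions, n_per_cell = 5L, seed = 11)
  expect_identical(generate_cohort(d1, pl), generate_cohort(d1, pl))

  # restricting the design to fewer groups leaves shared groups untouched
  d_small <- study_design(genotypes = "WT", region_names = regions,
                          n_per_cell = 5L, seed = 11)
  big <- generate_cohort(d1, pl)
  small <- generate_cohort(d_small, pl)
  for (g in names(small)) {
    expect_identical(small[[g]], big[[g]])
  }
})

test_that("sample statistics converge to the planted model", {
  regions <- paste0("R", 1:9)
  pl <- planted_structure(setNames(rep(1:3, each = 3), regions),
                          within_module_r = 0.8, between_module_r = 0.1,
                          base_mean = setNames(seq(30, 900, length.out = 9),
                                               regions),
                          noise_cv = 0.5)
  # mean check at n = 200: every per-region sample mean within 3 SEM
  des200 <- one_group_design(regions, 200, seed = 5)
  tab <- generate_cohort(des200, pl)[[1]]
  sm <- colMeans(tab$values)
  sem <- apply(tab$values, 2, sd) / sqrt(200)
  expect_true(all(abs(sm - pl$base_mean) < 3 * sem))

  # correlation consistency at n = 5000: max deviation from the latent
  # target below 0.05 on the log (latent) scale
  des5k <- one_group_design(regions, 5000, seed = 6)
  tab5 <- generate_cohort(des5k, pl)[[1]]
  target <- build_target_correlation(pl)
  latent_r <- cor(log(tab5$values))
  expect_lt(max(abs(latent_r - target)), 0.05)
  # and the density-scale correlation is attenuated but within tolerance
  dens_r <- cor(tab5$values)
  expect_lt(max(abs(dens_r - target)), 0.05)
})

test_that("cohort summaries report mean and sd/sqrt(n), and reject n < 2", {
  regions <- paste0("R", 1:3)
  tab <- structure(list(
    group_label = "WT_vehicle_naive",
    values = cbind(R1 = c(100, 100, 100, 100),
                   R2 = c(1, 2, 3, 4),
                   R3 = c(10, 20, 30, 40)),
    animal_ids = paste0("a", 1:4)), class = "region_activity_table")
  s <- summarize_cohort(list(tab))
  expect_equal(s$WT_vehicle_naive_mean, c(100, 2.5, 25))
  expect_equal(s$WT_vehicle_naive_sem[1], 0)
  expect_equal(s$WT_vehicle_naive_sem[2], sd(1:4) / 2)
  expect_equal(s$WT_vehicle_naive_sem[2], 0.6455, tolerance = 1e-4)

  solo <- tab
  solo$values <- solo$values[1, , drop = FALSE]
  expect_error(summarize_cohort(list(solo)), "fewer than 2")
  expect_error(summarize_cohort(list()), "no groups")
})

test_that("cohorts round-trip through disk and long format", {
  regions <- paste0("R", 1:4)
  pl <- planted_structure(setNames(rep(1:2, each = 2), regions),
                          within_module_r = 0.5, between_module_r = 0)
  des <- study_design(genotypes = "WT", treatments = c("vehicle", "drug"),
                      stress_conditions = "naive", n_per_cell = 3L,
                      region_names = regions, seed = 2)
  tabs <- generate_cohort(des, pl)
  dir <- withr::local_tempdir()
  write_cohort(tabs, dir, design = des, planted = pl)
  expect_true(file.exists(file.path(dir, "cohort_meta.json")))

  reread <- read_region_table(file.path(dir, "cohort_long.tsv"))
  expect_identical(names(reread), names(tabs))
  for (g in names(tabs)) {
    expect_equal(reread[[g]]$values, tabs[[g]]$values, tolerance = 1e-12)
  }
})
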