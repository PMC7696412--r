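test_that("render_plant rasterizes a straight vertical blade exactly as the brute-force rule", {
  im <- imaging_spec(rows = 100L, cols = 51L, scale = 1, fg_sd = 0, bg_sd = 0)
  blade <- plant_spec(1, length_mm = 50, width_mm = 10, curvature = 0, taper = 0)
  rp <- render_plant(blade, im, 0, seed = 1)
  L_px <- 50
  n_s <- max(8L, ceiling(L_px * 3))
  expected <- oracle_vertical_blade_mask(100, 51, base_row = 98, base_col = 26,
                                         length_px = L_px, radius_px = 5,
                                         n_samples = n_s)
  expect_identical(rp$mask, expected)
  expect_equal(rp$true_area_mm2, sum(expected))
})

test_that("side projection is symmetric under a 180-degree rotation and seed-deterministic", {
  set.seed(8)
  pl <- random_plant_spec(0.7)
  im <- imaging_spec(seed = 99)
  a <- render_plant(pl, im, 40, seed = 5)
  b <- render_plant(pl, im, 220, seed = 5)
  expect_equal(sum(a$mask), sum(b$mask))
  expect_equal(a$true_area_mm2, b$true_area_mm2)
  # identical seed => bitwise identical image; different seed => different noise
  a2 <- render_plant(pl, im, 40, seed = 5)
  expect_identical(a$image$pixels, a2$image$pixels)
  a3 <- render_plant(pl, im, 40, seed = 6)
  expect_false(identical(a$image$pixels, a3$image$pixels))
  expect_identical(a$mask, a3$mask)
})

test_that("render_plant rejects geometry that exceeds the canvas", {
  im <- imaging_spec(rows = 120L, cols = 120L, scale = 1)
  tall <- plant_spec(1, length_mm = 300, width_mm = 8)
  expect_error(render_plant(tall, im, 0, seed = 1), class = "pg_canvas_overflow")
})

test_that("noise-free destructive simulation returns the analytic trajectory per replicate", {
  spec <- growth_sim_spec(replicates = 3, noise_sd = 0, trait_noise_sd = 0, seed = 1)
  sim <- simulate_destructive_study(spec)
  expect_equal(nrow(sim), 2 * 8 * 3)
  expect_equal(length(unique(sim$plant_id)), 2 * 8 * 3)  # destructive: no reuse
  for (gn in names(spec$genotypes)) {
    traj <- trait_trajectory(spec$genotypes[[gn]], spec$time_points)
    sub <- sim[sim$genotype == gn, ]
    for (i in seq_along(spec$time_points)) {
      cell <- sub[sub$dap == spec$time_points[i], ]
      expect_equal(cell$SPA, rep(traj$SPA[i], 3), tolerance = 1e-12)
      expect_equal(cell$BIO, rep(traj$BIO[i], 3), tolerance = 1e-12)
    }
  }
})

test_that("replicate means converge to the trajectory under lognormal noise", {
  g <- default_genotypes()["early_heading"]
  spec <- growth_sim_spec(genotypes = g, time_points = c(30, 35),
                          replicates = 1000, noise_sd = 0.1,
                          trait_noise_sd = 0, seed = 77)
  sim <- simulate_destructive_study(spec)
  traj <- trait_trajectory(g[[1]], c(30, 35))
  m30 <- mean(sim$SPA[sim$dap == 30])
  expect_lt(abs(m30 - traj$SPA[1]) / traj$SPA[1], 0.01)
})

test_that("the compound-interest fit recovers the simulated rate before deceleration", {
  g <- list(fast = list(spa0 = 10000, r = 0.25, th = 80, tau = 4,
                        heading_dap = 60, bio_inflation = 0.08,
                        allometry = c(la = 0.01, ldw = 0.06, bio = 0.08)))
  spec <- growth_sim_spec(genotypes = g, time_points = c(21, 25, 30),
                          replicates = 5, noise_sd = 0.05, seed = 42)
  sim <- simulate_destructive_study(spec)
  means <- aggregate(SPA ~ dap, sim, mean)
  fit <- fit_compound_interest(means$dap, means$SPA)
  expect_lt(abs(fit$r - 0.25) / 0.25, 0.05)
})

test_that("simulation is seed-deterministic and reproduces the study's qualitative patterns", {
  s1 <- simulate_destructive_study(growth_sim_spec(seed = 9))
  s2 <- simulate_destructive_study(growth_sim_spec(seed = 9))
  expect_identical(s1, s2)

  # noise-free patterns: monotone mean growth, RGR maximal in the earliest
  # interval and declining for SPA, superlinear late biomass-SPA relation
  spec <- growth_sim_spec(noise_sd = 0, trait_noise_sd = 0, seed = 1)
  sim <- simulate_destructive_study(spec)
  for (gn in unique(sim$genotype)) {
    sub <- sim[sim$genotype == gn, ]
    sub <- sub[!duplicated(sub$dap), ]
    sub <- sub[order(sub$dap), ]
    for (tr in c("LA", "LDW", "BIO", "SPA"))
      expect_true(all(diff(sub[[tr]]) > 0))
    rgr_spa <- rgr_table(sub$dap, sub$SPA)$rgr
    expect_true(all(diff(rgr_spa) < 0))
    rgr_bio <- rgr_table(sub$dap, sub$BIO)$rgr
    expect_equal(which.max(rgr_bio), 1L)
  }
  # biomass is linear in SPA until heading, superlinear well past it: the
  # early-heading genotype (14 days post heading) departs from the line,
  # while the one heading 2 days before study end is still almost linear
  early <- sim[sim$genotype == "early_heading", ]
  early <- early[!duplicated(early$dap), ]
  lin <- ols_simple(early$SPA, early$BIO)
  expc <- fit_exponential_predictor(early$SPA, early$BIO)
  expect_gt(expc$pseudo_r2, lin$r2)
  late <- sim[sim$genotype == "late_heading", ]
  late <- late[!duplicated(late$dap), ]
  expect_gt(ols_simple(late$SPA, late$BIO)$r2, lin$r2)
})

test_that("longitudinal mode tracks the same plants so per-plant RGR equals the trajectory RGR", {
  g <- default_genotypes()["early_heading"]
  spec <- growth_sim_spec(genotypes = g, replicates = 3, noise_sd = 0.2,
                          mode = "longitudinal", seed = 15)
  sim <- simulate_destructive_study(spec)
  expect_equal(length(unique(sim$plant_id)), 3)  # plants persist
  traj <- trait_trajectory(g[[1]], spec$time_points)
  expected <- rgr_table(spec$time_points, traj$SPA)$rgr
  for (pid in unique(sim$plant_id)) {
    sub <- sim[sim$plant_id == pid, ]
    sub <- sub[order(sub$dap), ]
    # the plant's constant size factor cancels out of the relative rate
    expect_equal(rgr_table(sub$dap, sub$SPA)$rgr, expected, tolerance = 1e-10)
  }
})

test_that("simulate_imaging_series writes one view per plant, time point and angle", {
  g <- default_genotypes()["early_heading"]
  growth <- growth_sim_spec(genotypes = g, time_points = c(21, 39),
                            replicates = 1, seed = 33)
  im <- imaging_spec(seed = 33)
  dir <- file.path(tempdir(), "pg_series_test")
  man <- simulate_imaging_series(growth, im, dir)
  expect_equal(nrow(man), 1 * 2 * 12)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_equal(man$true_spa_mm2, man$true_spa_px * im$scale^2)
  # a written image reloads to the rendered intensities
  img <- read_gray_image(file.path(dir, man$file[1]))
  expect_equal(dim(img$pixels), c(im$rows, im$cols))
  unlink(dir, recursive = TRUE)
})
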