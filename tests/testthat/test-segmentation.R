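test_that("otsu_threshold equals the exhaustive-scan oracle on random histograms", {
  set.seed(101)
  for (i in 1:120) {
    nbins <- sample(c(16L, 64L, 256L), 1L)
    h <- rpois(nbins, lambda = runif(1, 0.5, 20))
    # force bimodality sometimes, sparsity other times
    if (i %% 3 == 0) {
      h[] <- 0L
      m1 <- sample(nbins %/% 2, 1); m2 <- sample((nbins %/% 2):nbins, 1)
      h[m1] <- rpois(1, 200) + 1L; h[m2] <- rpois(1, 200) + 1L
      h <- h + rpois(nbins, 0.5)
    }
    if (sum(h > 0) < 2L) next
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
})

test_that("otsu_threshold separates a two-level histogram and rejects degenerate ones", {
  img <- gray_image(matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10))
  h <- gray_histogram(img)
  t <- otsu_threshold(h)
  expect_gt(t, 10)
  expect_lte(t, 200)
  expect_identical(t, oracle_otsu(h))
  h1 <- integer(256); h1[43] <- 100L
  expect_error(otsu_threshold(h1), class = "pg_degenerate_histogram")
  expect_error(otsu_threshold(integer(256)), class = "pg_bad_input")
})

test_that("binarize matches a per-pixel loop count, keeps shape, and is monotone in the threshold", {
  set.seed(7)
  px <- matrix(sample(0:255, 30 * 20, replace = TRUE), 30, 20)
  img <- gray_image(px)
  for (thr in c(0L, 40L, 128L, 255L)) {
    m <- binarize(img, thr)
    expect_identical(dim(m), dim(px))
    expect_true(all(m %in% c(0L, 1L)))
    expect_identical(sum(m), oracle_count_at_threshold(px, thr))
  }
  counts <- sapply(0:255, function(t) sum(binarize(img, t)))
  expect_true(all(diff(counts) <= 0))
  expect_equal(sum(binarize(img, 0)), length(px))       # all >= 0
  expect_equal(sum(binarize(gray_image(matrix(5L, 4, 4)), 200)), 0)
  expect_error(binarize(img, 256), class = "pg_bad_parameter")
})

test_that("clean_mask removes speckle, fills holes, and opening is idempotent", {
  m <- matrix(0L, 15, 15); m[8, 8] <- 1L
  expect_equal(sum(clean_mask(m, morphology_config(1, 0))), 0)

  solid <- matrix(0L, 30, 30); solid[5:24, 5:24] <- 1L
  holed <- solid; holed[12, 12] <- 0L
  expect_identical(clean_mask(holed, morphology_config(0, 1)), solid)

  set.seed(11)
  for (i in 1:5) {
    m <- random_mask(32, 32, p = runif(1, 0.2, 0.6))
    once <- clean_mask(m, morphology_config(1, 0))
    twice <- clean_mask(once, morphology_config(1, 0))
    expect_identical(twice, once)
    # opening never adds foreground; closing never removes it
    expect_true(all(once <= m))
    closed <- clean_mask(m, morphology_config(0, 1))
    expect_true(all(closed >= m))
  }
})

test_that("segment recovers ground truth on synthetic images and flags degenerate input", {
  im <- imaging_spec(fg_mean = 180, bg_mean = 30, fg_sd = 10, bg_sd = 10, seed = 5)
  set.seed(5)
  pl <- random_plant_spec(0.5)
  rp <- render_plant(pl, im, 0)
  mask <- segment(rp$image)
  expect_gte(mean(mask == rp$mask), 0.99)

  # noise-free two-level image: exact recovery (morphology touches nothing
  # on a smooth silhouette wider than the structuring element)
  im0 <- imaging_spec(fg_sd = 0, bg_sd = 0, seed = 1)
  blade <- plant_spec(1, length_mm = 100, width_mm = 12, curvature = 0, taper = 0)
  rp0 <- render_plant(blade, im0, 0)
  expect_identical(segment(rp0$image), rp0$mask)

  expect_error(segment(gray_image(matrix(7L, 10, 10))),
               class = "pg_degenerate_histogram")
})

test_that("segment is invariant to a constant intensity shift below saturation", {
  im0 <- imaging_spec(fg_sd = 0, bg_sd = 0, seed = 1)
  pl <- plant_spec(2, length_mm = c(80, 60), width_mm = 10,
                   curvature = c(0.2, -0.3), azimuth_deg = c(0, 120))
  rp <- render_plant(pl, im0, 30)
  shifted <- gray_image(rp$image$pixels + 40L)
  expect_identical(segment(shifted), segment(rp$image))
})

test_that("keep_largest_component retains only the dominant blob when enabled", {
  m <- matrix(0L, 20, 20)
  m[2:10, 2:10] <- 1L   # 81 px
  m[15:16, 15:16] <- 1L # 4 px
  kept <- keep_largest_component(m)
  expect_equal(sum(kept), 81)
  expect_equal(sum(kept[15:16, 15:16]), 0)
  # off by default in the pipeline config
  expect_false(morphology_config()$keep_largest)
})
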