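test_that("ols_simple matches the normal-equations oracle and its own invariants", {
  r <- suppressWarnings(ols_simple(1:8, 2 * (1:8) + 1))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r2, 1)
  set.seed(13)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    x <- runif(n, 0, 50); y <- 3 * x + rnorm(n, 0, 5)
    fit <- ols_simple(x, y)
    ora <- oracle_ols(x, y)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(fit$r2, ora$r2, tolerance = 1e-10)
    # in simple regression R^2 is the squared Pearson correlation
    expect_equal(fit$r2, fit$pearson_r^2, tolerance = 1e-9)
    expect_equal(sign(fit$pearson_r), sign(fit$slope))
  }
  expect_error(ols_simple(rep(2, 5), 1:5), class = "pg_degenerate_predictor")
  expect_error(ols_simple(1:2, 1:2), class = "pg_insufficient_data")
})

test_that("pearson matches the covariance-ratio oracle and validates input", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson(x, -x), -1)
  set.seed(17)
  for (i in 1:6) {
    a <- rnorm(7); b <- 0.5 * a + rnorm(7)
    expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
    expect_gte(pearson(a, b), -1); expect_lte(pearson(a, b), 1)
  }
  expect_error(pearson(rep(1, 5), 1:5), class = "pg_degenerate_predictor")
  expect_error(pearson(1:3, 1:4), class = "pg_bad_input")
})

test_that("two_way_anova reproduces the cell-means decomposition on a balanced layout", {
  set.seed(31)
  d <- expand.grid(dap = c(21, 25, 30, 35, 39, 44, 49, 53),
                   genotype = c("A", "B"), rep = 1:5)
  d$value <- 10 + 0.5 * as.integer(factor(d$dap)) +
    2 * (d$genotype == "B") +
    0.3 * as.integer(factor(d$dap)) * (d$genotype == "B") + rnorm(nrow(d))
  res <- two_way_anova(d)
  ora <- oracle_anova_ss(d$value, d$dap, d$genotype)
  expect_equal(res$table$sum_sq[1], unname(ora["a"]), tolerance = 1e-8)
  expect_equal(res$table$sum_sq[2], unname(ora["b"]), tolerance = 1e-8)
  expect_equal(res$table$sum_sq[3], unname(ora["ab"]), tolerance = 1e-8)
  expect_equal(res$table$sum_sq[4], unname(ora["res"]), tolerance = 1e-8)
  # components sum to the total
  expect_equal(sum(res$table$sum_sq), unname(ora["tot"]), tolerance = 1e-6)
  expect_equal(res$table$df, c(7, 1, 7, 64))
  expect_equal(res$r2, sum(res$table$sum_sq[1:3]) / sum(res$table$sum_sq),
               tolerance = 1e-12)
  expect_true(all(res$table$f[1:3] >= 0))
})

test_that("two_way_anova rejects degenerate and unbalanced designs", {
  d <- expand.grid(dap = c(1, 2), genotype = c("A", "B"), rep = 1:3)
  d$value <- rnorm(nrow(d))
  expect_error(two_way_anova(d[d$genotype == "A", ]), class = "pg_bad_design")
  expect_error(two_way_anova(d[-1, ]), class = "pg_unbalanced")
  d0 <- d; d0$value <- 5
  expect_warning(res <- two_way_anova(d0), "identical")
  expect_equal(res$r2, 0)
  expect_true(all(res$table$sum_sq == 0))
  expect_error(two_way_anova(d[, c("dap", "genotype")]), class = "pg_bad_input")
})

test_that("fit_exponential_predictor recovers exact exponential relations", {
  x <- seq(1000, 80000, length.out = 9)
  f <- suppressWarnings(fit_exponential_predictor(x, 3 * exp(0.0001 * x)))
  expect_equal(f$a, 3, tolerance = 1e-8)
  expect_equal(f$b, 0.0001, tolerance = 1e-10)
  expect_equal(f$pseudo_r2, 1, tolerance = 1e-8)
  # two points: exact interpolation
  f2 <- fit_exponential_predictor(c(1, 5), c(2, 7))
  expect_equal(f2$a * exp(f2$b * c(1, 5)), c(2, 7), tolerance = 1e-10)
  expect_error(fit_exponential_predictor(1:4, c(1, 2, -3, 4)), class = "pg_domain")
})

test_that("the exponential SPA-biomass model outperforms the linear one on the reference means", {
  m <- wheat_trait_means()
  for (gn in unique(m$genotype)) {
    spa <- m[m$genotype == gn & m$trait == "SPA", ]
    bio <- m[m$genotype == gn & m$trait == "BIO", ]
    spa <- spa[order(spa$dap), ]; bio <- bio[order(bio$dap), ]
    lin <- ols_simple(spa$mean, bio$mean)
    expc <- fit_exponential_predictor(spa$mean, bio$mean)
    expect_gt(expc$pseudo_r2, lin$r2)
  }
})
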