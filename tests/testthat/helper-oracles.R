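# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / direct formulas, never the package's vectorized paths.

# Exhaustive-scan Otsu: between-class variance evaluated level by level.
oracle_otsu <- function(h) {
  levels <- seq_along(h) - 1L
  n <- sum(h)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in levels[-1L]) {
    lo <- levels < t
    n0 <- sum(h[lo]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / n; w1 <- n1 / n
    mu0 <- sum((h * levels)[lo]) / n0
    mu1 <- sum((h * levels)[!lo]) / n1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Element-by-element foreground count at a threshold.
oracle_count_at_threshold <- function(pixels, thr) {
  cnt <- 0L
  for (i in seq_len(nrow(pixels))) for (j in seq_len(ncol(pixels)))
    if (pixels[i, j] >= thr) cnt <- cnt + 1L
  cnt
}

# Double-loop mask summation.
oracle_mask_sum <- function(mask) {
  s <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    s <- s + mask[i, j]
  s
}

# Scan-all-pixels bounding extent.
oracle_extent <- function(mask) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] == 1L) {
      rmin <- min(rmin, i); rmax <- max(rmax, i)
      cmin <- min(cmin, j); cmax <- max(cmax, j)
    }
  c(rmax - rmin + 1, cmax - cmin + 1)
}

# Normal-equations simple OLS from explicit sums.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Covariance-ratio Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Balanced two-way ANOVA sums of squares from cell means.
oracle_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  g <- mean(y)
  cell <- tapply(y, list(a, b), mean)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  n_cell <- length(y) / (nlevels(a) * nlevels(b))
  ss_a <- nlevels(b) * n_cell * sum((am - g)^2)
  ss_b <- nlevels(a) * n_cell * sum((bm - g)^2)
  ss_ab <- n_cell * sum((cell - outer(am, rep(1, nlevels(b))) -
                         outer(rep(1, nlevels(a)), bm) + g)^2)
  fitted_cell <- cell[cbind(as.integer(a), as.integer(b))]
  ss_res <- sum((y - fitted_cell)^2)
  c(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res, tot = sum((y - g)^2))
}

# Brute-force silhouette raster for a single straight vertical blade:
# a pixel is foreground iff it lies within the stroke radius of any
# centreline sample, mirroring the renderer's stated rasterization rule.
oracle_vertical_blade_mask <- function(rows, cols, base_row, base_col,
                                       length_px, radius_px, n_samples) {
  mask <- matrix(0L, rows, cols)
  t <- seq(0, 1, length.out = n_samples)
  cr <- base_row - length_px * t
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    for (k in seq_len(n_samples)) {
      if ((i - cr[k])^2 + (j - base_col)^2 <= radius_px^2) {
        mask[i, j] <- 1L
        break
      }
    }
  }
  mask
}

# Reference trait means reshaped into the tidy trait-table schema the
# pipeline entry points consume (one pseudo-plant per genotype/time holding
# the mean).
reference_trait_table <- function() {
  m <- wheat_trait_means()
  out <- NULL
  for (gn in unique(m$genotype)) for (d in unique(m$dap)) {
    sub <- m[m$genotype == gn & m$dap == d, ]
    row <- data.frame(genotype = gn, plant_id = paste0(gn, "_mean"), dap = d)
    for (tr in c("LA", "LDW", "BIO", "SPA"))
      row[[tr]] <- sub$mean[sub$trait == tr]
    out <- rbind(out, row)
  }
  out
}

random_mask <- function(rows = 32, cols = 32, p = 0.3) {
  matrix(as.integer(stats::runif(rows * cols) < p), rows, cols)
}
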