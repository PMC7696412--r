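with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic plant geometry
#'
#' A stylised wheat-like plant: a fan of thin, tapered, curved blades rising
#' from a common base. Each blade lies in a vertical plane at its own azimuth;
#' a side view projects the in-plane lateral sweep by the cosine of the angle
#' between blade azimuth and viewing direction.
#'
#' @param n_blades Number of blades (>= 1).
#' @param length_mm Blade lengths in mm (recycled to `n_blades`).
#' @param width_mm Basal blade widths in mm (recycled).
#' @param curvature Dimensionless lateral sweep per blade: the blade tip is
#'   displaced sideways by `curvature * length` in its plane (recycled).
#' @param azimuth_deg Blade azimuths in `[0, 360)` degrees (recycled).
#' @param taper Fraction of basal width lost linearly from base to tip.
#' @return A `plant_spec` list with per-blade vectors.
#' @export
plant_spec <- function(n_blades, length_mm, width_mm, curvature = 0,
                       azimuth_deg = 0, taper = 0.35) {
  n_blades <- as.integer(n_blades)
  if (n_blades < 1L) pg_error("a plant needs at least one blade", "pg_bad_parameter")
  spec <- list(n_blades = n_blades,
               length_mm = rep_len(length_mm, n_blades),
               width_mm = rep_len(width_mm, n_blades),
               curvature = rep_len(curvature, n_blades),
               azimuth_deg = rep_len(azimuth_deg, n_blades) %% 360,
               taper = taper)
  if (any(spec$length_mm <= 0) || any(spec$width_mm <= 0))
    pg_error("blade lengths and widths must be positive", "pg_bad_parameter")
  if (taper < 0 || taper >= 1) pg_error("taper must lie in [0, 1)", "pg_bad_parameter")
  structure(spec, class = "plant_spec")
}

#' Random plant geometry for a growth stage
#'
#' Draws a plausible blade fan whose size scales with a growth-stage scalar:
#' more, longer and slightly wider blades as the plant develops. Uses the
#' current RNG state.
#'
#' @param stage Growth stage in `[0, 1]`.
#' @param base_length_mm Blade length scale at `stage = 1`.
#' @return A [plant_spec()].
#' @export
random_plant_spec <- function(stage, base_length_mm = 170) {
  stage <- min(max(stage, 0), 1)
  n <- 3L + as.integer(round(9 * stage))
  plant_spec(
    n_blades = n,
    length_mm = base_length_mm * (0.25 + 0.75 * stage) * stats::runif(n, 0.7, 1),
    width_mm = (5 + 3 * stage) * stats::runif(n, 0.85, 1.15),
    curvature = stats::runif(n, -0.45, 0.45),
    azimuth_deg = stats::runif(n, 0, 360)
  )
}

#' Imaging geometry and noise model for synthetic views
#'
#' Mimics a fluorescence imaging booth: the plant silhouette is bright
#' (chlorophyll fluorescence) on a dark, noisy background; the camera sits at
#' one of 12 azimuthal angles 30 degrees apart.
#'
#' @param rows,cols Canvas size in pixels.
#' @param scale Millimetres per pixel.
#' @param fg_mean,fg_sd Foreground (plant) intensity mean and sd (gray levels).
#' @param bg_mean,bg_sd Background intensity mean and sd.
#' @param angles Viewing angles in degrees (default 12 views at 30 degree
#'   steps).
#' @param bit_depth Image bit depth.
#' @param seed Optional base seed making every rendered image reproducible.
#' @return An `imaging_spec` list.
#' @export
imaging_spec <- function(rows = 200L, cols = 200L, scale = 1.0,
                         fg_mean = 180, fg_sd = 10, bg_mean = 30, bg_sd = 10,
                         angles = seq(0, 330, by = 30), bit_depth = 8L,
                         seed = NULL) {
  if (fg_mean <= bg_mean) pg_error("foreground must be brighter than background", "pg_bad_parameter")
  if (fg_sd < 0 || bg_sd < 0) pg_error("intensity sds must be non-negative", "pg_bad_parameter")
  maxlev <- 2^as.integer(bit_depth) - 1
  if (fg_mean > maxlev || bg_mean < 0)
    pg_error("intensity means must be representable at the bit depth", "pg_bad_parameter")
  structure(list(rows = as.integer(rows), cols = as.integer(cols), scale = scale,
                 fg_mean = fg_mean, fg_sd = fg_sd, bg_mean = bg_mean, bg_sd = bg_sd,
                 angles = angles, bit_depth = as.integer(bit_depth), seed = seed),
            class = "imaging_spec")
}

# Centreline samples of one blade as projected pixel coordinates.
# Blade plane coordinates at parameter t in [0,1]: vertical rise L*t,
# lateral sweep curvature*L*t^2; projection multiplies the lateral component
# by cos(azimuth - view angle). Returns per-sample (row, col, radius_px).
blade_samples <- function(length_mm, width_mm, curvature, azimuth_deg, taper,
                          view_deg, scale, base_row, base_col) {
  L_px <- length_mm / scale
  n_s <- max(8L, ceiling(L_px * (1 + abs(curvature)) * 3))
  t <- seq(0, 1, length.out = n_s)
  proj <- cos((azimuth_deg - view_deg) * pi / 180)
  list(row = base_row - L_px * t,
       col = base_col + curvature * L_px * t^2 * proj,
       r_px = pmax(0.5, width_mm * (1 - taper * t) / 2 / scale))
}

stamp_discs <- function(mask, row, col, r_px) {
  rows <- nrow(mask); cols <- ncol(mask)
  for (k in seq_along(row)) {
    r <- r_px[k]
    i0 <- max(1L, floor(row[k] - r)); i1 <- min(rows, ceiling(row[k] + r))
    j0 <- max(1L, floor(col[k] - r)); j1 <- min(cols, ceiling(col[k] + r))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - row[k])^2, (jj - col[k])^2, `+`)
    blk <- mask[ii, jj, drop = FALSE]
    blk[d2 <= r^2] <- 1L
    mask[ii, jj] <- blk
  }
  mask
}

#' Render one synthetic side view
#'
#' Rasterizes the plant silhouette for a viewing angle (the ground-truth
#' mask), then draws foreground and background intensities from their normal
#' models, rounded and clipped to the bit depth.
#'
#' @param plant A [plant_spec()].
#' @param imaging An [imaging_spec()].
#' @param angle_deg Viewing angle in degrees.
#' @param seed Seed for the intensity noise; defaults to a value derived from
#'   `imaging$seed` and the angle so that every view is independently
#'   reproducible. `NULL` with no spec seed uses the current RNG state.
#' @return List with `image` (a [gray_image()]), `mask` (ground-truth 0/1
#'   matrix) and `true_area_mm2` (exact foreground pixel count times
#'   `scale^2`).
#' @export
render_plant <- function(plant, imaging, angle_deg,
                         seed = if (is.null(imaging$seed)) NULL
                                else imaging$seed + round(angle_deg)) {
  base_row <- imaging$rows - 2
  base_col <- (imaging$cols + 1) / 2
  mask <- matrix(0L, imaging$rows, imaging$cols)
  for (b in seq_len(plant$n_blades)) {
    s <- blade_samples(plant$length_mm[b], plant$width_mm[b], plant$curvature[b],
                       plant$azimuth_deg[b], plant$taper, angle_deg,
                       imaging$scale, base_row, base_col)
    if (any(s$row - s$r_px < 0.5) || any(s$col - s$r_px < 0.5) ||
        any(s$col + s$r_px > imaging$cols + 0.5))
      pg_error("blade geometry exceeds the canvas; enlarge the canvas or shrink the plant",
               "pg_canvas_overflow")
    mask <- stamp_discs(mask, s$row, s$col, s$r_px)
  }
  maxlev <- 2^imaging$bit_depth - 1
  img <- with_seed(seed, {
    n <- length(mask)
    noise_fg <- stats::rnorm(n, imaging$fg_mean, imaging$fg_sd)
    noise_bg <- stats::rnorm(n, imaging$bg_mean, imaging$bg_sd)
    vals <- ifelse(as.vector(mask) == 1L, noise_fg, noise_bg)
    matrix(as.integer(pmin(maxlev, pmax(0, round(vals)))), imaging$rows, imaging$cols)
  })
  list(image = gray_image(img, imaging$bit_depth), mask = mask,
       true_area_mm2 = sum(mask) * imaging$scale^2)
}

#' Growth-study simulation design
#'
#' Defines a two-genotype (or more) destructive growth study: per-genotype
#' growth-trajectory parameters, a sampling schedule, replication, and
#' plant-to-plant lognormal variability. The underlying trajectory is
#' exponential growth whose instantaneous rate declines logistically, so the
#' earliest intervals follow the compound-interest law and late intervals
#' flatten:
#' `SPA(t) = spa0 * exp(r * [(t - t0) - tau * (log(1 + e^((t - th)/tau)) - log(1 + e^((t0 - th)/tau)))])`.
#' Leaf area and leaf dry weight scale linearly with SPA; biomass scales
#' linearly before heading and inflates afterwards (spikes are denser than
#' leaves), making the late SPA-biomass relation superlinear.
#'
#' @param genotypes Named list; each element a list with `spa0` (mm^2 at
#'   `t0`), `r` (early rate, per day), `th` (DAP at which the rate has
#'   halved), `tau` (deceleration width, days), `heading_dap`,
#'   `bio_inflation` (fractional biomass gain per day after heading), and
#'   `allometry` (named vector `la` cm^2/mm^2, `ldw` mg/mm^2, `bio` mg/mm^2).
#' @param time_points Sampling schedule in days after planting.
#' @param replicates Independent plants per genotype per time point.
#' @param noise_sd Plant-to-plant lognormal sd (log scale) of a size factor
#'   shared by all traits of one plant (a large plant is large in area and in
#'   weight alike; in a destructive design the same plants supply both the
#'   image-derived and the weighed traits, which is what makes their interval
#'   growth rates co-vary). Draws are mean-one corrected so replicate means
#'   converge to the trajectory.
#' @param trait_noise_sd Additional per-trait lognormal sd (measurement and
#'   allometric scatter around the shared size factor).
#' @param t0 Reference day at which `spa0` applies.
#' @param mode `"destructive"` (fresh independent plants at every time point)
#'   or `"longitudinal"` (the same plants tracked over time, enabling
#'   per-plant growth rates).
#' @param seed Optional seed.
#' @return A `growth_sim_spec` list.
#' @export
growth_sim_spec <- function(genotypes = default_genotypes(),
                            time_points = c(21, 25, 30, 35, 39, 44, 49, 53),
                            replicates = 5L, noise_sd = 0.12,
                            trait_noise_sd = 0.04, t0 = 21,
                            mode = c("destructive", "longitudinal"),
                            seed = NULL) {
  mode <- match.arg(mode)
  if (any(diff(time_points) <= 0))
    pg_error("time points must be strictly increasing", "pg_bad_parameter")
  if (noise_sd < 0 || trait_noise_sd < 0)
    pg_error("noise sd must be non-negative", "pg_bad_parameter")
  for (g in genotypes)
    if (g$spa0 <= 0 || g$r <= 0 || g$tau <= 0)
      pg_error("genotype sizes and rates must be positive", "pg_bad_parameter")
  structure(list(genotypes = genotypes, time_points = time_points,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 trait_noise_sd = trait_noise_sd, t0 = t0, mode = mode,
                 seed = seed),
            class = "growth_sim_spec")
}

#' Default two-genotype parameter set
#'
#' Parameters chosen so the simulated trajectories have the magnitudes of a
#' controlled-environment spring wheat study: SPA starting near 1.1-1.3 dm^2
#' at 21 DAP and growing 6-10x by 53 DAP, an early-heading genotype and a
#' late-heading one.
#'
#' @return Named list of genotype parameter lists.
#' @export
default_genotypes <- function() {
  list(
    early_heading = list(spa0 = 12500, r = 0.14, th = 34, tau = 4,
                         heading_dap = 39, bio_inflation = 0.08,
                         allometry = c(la = 0.011, ldw = 0.065, bio = 0.09)),
    late_heading = list(spa0 = 10900, r = 0.15, th = 36, tau = 4,
                        heading_dap = 51, bio_inflation = 0.08,
                        allometry = c(la = 0.016, ldw = 0.10, bio = 0.08))
  )
}

#' Noise-free trait trajectories for one genotype
#'
#' Evaluates the analytic SPA trajectory and its allometric trait links at
#' the given days.
#'
#' @param g One genotype parameter list (see [growth_sim_spec()]).
#' @param t Days after planting.
#' @param t0 Reference day.
#' @return Data frame with `dap`, `SPA`, `LA`, `LDW`, `BIO`.
#' @export
trait_trajectory <- function(g, t, t0 = 21) {
  growth_int <- (t - t0) -
    g$tau * (log1p(exp((t - g$th) / g$tau)) - log1p(exp((t0 - g$th) / g$tau)))
  spa <- g$spa0 * exp(g$r * growth_int)
  bio <- g$allometry[["bio"]] * spa * (1 + g$bio_inflation * pmax(0, t - g$heading_dap))
  data.frame(dap = t, SPA = spa,
             LA = g$allometry[["la"]] * spa,
             LDW = g$allometry[["ldw"]] * spa,
             BIO = bio)
}

lognormal_factor <- function(n, sd) exp(stats::rnorm(n, 0, sd) - sd^2 / 2)

#' Simulate a destructive growth study
#'
#' Draws independent plants for every genotype x time-point cell (destructive
#' sampling semantics: no plant appears twice) around the analytic
#' trajectories of the design. Each plant carries one mean-one lognormal size
#' factor (`noise_sd`) shared by all four of its traits — the same harvested
#' plant supplies both the imaged and the weighed measurements — plus
#' independent per-trait scatter (`trait_noise_sd`). In longitudinal mode the
#' same plants persist across the schedule: the factors are drawn once per
#' plant, so each plant's own growth curve is a scaled copy of the
#' trajectory.
#'
#' @param spec A [growth_sim_spec()].
#' @return Data frame with columns `genotype`, `plant_id`, `dap`, `LA`,
#'   `LDW`, `BIO`, `SPA` (units cm^2, mg, mg, mm^2).
#' @export
simulate_destructive_study <- function(spec) {
  traits <- c("LA", "LDW", "BIO", "SPA")
  plant_factors <- function()
    lognormal_factor(1L, spec$noise_sd) *
      stats::setNames(lognormal_factor(4L, spec$trait_noise_sd), traits)
  with_seed(spec$seed, {
    out <- list()
    for (gn in names(spec$genotypes)) {
      g <- spec$genotypes[[gn]]
      traj <- trait_trajectory(g, spec$time_points, spec$t0)
      if (spec$mode == "longitudinal") {
        fac <- lapply(seq_len(spec$replicates), function(i) plant_factors())
        for (i in seq_along(spec$time_points)) {
          for (rep_i in seq_len(spec$replicates)) {
            f <- fac[[rep_i]]
            out[[length(out) + 1L]] <- data.frame(
              genotype = gn, plant_id = sprintf("%s_p%02d", gn, rep_i),
              dap = spec$time_points[i],
              LA = traj$LA[i] * f[["LA"]], LDW = traj$LDW[i] * f[["LDW"]],
              BIO = traj$BIO[i] * f[["BIO"]], SPA = traj$SPA[i] * f[["SPA"]])
          }
        }
      } else {
        for (i in seq_along(spec$time_points)) {
          for (rep_i in seq_len(spec$replicates)) {
            f <- plant_factors()
            out[[length(out) + 1L]] <- data.frame(
              genotype = gn,
              plant_id = sprintf("%s_d%02d_p%02d", gn, spec$time_points[i], rep_i),
              dap = spec$time_points[i],
              LA = traj$LA[i] * f[["LA"]], LDW = traj$LDW[i] * f[["LDW"]],
              BIO = traj$BIO[i] * f[["BIO"]], SPA = traj$SPA[i] * f[["SPA"]])
          }
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate an imaging series with ground truth
#'
#' For every plant of a (destructively sampled) simulated study, renders the
#' full set of rotational views with known ground-truth masks, writes the
#' images as PNGs, and returns a manifest linking each file to its plant and
#' exact silhouette area. Plant geometry grows with the simulated growth
#' stage (the ratio of the plant's trajectory SPA to its end-of-study value).
#'
#' @param growth A [growth_sim_spec()].
#' @param imaging An [imaging_spec()]; its `seed` (or `growth$seed`) drives
#'   both geometry and noise.
#' @param dir Output directory (created if missing); `NULL` renders without
#'   writing files.
#' @return Manifest data frame: `file`, `genotype`, `plant_id`, `dap`,
#'   `angle_deg`, `true_spa_px`, `true_spa_mm2`. Written to
#'   `<dir>/manifest.csv` when `dir` is given.
#' @export
simulate_imaging_series <- function(growth, imaging = imaging_spec(), dir = NULL) {
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base_seed <- if (!is.null(imaging$seed)) imaging$seed else growth$seed
  rows <- list()
  img_idx <- 0L
  for (gn in names(growth$genotypes)) {
    g <- growth$genotypes[[gn]]
    traj <- trait_trajectory(g, growth$time_points, growth$t0)
    spa_end <- max(traj$SPA)
    for (i in seq_along(growth$time_points)) {
      stage <- traj$SPA[i] / spa_end
      for (rep_i in seq_len(growth$replicates)) {
        img_idx <- img_idx + 1L
        plant_id <- sprintf("%s_d%02d_p%02d", gn, growth$time_points[i], rep_i)
        plant <- with_seed(if (is.null(base_seed)) NULL else base_seed + img_idx,
                           random_plant_spec(stage))
        for (ang in imaging$angles) {
          view_seed <- if (is.null(base_seed)) NULL
                       else base_seed + 1000L * img_idx + round(ang)
          rp <- render_plant(plant, imaging, ang, seed = view_seed)
          fname <- sprintf("%s_a%03d.png", plant_id, round(ang))
          if (!is.null(dir))
            png::writePNG(rp$image$pixels / (2^imaging$bit_depth - 1),
                          file.path(dir, fname))
          rows[[length(rows) + 1L]] <- data.frame(
            file = fname, genotype = gn, plant_id = plant_id,
            dap = growth$time_points[i], angle_deg = ang,
            true_spa_px = sum(rp$mask), true_spa_mm2 = rp$true_area_mm2)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
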