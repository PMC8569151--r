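# Synthetic field-trial generator. Emulates the statistical structure the
# pipeline assumes -- an RCBD peanut trial with logistic canopy growth, a
# soil/canopy reflectance mixture scene, sensor quantization and an 8-shade
# calibration panel -- so that every downstream stage is testable without the
# (non-public) field data.

#' Field-trial design
#'
#' @param genotypes character genotype labels.
#' @param reps number of replicate blocks (>= 2).
#' @param dap_schedule increasing measurement days after planting.
#' @param rows_per_plot 1 or 2 crop rows per plot.
#' @param lai_range,lg_range length-2 trait ranges the trial should span
#'   (min at the first DAP, max at the last).
#' @param seed integer RNG seed.
#' @return an object of class \code{trial_design}.
#' @export
trial_design <- function(genotypes, reps, dap_schedule, rows_per_plot,
                         lai_range, lg_range, seed = 1L) {
  reps <- as.integer(reps)
  if (reps < 2L) stop("`reps` must be >= 2")
  if (is.unsorted(dap_schedule, strictly = TRUE))
    stop("`dap_schedule` must be strictly increasing")
  if (!rows_per_plot %in% c(1L, 2L)) stop("`rows_per_plot` must be 1 or 2")
  for (r in list(lai_range, lg_range))
    if (length(r) != 2L || r[1] <= 0 || r[2] <= r[1])
      stop("trait ranges must be positive length-2 (lo, hi) with lo < hi")
  structure(list(genotypes = as.character(genotypes), reps = reps,
                 dap_schedule = as.numeric(dap_schedule),
                 rows_per_plot = as.integer(rows_per_plot),
                 lai_range = as.numeric(lai_range),
                 lg_range = as.numeric(lg_range), seed = as.integer(seed)),
            class = "trial_design")
}

#' Built-in trial presets
#'
#' "2017": 18 genotypes x 6 reps, 2-row plots, 30-50 DAP, LAI 0.8-2.6,
#' LG 43-75 cm. "2019": 8 genotypes x 16 reps, 1-row plots, 45-75 DAP,
#' LAI 1.5-5.8, LG 66-111 cm.
#'
#' @param campaign "2017" or "2019".
#' @param seed integer RNG seed.
#' @return a \code{trial_design}.
#' @export
trial_preset <- function(campaign = c("2017", "2019"), seed = 1L) {
  campaign <- as.character(campaign[1])
  switch(campaign,
    "2017" = trial_design(sprintf("G%02d", 1:18), reps = 6L,
                          dap_schedule = c(30, 35, 40, 45, 50),
                          rows_per_plot = 2L,
                          lai_range = c(0.8, 2.6), lg_range = c(43, 75),
                          seed = seed),
    "2019" = trial_design(sprintf("V%02d", 1:8), reps = 16L,
                          dap_schedule = c(45, 55, 65, 75),
                          rows_per_plot = 1L,
                          lai_range = c(1.5, 5.8), lg_range = c(66, 111),
                          seed = seed),
    stop(sprintf("unknown campaign '%s'", campaign)))
}

# logistic growth shape normalized to [0, 1] over the DAP schedule
.growth_shape <- function(dap, schedule, rate = 0.15) {
  t0 <- mean(range(schedule))
  s <- 1 / (1 + exp(-rate * (dap - t0)))
  s1 <- 1 / (1 + exp(-rate * (min(schedule) - t0)))
  sk <- 1 / (1 + exp(-rate * (max(schedule) - t0)))
  (s - s1) / (sk - s1)
}

#' Generate ground truth for a field trial
#'
#' Each genotype follows a logistic growth curve over the DAP schedule,
#' scaled into the design's trait range; a per-genotype amplitude multiplier
#' (uniform 0.8-1), a block effect and a bounded per-plot factor add RCBD
#' structure while keeping every value within 10 percent of the stated range
#' and each plot's trajectory non-decreasing in DAP. End-of-season pod yield
#' is a cubic function of the plot's mid-season LAI plus Gaussian noise
#' (sd 150 kg/ha).
#'
#' @param design a \code{trial_design}.
#' @param yield_coef cubic yield-link coefficients (intercept, linear,
#'   quadratic, cubic) in kg/ha per LAI power.
#' @return a data.frame with one row per plot x DAP: \code{plot_id, genotype,
#'   rep, dap, lai, lg, pod_yield} (pod_yield constant within a plot).
#' @export
generate_trial <- function(design,
                           yield_coef = c(1500, 1800, -150, 8)) {
  stopifnot(inherits(design, "trial_design"))
  with_local_seed(design$seed, {
    g <- design$genotypes
    shape <- .growth_shape(design$dap_schedule, design$dap_schedule)
    amp_lai <- stats::runif(length(g), 0.8, 1.0)
    amp_lg <- stats::runif(length(g), 0.8, 1.0)
    block_eff <- stats::runif(design$reps, -0.02, 0.02)
    rows <- list()
    for (ig in seq_along(g)) for (r in seq_len(design$reps)) {
      plot_id <- sprintf("%s_r%02d", g[ig], r)
      pf_lai <- 1 + block_eff[r] + stats::runif(1, -0.03, 0.03)
      pf_lg <- 1 + block_eff[r] + stats::runif(1, -0.03, 0.03)
      lai <- pf_lai * (design$lai_range[1] +
                       diff(design$lai_range) * shape * amp_lai[ig])
      lg <- pf_lg * (design$lg_range[1] +
                     diff(design$lg_range) * shape * amp_lg[ig])
      lai_mid <- lai[ceiling(length(lai) / 2)]
      pod <- sum(yield_coef * lai_mid^(0:3)) + stats::rnorm(1, 0, 150)
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = plot_id, genotype = g[ig], rep = r,
        dap = design$dap_schedule, lai = lai, lg = lg,
        pod_yield = max(pod, 0), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

# plausible independent sampling ranges for the six indices (all positive)
.vi_ranges <- list(bgi = c(0.2, 0.9), rgr = c(0.3, 1.0), nppr = c(0.6, 2.0),
                   ngrdi = c(0.02, 0.45), ppr = c(0.05, 0.6),
                   ncpi = c(0.02, 0.45))

#' Generate a model-consistent VI + trait table
#'
#' Samples VI vectors independently and uniformly within plausible field
#' ranges, then computes the trait with the requested frozen estimator plus
#' Gaussian noise. With \code{noise_sd = 0} the table is exactly
#' model-consistent, so an OLS refit recovers the frozen coefficients to
#' numerical precision.
#'
#' @param n number of rows, or a ground-truth data.frame whose row count is
#'   used.
#' @param model_id frozen model id ("reg1".."reg4").
#' @param noise_sd trait noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return a data.frame with the six VI columns plus the trait column
#'   ("LAI" or "LG").
#' @export
generate_vi_table <- function(n, model_id, noise_sd = 0, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  model <- frozen_model(model_id)
  with_local_seed(seed, {
    vi <- as.data.frame(lapply(.vi_ranges, function(r)
      stats::runif(n, r[1], r[2])))
    trait <- as.numeric(estimate_trait(vi, model)) +
      stats::rnorm(n, 0, noise_sd)
    vi[[model$trait]] <- trait
    vi
  })
}

#' Scene-rendering configuration
#'
#' @param canopy_reflectance,soil_reflectance endmember reflectance triples
#'   (red, green, blue); the canopy must be greener than the soil (higher
#'   PPR).
#' @param extinction_k canopy light-extinction coefficient linking LAI to
#'   canopy cover via \eqn{f = 1 - \exp(-k \cdot LAI)}.
#' @param reflectance_noise_sd per-pixel Gaussian reflectance noise.
#' @param gsd ground sampling distance, metres per pixel.
#' @param bit_depth sensor bits per channel.
#' @param panel_shades 8 panel reflectance levels (grey: equal across bands).
#' @param seed integer RNG seed.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(canopy_reflectance = c(0.08, 0.18, 0.05),
                         soil_reflectance = c(0.25, 0.22, 0.18),
                         extinction_k = 0.5,
                         reflectance_noise_sd = 0.01,
                         gsd = 0.05, bit_depth = 8L,
                         panel_shades = seq(0.95, 0.18, length.out = 8),
                         seed = 1L) {
  for (e in list(canopy_reflectance, soil_reflectance))
    if (length(e) != 3L || any(e <= 0)) stop("endmembers must be positive triples")
  ppr <- function(e) (e[2] - e[3]) / (e[2] + e[3])
  if (ppr(canopy_reflectance) <= ppr(soil_reflectance))
    stop("canopy endmember must have higher PPR than soil")
  if (extinction_k <= 0) stop("`extinction_k` must be > 0")
  if (reflectance_noise_sd < 0) stop("`reflectance_noise_sd` must be >= 0")
  if (gsd <= 0) stop("`gsd` must be > 0")
  if (length(panel_shades) != 8L || any(panel_shades <= 0))
    stop("`panel_shades` must be 8 positive reflectance levels")
  structure(list(canopy_reflectance = canopy_reflectance,
                 soil_reflectance = soil_reflectance,
                 extinction_k = extinction_k,
                 reflectance_noise_sd = reflectance_noise_sd,
                 gsd = gsd, bit_depth = as.integer(bit_depth),
                 panel_shades = as.numeric(panel_shades),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Render a synthetic orthomosaic scene at one measurement date
#'
#' Lays the trial out on a soil background (genotypes as rows of the grid,
#' replicates as columns), draws each crop row as an ellipse whose lateral
#' semi-axis is proportional to the plot's LG, fills ellipse pixels with the
#' canopy endmember with probability \eqn{f = 1 - \exp(-k \cdot LAI)} (soil
#' otherwise), adds per-pixel Gaussian reflectance noise, and quantizes
#' through the inverse calibration to integer DN clipped to the sensor range.
#' An 8-patch grey calibration panel is rendered along the bottom edge.
#'
#' @param truth ground-truth data.frame (one DAP only) with columns
#'   \code{plot_id, genotype, rep, lai, lg}.
#' @param config a \code{scene_config}.
#' @param calibration a \code{calibration_set} used to invert reflectance to
#'   DN.
#' @param rows_per_plot crop rows per plot (1 or 2).
#' @return a list: \code{scene} (scene_raster), \code{net} (plot fishnet),
#'   \code{panel_net} (panel-patch fishnet), \code{panel} (data.frame
#'   shade, reflectance).
#' @export
render_scene <- function(truth, config, calibration, rows_per_plot = 2L) {
  stopifnot(inherits(config, "scene_config"),
            inherits(calibration, "calibration_set"))
  if (length(unique(truth$dap)) > 1)
    stop("`truth` must contain a single DAP")
  genos <- unique(truth$genotype)
  reps <- sort(unique(truth$rep))
  row_spacing <- 0.91                     # m between crop rows in a plot
  plot_len <- 1.9                         # m, along-row ellipse extent
  cell_w <- 2.4                           # m per replicate column
  cell_h <- rows_per_plot * row_spacing + 0.8
  margin <- 0.5
  panel_h <- 0.8                          # strip below the trial
  width <- max(2 * margin + length(reps) * cell_w,
               2 * margin + 8 * 0.7)      # panel strip must fit

  height <- 2 * margin + length(genos) * cell_h + panel_h
  nc <- as.integer(ceiling(width / config$gsd))
  nr <- as.integer(ceiling(height / config$gsd))
  dn_max <- 2^config$bit_depth - 1

  # pixel-centre world coordinates (north-up grid, origin bottom-left)
  xs <- (seq_len(nc) - 0.5) * config$gsd
  ys_top_down <- height - (seq_len(nr) - 0.5) * config$gsd
  px <- matrix(rep(xs, each = nr), nr, nc)
  py <- matrix(rep(ys_top_down, times = nc), nr, nc)

  soil <- config$soil_reflectance
  canopy <- config$canopy_reflectance
  refl <- list(matrix(soil[1], nr, nc), matrix(soil[2], nr, nc),
               matrix(soil[3], nr, nc))

  polys <- list()
  with_local_seed(config$seed, {
    for (ig in seq_along(genos)) for (ir in seq_along(reps)) {
      sub <- truth[truth$genotype == genos[ig] & truth$rep == reps[ir], ]
      if (!nrow(sub)) next
      x0 <- margin + (ir - 1) * cell_w
      y0 <- margin + panel_h + (length(genos) - ig) * cell_h
      cx <- x0 + cell_w / 2
      f <- 1 - exp(-config$extinction_k * sub$lai[1])
      b_semi <- min(sub$lg[1] / 100 / 2, 0.55 * row_spacing)
      for (j in seq_len(rows_per_plot)) {
        cy <- y0 + 0.4 + (j - 0.5) * row_spacing
        inside <- ((px - cx) / (plot_len / 2))^2 +
                  ((py - cy) / b_semi)^2 <= 1
        idx <- which(inside)
        if (length(idx) && f > 0) {
          is_canopy <- idx[stats::runif(length(idx)) < f]
          for (k in 1:3) refl[[k]][is_canopy] <- canopy[k]
        }
      }
      hw <- plot_len / 2 + 0.15
      hh <- rows_per_plot * row_spacing / 2 + 0.25
      ymid <- y0 + 0.4 + rows_per_plot * row_spacing / 2
      ring <- cbind(c(cx - hw, cx + hw, cx + hw, cx - hw),
                    c(ymid - hh, ymid - hh, ymid + hh, ymid + hh))
      polys[[length(polys) + 1L]] <-
        plot_polygon(sub$plot_id[1], ring, genotype = genos[ig],
                     rep = reps[ir])
    }

    # calibration panel: 8 grey patches along the bottom strip
    panel_polys <- list()
    patch <- 0.6
    for (s in 1:8) {
      x0 <- margin + (s - 1) * (patch + 0.1)
      y0 <- 0.1
      inside <- px >= x0 & px <= x0 + patch & py >= y0 & py <= y0 + patch
      for (k in 1:3) refl[[k]][inside] <- config$panel_shades[s]
      ring <- cbind(c(x0, x0 + patch, x0 + patch, x0),
                    c(y0, y0, y0 + patch, y0 + patch))
      panel_polys[[s]] <- plot_polygon(sprintf("shade%d", s), ring)
    }

    # per-pixel reflectance noise, then quantize through the calibration
    bands <- list(calibration$red, calibration$green, calibration$blue)
    dn <- lapply(1:3, function(k) {
      r <- refl[[k]]
      if (config$reflectance_noise_sd > 0)
        r <- r + matrix(stats::rnorm(nr * nc, 0, config$reflectance_noise_sd),
                        nr, nc)
      r <- pmax(r, 1e-6)
      d <- suppressWarnings(invert_calibration(r, bands[[k]]))
      matrix(pmin(pmax(round(d), 0), dn_max), nr, nc)
    })
    transform <- c(config$gsd / 2, config$gsd, 0,
                   height - config$gsd / 2, 0, -config$gsd)
    scene <- scene_raster(
      band_raster(dn[[1]], config$bit_depth, transform),
      band_raster(dn[[2]], config$bit_depth, transform),
      band_raster(dn[[3]], config$bit_depth, transform))
    list(scene = scene, net = fishnet(polys),
         panel_net = fishnet(panel_polys),
         panel = data.frame(shade = 1:8,
                            reflectance = config$panel_shades))
  })
}

#' Simulate a full campaign: trial, scenes and extracted tables
#'
#' Generates the trial ground truth for a preset, renders one scene per DAP,
#' extracts zonal DN through the plot fishnet, calibrates to reflectance and
#' computes the six VIs. The returned table joins VIs with ground truth, one
#' row per plot x DAP.
#'
#' @param design a \code{trial_design} (e.g. from \code{\link{trial_preset}}).
#' @param config a \code{scene_config}.
#' @param calibration a \code{calibration_set}; default the published set for
#'   a 2017-style campaign.
#' @return a list: \code{truth} (ground-truth table), \code{table} (VI +
#'   truth table), \code{scenes} (list of render_scene results, one per DAP).
#' @export
simulate_campaign <- function(design, config = scene_config(),
                              calibration = builtin_calibrations("2017")) {
  truth <- generate_trial(design)
  scenes <- list()
  tables <- list()
  for (i in seq_along(design$dap_schedule)) {
    dap <- design$dap_schedule[i]
    day <- truth[truth$dap == dap, ]
    cfg <- config
    cfg$seed <- config$seed + i   # distinct pixel noise per flight
    sc <- render_scene(day, cfg, calibration,
                       rows_per_plot = design$rows_per_plot)
    zonal <- zonal_mean_dn(sc$scene, sc$net)
    refl <- data.frame(
      plot_id = zonal$plot_id,
      red = apply_calibration(zonal$mean_dn_red, calibration$red),
      green = apply_calibration(zonal$mean_dn_green, calibration$green),
      blue = apply_calibration(zonal$mean_dn_blue, calibration$blue),
      stringsAsFactors = FALSE)
    vis <- vi_table(refl)
    vis$dap <- dap
    tables[[i]] <- vis
    scenes[[i]] <- sc
  }
  vis_all <- do.call(rbind, tables)
  table <- merge(vis_all, truth, by = c("plot_id", "dap"), sort = FALSE)
  list(truth = truth, table = table, scenes = scenes)
}
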