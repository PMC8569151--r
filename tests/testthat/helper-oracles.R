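# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# point-in-polygon by winding angle summation (interior points only; the
# fixtures keep pixel centres strictly off polygon boundaries)
pip_winding <- function(x, y, ring) {
  n <- nrow(ring)
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(ring[i, 2] - y, ring[i, 1] - x)
    a2 <- atan2(ring[j, 2] - y, ring[j, 1] - x)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# brute-force zonal mean: loop every pixel of every band
brute_zonal <- function(scene, poly) {
  ctr <- aerialpheno:::pixel_centers(scene$red)
  sums <- c(red = 0, green = 0, blue = 0)
  count <- 0L
  for (i in seq_len(nrow(scene$red$values))) {
    for (j in seq_len(ncol(scene$red$values))) {
      if (pip_winding(ctr$x[i, j], ctr$y[i, j], poly$ring)) {
        sums <- sums + c(scene$red$values[i, j], scene$green$values[i, j],
                         scene$blue$values[i, j])
        count <- count + 1L
      }
    }
  }
  list(means = sums / count, count = count)
}

# leave-one-out PRESS by explicit refitting
brute_press <- function(x, y) {
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(cbind(1, x[-i, , drop = FALSE]), y[-i])
    pred <- sum(c(1, x[i, ]) * fit$coefficients)
    (y[i] - pred)^2
  }, 0))
}

# textbook Pearson correlation
textbook_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# hand paired t statistic
hand_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) /
  sum((obs - mean(obs))^2)

# small constant-value scene on the default unit-cell transform
const_scene <- function(nr = 10, nc = 10, dn = c(100, 100, 100),
                        bit_depth = 8L) {
  scene_raster(band_raster(matrix(dn[1], nr, nc), bit_depth),
               band_raster(matrix(dn[2], nr, nc), bit_depth),
               band_raster(matrix(dn[3], nr, nc), bit_depth))
}

reg1_predictors <- c("bgi", "ppr", "ngrdi", "ncpi", "nppr")
reg3_predictors <- c("nppr", "ncpi", "ngrdi", "ppr")

# tiny trial design used by scene/workflow tests (kept small for speed)
tiny_design <- function(seed = 5L) {
  trial_design(sprintf("T%d", 1:4), reps = 2L, dap_schedule = c(30, 40, 50),
               rows_per_plot = 2L, lai_range = c(0.8, 2.6),
               lg_range = c(43, 75), seed = seed)
}
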