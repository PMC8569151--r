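test_that("scene construction validates shapes and DN range", {
  sc <- const_scene(10, 10, c(100, 100, 100))
  expect_s3_class(sc, "scene_raster")
  expect_true(all(sc$red$values == 100))

  expect_error(
    scene_raster(band_raster(matrix(0, 10, 10)),
                 band_raster(matrix(0, 10, 9)),
                 band_raster(matrix(0, 10, 10))),
    "shape mismatch")
  expect_error(band_raster(matrix(300, 2, 2), bit_depth = 8L), "DN values")
  expect_error(band_raster(matrix(-1, 2, 2)), "DN values")
  expect_error(band_raster(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("ASC round trip preserves grid values and geotransform", {
  set.seed(42)
  vals <- matrix(as.numeric(sample(0:255, 60, replace = TRUE)), 6, 10)
  b <- band_raster(vals, 8L, transform = c(100.025, 0.05, 0, 203.975, 0, -0.05))
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(b, path)
  b2 <- read_asc(path)
  expect_identical(b2$values, vals)
  expect_equal(b2$transform, b$transform)

  sc <- scene_raster(b, b, b)
  paths <- file.path(withr::local_tempdir(), c("r.asc", "g.asc", "b.asc"))
  write_scene(sc, paths)
  sc2 <- read_scene(paths)
  expect_identical(sc2$green$values, vals)
  expect_error(read_scene(paths[1:2]), "three band files")
  expect_error(read_scene(c(paths[1:2], "nope.asc")), "not found")
})

test_that("zonal means match hand-computed and degenerate cases", {
  sc <- const_scene(6, 6, c(7, 7, 7))
  net <- fishnet(list(plot_polygon("p1",
    cbind(c(0.2, 3.2, 3.2, 0.2), c(0.2, 0.2, 3.2, 3.2)))))
  z <- zonal_mean_dn(sc, net)
  expect_equal(z$mean_dn_red, 7)
  expect_equal(z$pixel_count, 9L)  # centres at 0.5..2.5 in both axes

  # 4x4 grid, DN = 0-based column index, polygon covering everything
  vals <- matrix(rep(0:3, each = 4), 4, 4)
  sc2 <- scene_raster(band_raster(vals), band_raster(vals), band_raster(vals))
  all_net <- fishnet(list(plot_polygon("all",
    cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))))
  z2 <- zonal_mean_dn(sc2, all_net)
  expect_equal(z2$mean_dn_red, 1.5)
  expect_equal(z2$pixel_count, 16L)

  # polygon entirely outside the raster: error record, not an abort
  out_net <- fishnet(list(plot_polygon("out",
    cbind(c(50, 51, 51, 50), c(50, 50, 51, 51)))))
  z3 <- zonal_mean_dn(sc, out_net)
  expect_equal(z3$pixel_count, 0L)
  expect_true(is.na(z3$mean_dn_red))
  expect_match(z3$error, "no pixel centres")
})

test_that("zonal mean equals independent brute-force winding-number loop", {
  for (seed in 1:5) {
    set.seed(seed)
    nr <- sample(5:9, 1); nc <- sample(5:9, 1)
    mk <- function() band_raster(matrix(sample(0:255, nr * nc, TRUE), nr, nc))
    sc <- scene_raster(mk(), mk(), mk())
    # random convex quadrilateral with irrational-ish offsets so that no
    # pixel centre sits exactly on an edge
    cx <- runif(1, 2, nc - 2); cy <- runif(1, 2, nr - 2)
    ang <- sort(runif(4, 0, 2 * pi))
    rad <- runif(4, 1.3, min(nr, nc) / 2)
    ring <- cbind(cx + rad * cos(ang) + pi * 1e-3,
                  cy + rad * sin(ang) + exp(1) * 1e-3)
    net <- fishnet(list(plot_polygon("q", ring)))
    z <- zonal_mean_dn(sc, net)
    oracle <- brute_zonal(sc, net$polygons[[1]])
    expect_identical(z$pixel_count, oracle$count)
    expect_equal(unname(c(z$mean_dn_red, z$mean_dn_green, z$mean_dn_blue)),
                 unname(oracle$means), tolerance = 1e-12)
  }
})

test_that("zonal results are invariant to a common world translation", {
  set.seed(3)
  vals <- matrix(sample(0:255, 64, TRUE), 8, 8)
  ring <- cbind(c(1.1, 6.3, 5.9, 1.4), c(1.2, 1.7, 6.1, 5.8))
  for (off in list(c(0, 0), c(250, -31.5), c(-7.25, 1000))) {
    tr <- c(0.5 + off[1], 1, 0, 7.5 + off[2], 0, -1)
    b <- band_raster(vals, transform = tr)
    sc <- scene_raster(b, b, b)
    net <- fishnet(list(plot_polygon("p", sweep(ring, 2, -off))))
    z <- zonal_mean_dn(sc, net)
    if (all(off == 0)) ref <- z
    expect_equal(z$mean_dn_red, ref$mean_dn_red)
    expect_equal(z$pixel_count, ref$pixel_count)
  }
})

test_that("disjoint polygons cover at most the raster's pixels", {
  sc <- const_scene(10, 10, c(1, 1, 1))
  polys <- list()
  for (i in 0:2) for (j in 0:2)
    polys[[length(polys) + 1L]] <- plot_polygon(
      sprintf("p%d%d", i, j),
      cbind(c(0, 3, 3, 0) + i * 3.3, c(0, 0, 3, 3) + j * 3.3) + 0.05)
  z <- zonal_mean_dn(sc, fishnet(polys))
  expect_lte(sum(z$pixel_count), 100L)
  expect_true(all(z$pixel_count >= 1L))
})

test_that("two-row averaging is the componentwise mean", {
  expect_equal(average_rows_to_plot(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)),
               c(0.1, 0.2, 0.3))
  expect_equal(average_rows_to_plot(c(0.10, 0.20, 0.05), c(0.20, 0.20, 0.15)),
               c(0.15, 0.20, 0.10))
  expect_error(average_rows_to_plot(c(0.1, 0.2, 0.3), NULL), "triple")
  expect_error(average_rows_to_plot(c(0.1, NA, 0.3), c(0.1, 0.2, 0.3)),
               "complete")
})

test_that("fishnet GeoJSON round trip preserves geometry and properties", {
  polys <- list(
    plot_polygon("A1", cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)), "Bailey", 1L),
    plot_polygon("A2", cbind(c(3, 5, 5, 3), c(0, 0, 1, 1)), "Sugg", 2L))
  net <- fishnet(polys)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_fishnet_geojson(net, path)
  net2 <- read_fishnet_geojson(path)
  expect_equal(length(net2), 2L)
  expect_equal(net2$polygons[[1]]$ring, polys[[1]]$ring)
  expect_equal(net2$polygons[[2]]$genotype, "Sugg")
  expect_error(fishnet(list(polys[[1]], polys[[1]])), "unique")
  expect_error(plot_polygon("bad", cbind(c(0, 1), c(0, 0))), "3 distinct")
})
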