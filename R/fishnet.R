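#' Plot polygon
#'
#' A single field-plot boundary in world coordinates. The ring must be simple
#' (non-self-intersecting) and enclose a positive area; it may be given open or
#' closed (first vertex repeated) and is stored open.
#'
#' @param plot_id unique identifier.
#' @param ring numeric matrix with columns x, y of ordered vertices.
#' @param genotype genotype label.
#' @param rep integer replicate (block) number.
#' @return an object of class \code{plot_polygon}.
#' @export
plot_polygon <- function(plot_id, ring, genotype = NA_character_, rep = NA_integer_) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || !is.numeric(ring) || anyNA(ring))
    stop("`ring` must be a numeric matrix with columns x, y")
  n <- nrow(ring)
  if (n >= 2L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("`ring` must have at least 3 distinct vertices")
  if (abs(ring_area(ring)) <= 0) stop("polygon area must be > 0")
  structure(list(plot_id = as.character(plot_id),
                 genotype = as.character(genotype),
                 rep = as.integer(rep),
                 ring = unname(ring)),
            class = "plot_polygon")
}

#' Signed area of a ring (shoelace formula)
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Fishnet: an ordered collection of plot polygons
#'
#' @param polygons list of \code{plot_polygon}; plot_ids must be unique.
#' @return an object of class \code{fishnet}.
#' @export
fishnet <- function(polygons) {
  if (!length(polygons) || !all(vapply(polygons, inherits, TRUE, "plot_polygon")))
    stop("`polygons` must be a non-empty list of plot_polygon objects")
  ids <- vapply(polygons, `[[`, "", "plot_id")
  if (anyDuplicated(ids)) stop("plot_ids must be unique")
  structure(list(polygons = polygons), class = "fishnet")
}

#' @export
length.fishnet <- function(x) length(x$polygons)

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> %d plot polygons\n", length(x)))
  invisible(x)
}

#' Point-in-polygon test (even-odd rule, boundary counts as inside)
#'
#' @param px,py numeric vectors of point coordinates.
#' @param ring open vertex matrix (columns x, y).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- x[j]; y1 <- y[j]; x2 <- x[i]; y2 <- y[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    # boundary: collinear with the edge and within its bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(c(x1, y1, x2, y2, 1)))
    col_on <- abs(cross) <= 1e-12 * scale * scale &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | col_on
    j <- i
  }
  inside | on_edge
}

#' Zonal mean digital numbers per plot
#'
#' For each fishnet polygon, averages the DN of all pixels whose centres fall
#' inside the polygon (boundary-inclusive), independently for the red, green
#' and blue bands.
#'
#' @param scene a \code{scene_raster}.
#' @param net a \code{fishnet}.
#' @return a data.frame with columns \code{plot_id, genotype, rep,
#'   mean_dn_red, mean_dn_green, mean_dn_blue, pixel_count, error}; a polygon
#'   covering no pixel centres yields NA means, pixel_count 0 and an error
#'   message rather than aborting the run.
#' @export
zonal_mean_dn <- function(scene, net) {
  if (!inherits(scene, "scene_raster")) stop("`scene` must be a scene_raster")
  if (!inherits(net, "fishnet")) stop("`net` must be a fishnet")
  ctr <- pixel_centers(scene$red)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  r <- as.vector(scene$red$values)
  g <- as.vector(scene$green$values)
  b <- as.vector(scene$blue$values)
  rows <- lapply(net$polygons, function(p) {
    # restrict to the polygon's bounding box before the exact test
    bb <- apply(p$ring, 2, range)
    cand <- which(px >= bb[1, 1] - 1e-9 & px <= bb[2, 1] + 1e-9 &
                  py >= bb[1, 2] - 1e-9 & py <= bb[2, 2] + 1e-9)
    hit <- cand[point_in_polygon(px[cand], py[cand], p$ring)]
    if (!length(hit)) {
      data.frame(plot_id = p$plot_id, genotype = p$genotype, rep = p$rep,
                 mean_dn_red = NA_real_, mean_dn_green = NA_real_,
                 mean_dn_blue = NA_real_, pixel_count = 0L,
                 error = "no pixel centres inside polygon",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(plot_id = p$plot_id, genotype = p$genotype, rep = p$rep,
                 mean_dn_red = mean(r[hit]), mean_dn_green = mean(g[hit]),
                 mean_dn_blue = mean(b[hit]), pixel_count = length(hit),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Average two row-level reflectance triples to one plot triple
#'
#' Two-row plots are extracted row by row; the calibrated reflectances of the
#' two rows are averaged componentwise to give the plot reflectance.
#'
#' @param row1,row2 numeric length-3 vectors (red, green, blue reflectance).
#' @return numeric length-3 plot reflectance.
#' @export
average_rows_to_plot <- function(row1, row2) {
  for (r in list(row1, row2)) {
    if (length(r) != 3L || anyNA(r) || !is.numeric(r))
      stop("each row must be a complete numeric reflectance triple")
  }
  (as.numeric(row1) + as.numeric(row2)) / 2
}

# GeoJSON fishnet I/O -------------------------------------------------------

#' Read a fishnet from a GeoJSON FeatureCollection
#'
#' Features must be Polygons with properties \code{plot_id}, and optionally
#' \code{genotype} and \code{rep}.
#'
#' @param path GeoJSON file path.
#' @return a \code{fishnet}.
#' @export
read_fishnet_geojson <- function(path) {
  if (!file.exists(path)) stop(sprintf("fishnet file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  polys <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("all features must be Polygons")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    pr <- f$properties
    plot_polygon(plot_id = pr$plot_id,
                 ring = ring,
                 genotype = if (is.null(pr$genotype)) NA_character_ else pr$genotype,
                 rep = if (is.null(pr$rep)) NA_integer_ else pr$rep)
  })
  fishnet(polys)
}

#' Write a fishnet as a GeoJSON FeatureCollection
#'
#' @param net a \code{fishnet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_fishnet_geojson <- function(net, path) {
  feats <- lapply(net$polygons, function(p) {
    ring <- rbind(p$ring, p$ring[1, ])
    coords <- list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id, genotype = p$genotype,
                           rep = p$rep),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
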