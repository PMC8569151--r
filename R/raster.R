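#' Single-band digital-number raster
#'
#' A band raster is a rectangular grid of raw sensor counts (digital numbers,
#' DN) with an affine geotransform mapping 0-based pixel-centre indices
#' \code{(col, row)} to world coordinates \code{(x, y)}:
#' \deqn{x = t_1 + col \cdot t_2 + row \cdot t_3,\quad
#'       y = t_4 + col \cdot t_5 + row \cdot t_6.}
#' Row 0 is the top row of the image.
#'
#' @param values numeric matrix of DN, \code{values[row, col]}, top row first.
#' @param bit_depth integer bits per channel; all DN must lie in
#'   \code{[0, 2^bit_depth - 1]}.
#' @param transform numeric length-6 affine as above. The default places pixel
#'   centres at \code{(col + 0.5, nrow - row - 0.5)} (unit cells, y up).
#' @return an object of class \code{band_raster}.
#' @export
band_raster <- function(values, bit_depth = 8L, transform = NULL) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric matrix")
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 1L) stop("`bit_depth` must be >= 1")
  dn_max <- 2^bit_depth - 1
  if (anyNA(values) || any(values < 0) || any(values > dn_max))
    stop(sprintf("DN values must lie in [0, %d]", dn_max))
  if (is.null(transform))
    transform <- c(0.5, 1, 0, nrow(values) - 0.5, 0, -1)
  transform <- as.numeric(transform)
  if (length(transform) != 6L || anyNA(transform))
    stop("`transform` must be a numeric vector of length 6")
  if (abs(transform[2] * transform[6] - transform[3] * transform[5]) < 1e-300)
    stop("`transform` is not invertible")
  structure(list(values = values, bit_depth = bit_depth, transform = transform),
            class = "band_raster")
}

#' Three co-registered RGB band rasters
#'
#' @param red,green,blue \code{band_raster} objects with identical shape and
#'   geotransform.
#' @return an object of class \code{scene_raster}.
#' @export
scene_raster <- function(red, green, blue) {
  bands <- list(red = red, green = green, blue = blue)
  for (b in bands)
    if (!inherits(b, "band_raster")) stop("all bands must be band_raster objects")
  dims <- vapply(bands, function(b) dim(b$values), integer(2))
  if (any(dims != dims[, 1]))
    stop("band shape mismatch: all bands must share the same grid dimensions")
  trs <- vapply(bands, function(b) b$transform, numeric(6))
  if (any(abs(trs - trs[, 1]) > 1e-9))
    stop("band transform mismatch: all bands must share the same geotransform")
  structure(bands, class = "scene_raster")
}

#' @export
dim.band_raster <- function(x) dim(x$values)

#' @export
dim.scene_raster <- function(x) dim(x$red$values)

#' @export
print.scene_raster <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<scene_raster> %d x %d px, %d-bit, transform [%s]\n",
              d[1], d[2], x$red$bit_depth,
              paste(format(x$red$transform, digits = 6), collapse = ", ")))
  invisible(x)
}

#' World coordinates of every pixel centre
#'
#' @param raster a \code{band_raster}.
#' @return a list with matrices \code{x} and \code{y} (same shape as the grid).
#' @keywords internal
pixel_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  col <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  row <- matrix(rep(0:(nr - 1), times = nc), nr, nc)
  t <- raster$transform
  list(x = t[1] + col * t[2] + row * t[3],
       y = t[4] + col * t[5] + row * t[6])
}

# ESRI ASCII grid I/O -------------------------------------------------------
# Plain-text raster dialect used throughout (no binary GeoTIFF dependency);
# restricted to north-up square cells, which is what an orthomosaic export is.

#' Read a band from an ESRI ASCII grid (.asc) file
#'
#' @param path file path.
#' @param bit_depth bits per channel for DN validation.
#' @return a \code{band_raster}.
#' @export
read_asc <- function(path, bit_depth = 8L) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("malformed ASC header in %s", path))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASC body has %d values, expected %d", length(vals), nr * nc))
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  cs <- hdr$cellsize
  transform <- c(hdr$xllcorner + cs / 2, cs, 0,
                 hdr$yllcorner + (nr - 0.5) * cs, 0, -cs)
  band_raster(values, bit_depth = bit_depth, transform = transform)
}

#' Write a band raster as an ESRI ASCII grid
#'
#' Requires a north-up square-cell transform (no rotation terms).
#'
#' @param raster a \code{band_raster}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_asc <- function(raster, path) {
  t <- raster$transform
  if (t[3] != 0 || t[5] != 0 || t[6] != -t[2])
    stop("ASC export supports only north-up square-cell transforms")
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  cs <- t[2]
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", t[1] - cs / 2),
           sprintf("yllcorner %.10g", t[4] - (nr - 0.5) * cs),
           sprintf("cellsize %.10g", cs),
           "NODATA_value -9999")
  body <- apply(raster$values, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a three-band scene from per-band ASC files
#'
#' @param paths character vector of three file paths in red, green, blue order.
#' @param bit_depth bits per channel.
#' @return a \code{scene_raster}.
#' @export
read_scene <- function(paths, bit_depth = 8L) {
  if (length(paths) != 3L)
    stop("`paths` must name exactly three band files (red, green, blue)")
  bands <- lapply(paths, read_asc, bit_depth = bit_depth)
  scene_raster(bands[[1]], bands[[2]], bands[[3]])
}

#' Write a scene as three per-band ASC files
#'
#' @param scene a \code{scene_raster}.
#' @param paths three output paths in red, green, blue order.
#' @return \code{paths}, invisibly.
#' @export
write_scene <- function(scene, paths) {
  if (length(paths) != 3L) stop("`paths` must have length 3")
  write_asc(scene$red, paths[1])
  write_asc(scene$green, paths[2])
  write_asc(scene$blue, paths[3])
  invisible(paths)
}
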