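#' Exponential empirical-line calibration for one band
#'
#' The panel calibration maps a digital number to reflectance through
#' \deqn{\rho = a \cdot b^{DN}} where \code{a} (scale) is the reflectance at
#' DN 0 and \code{b} (base) the multiplicative growth per DN count.
#'
#' @param scale_a reflectance at DN 0; must be > 0.
#' @param base_b multiplicative growth per count; must be > 0.
#' @param band band label ("red", "green" or "blue").
#' @return an object of class \code{exp_calibration}.
#' @export
exp_calibration <- function(scale_a, base_b, band = NA_character_) {
  if (!is.numeric(scale_a) || length(scale_a) != 1L || scale_a <= 0)
    stop("`scale_a` must be a single positive number")
  if (!is.numeric(base_b) || length(base_b) != 1L || base_b <= 0)
    stop("`base_b` must be a single positive number")
  structure(list(band = as.character(band), scale_a = scale_a, base_b = base_b),
            class = "exp_calibration")
}

#' @export
print.exp_calibration <- function(x, ...) {
  cat(sprintf("<exp_calibration> %s: reflectance = %.6g * %.6g^DN\n",
              x$band, x$scale_a, x$base_b))
  invisible(x)
}

#' Fit the exponential calibration to panel observations
#'
#' Closed-form log-linear least squares: ordinary least squares of
#' \code{log(reflectance)} on DN gives \code{log a} (intercept) and
#' \code{log b} (slope). This is the canonical fit; the functional form is
#' exact on noiseless exponential data.
#'
#' @param dn numeric DN values (>= 0), at least 3, at least 2 distinct.
#' @param reflectance matching reflectances, all > 0.
#' @param band band label stored on the result.
#' @return an \code{exp_calibration}.
#' @export
fit_panel_calibration <- function(dn, reflectance, band = NA_character_) {
  if (length(dn) != length(reflectance))
    stop("`dn` and `reflectance` must have equal length")
  if (length(dn) < 3L) stop("need at least 3 panel observations")
  if (length(unique(dn)) < 2L) stop("need at least 2 distinct DN values")
  if (any(reflectance <= 0)) stop("all reflectances must be > 0")
  if (any(dn < 0)) stop("all DN must be >= 0")
  fit <- stats::lm.fit(cbind(1, dn), log(reflectance))
  exp_calibration(scale_a = exp(fit$coefficients[[1]]),
                  base_b = exp(fit$coefficients[[2]]),
                  band = band)
}

#' Apply a calibration: DN to reflectance
#'
#' Calibrated reflectance may exceed 1 at high DN; values are returned as-is
#' with a warning, never clamped.
#'
#' @param dn numeric DN values (>= 0); may be fractional (e.g. zonal means).
#' @param cal an \code{exp_calibration}.
#' @return reflectance fractions.
#' @export
apply_calibration <- function(dn, cal) {
  stopifnot(inherits(cal, "exp_calibration"))
  if (any(dn < 0)) stop("DN must be >= 0")
  r <- cal$scale_a * cal$base_b^dn
  if (any(r > 1))
    warning("calibrated reflectance exceeds 1 for some DN; returned unclamped")
  r
}

#' Invert a calibration: reflectance to (real-valued) DN
#'
#' @param reflectance reflectance fractions, all > 0.
#' @param cal an \code{exp_calibration} with base != 1.
#' @return real-valued DN such that \code{apply_calibration} recovers the input.
#' @export
invert_calibration <- function(reflectance, cal) {
  stopifnot(inherits(cal, "exp_calibration"))
  if (any(reflectance <= 0)) stop("reflectance must be > 0")
  if (cal$base_b == 1) stop("calibration base 1 is not invertible")
  log(reflectance / cal$scale_a) / log(cal$base_b)
}

#' Calibration set: one exponential calibration per band
#'
#' @param red,green,blue \code{exp_calibration} objects.
#' @param label campaign identifier (e.g. a year).
#' @return an object of class \code{calibration_set}.
#' @export
calibration_set <- function(red, green, blue, label = NA_character_) {
  for (c in list(red, green, blue))
    if (!inherits(c, "exp_calibration")) stop("all bands must be exp_calibration")
  structure(list(red = red, green = green, blue = blue,
                 label = as.character(label)),
            class = "calibration_set")
}

# Published panel calibrations per campaign (scale a, base b per band).
.builtin_cal <- list(
  "2017" = list(red   = c(0.1263, 1.0091),
                green = c(0.1263, 1.0087),
                blue  = c(0.1144, 1.0087)),
  "2019" = list(red   = c(0.0212, 1.0169),
                green = c(0.0211, 1.0165),
                blue  = c(0.0167, 1.0167))
)

#' Built-in published calibration sets
#'
#' Returns the panel calibrations fitted in the two field campaigns:
#' 2017 (red 0.1263 x 1.0091^DN, green 0.1263 x 1.0087^DN,
#' blue 0.1144 x 1.0087^DN) and 2019 (red 0.0212 x 1.0169^DN,
#' green 0.0211 x 1.0165^DN, blue 0.0167 x 1.0167^DN).
#'
#' @param campaign "2017" or "2019".
#' @return a \code{calibration_set}.
#' @export
builtin_calibrations <- function(campaign = c("2017", "2019")) {
  campaign <- as.character(campaign[1])
  if (!campaign %in% names(.builtin_cal))
    stop(sprintf("unknown campaign '%s'; available: %s", campaign,
                 paste(names(.builtin_cal), collapse = ", ")))
  p <- .builtin_cal[[campaign]]
  calibration_set(
    red   = exp_calibration(p$red[1],   p$red[2],   "red"),
    green = exp_calibration(p$green[1], p$green[2], "green"),
    blue  = exp_calibration(p$blue[1],  p$blue[2],  "blue"),
    label = campaign)
}

#' Fit all three band calibrations from a panel observation table
#'
#' @param panel data.frame with columns \code{shade, band, dn, reflectance}
#'   (the CSV dialect written by \code{\link{write_panel_csv}}).
#' @param label campaign label for the resulting set.
#' @return a \code{calibration_set}.
#' @export
fit_calibration_set <- function(panel, label = NA_character_) {
  need <- c("band", "dn", "reflectance")
  if (!all(need %in% names(panel)))
    stop("panel table must have columns band, dn, reflectance")
  one <- function(b) {
    sub <- panel[panel$band == b, ]
    fit_panel_calibration(sub$dn, sub$reflectance, band = b)
  }
  calibration_set(one("red"), one("green"), one("blue"), label = label)
}

#' @rdname fit_calibration_set
#' @param path CSV path with header \code{shade,band,dn,reflectance}.
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname fit_calibration_set
#' @param panel_df panel observation data.frame to write.
#' @export
write_panel_csv <- function(panel_df, path) {
  utils::write.csv(panel_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Calibration set JSON round trip
#'
#' Serialized as \code{{label, red: {scale_a, base_b}, ...}}.
#'
#' @param cal a \code{calibration_set}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{calibration_set} (read).
#' @export
write_calibration_json <- function(cal, path) {
  obj <- list(label = cal$label)
  for (b in c("red", "green", "blue"))
    obj[[b]] <- list(scale_a = cal[[b]]$scale_a, base_b = cal[[b]]$base_b)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  calibration_set(
    red   = exp_calibration(obj$red$scale_a,   obj$red$base_b,   "red"),
    green = exp_calibration(obj$green$scale_a, obj$green$base_b, "green"),
    blue  = exp_calibration(obj$blue$scale_a,  obj$blue$base_b,  "blue"),
    label = obj$label)
}
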