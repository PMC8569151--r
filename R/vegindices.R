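#' Names of the six RGB vegetation indices
#'
#' In canonical order: BGI (blue/green), RGR (red/green), NPPR
#' (green/(red+blue)), NGRDI ((green-red)/(green+red)), PPR
#' ((green-blue)/(green+blue)), NCPI ((red-blue)/(red+blue)).
#'
#' @export
vi_names <- function() c("bgi", "rgr", "nppr", "ngrdi", "ppr", "ncpi")

#' Compute the six RGB vegetation indices from reflectance triples
#'
#' All six indices are ratios of band reflectances and therefore invariant to
#' a common rescaling of the three bands. The normalized-difference indices
#' (NGRDI, PPR, NCPI) lie in (-1, 1) for strictly positive bands; negative
#' values are meaningful and are never clamped.
#'
#' @param red,green,blue numeric vectors of band reflectance; vectors are
#'   recycled to a common length. All bands must be strictly positive (the
#'   denominators require it).
#' @return a data.frame with columns \code{bgi, rgr, nppr, ngrdi, ppr, ncpi}.
#' @export
compute_vis <- function(red, green, blue) {
  n <- max(length(red), length(green), length(blue))
  red <- rep_len(as.numeric(red), n)
  green <- rep_len(as.numeric(green), n)
  blue <- rep_len(as.numeric(blue), n)
  if (anyNA(red) || anyNA(green) || anyNA(blue))
    stop("reflectance must not contain NA")
  if (any(red <= 0) || any(green <= 0) || any(blue <= 0))
    stop("all band reflectances must be > 0 (zero denominator)")
  data.frame(
    bgi   = blue / green,
    rgr   = red / green,
    nppr  = green / (red + blue),
    ngrdi = (green - red) / (green + red),
    ppr   = (green - blue) / (green + blue),
    ncpi  = (red - blue) / (red + blue)
  )
}

#' Per-plot vegetation index table from a plot reflectance table
#'
#' @param refl data.frame with columns \code{plot_id, red, green, blue};
#'   rows with any nonpositive band produce an error record instead of
#'   aborting the table.
#' @return data.frame \code{plot_id, bgi, rgr, nppr, ngrdi, ppr, ncpi, error}.
#' @export
vi_table <- function(refl) {
  need <- c("plot_id", "red", "green", "blue")
  if (!all(need %in% names(refl)))
    stop("reflectance table must have columns plot_id, red, green, blue")
  ok <- with(refl, is.finite(red) & is.finite(green) & is.finite(blue) &
               red > 0 & green > 0 & blue > 0)
  out <- data.frame(plot_id = refl$plot_id,
                    bgi = NA_real_, rgr = NA_real_, nppr = NA_real_,
                    ngrdi = NA_real_, ppr = NA_real_, ncpi = NA_real_,
                    error = ifelse(ok, NA_character_,
                                   "nonpositive or missing reflectance"),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    v <- compute_vis(refl$red[ok], refl$green[ok], refl$blue[ok])
    out[ok, vi_names()] <- v
  }
  out
}
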