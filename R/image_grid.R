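#' Calibrated 2D intensity raster
#'
#' The unit that every detector and profiler consumes: a non-negative
#' grayscale intensity matrix with its pixel size in µm/px and an exposure
#' group label. Rows index y (increasing downward), columns index x; the
#' centre of pixel `(r, c)` sits at `((c - 0.5) * pixel_size,
#' (r - 0.5) * pixel_size)` µm, so the coordinate origin is the field's
#' top-left corner.
#'
#' Intensity comparisons across images (relative peaks, comet counts at a
#' shared threshold) are only meaningful within one exposure group; the
#' label travels with the image so pipelines can enforce that.
#'
#' @param values Numeric matrix of intensities (>= 0).
#' @param pixel_size Pixel size, µm/px (> 0). Default 0.1 so that the
#'   0.2-1.2 µm² comet area gate corresponds to 20-120 px.
#' @param exposure_group Label for the fixed-exposure comparison group.
#' @return An `image_grid` object.
#' @export
image_grid <- function(values, pixel_size = 0.1, exposure_group = "default") {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_invalid("image values must be finite numbers")
  }
  if (any(values < 0)) stop_invalid("image values must be >= 0")
  check_positive(pixel_size, "pixel_size")
  structure(
    list(values = values, pixel_size = pixel_size,
         exposure_group = exposure_group),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid %d x %d px (%.3g x %.3g um), pixel %.3g um, group '%s'>\n",
    nrow(x$values), ncol(x$values),
    ncol(x$values) * x$pixel_size, nrow(x$values) * x$pixel_size,
    x$pixel_size, x$exposure_group))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' Field extent of an image, µm (width, height)
#' @param image An [image_grid()].
#' @return Numeric length-2 vector `c(width, height)` in µm.
#' @export
field_size <- function(image) {
  c(ncol(image$values), nrow(image$values)) * image$pixel_size
}

#' Bilinear intensity interpolation at continuous positions
#'
#' Samples the raster at µm coordinates by bilinear interpolation between
#' the four surrounding pixel centres; positions are clamped to the centre
#' grid at the borders. Returns `NA` for positions outside the image.
#'
#' @param image An [image_grid()].
#' @param x,y Query coordinates, µm.
#' @return Interpolated intensities (NA outside the image extent).
#' @export
interp_bilinear <- function(image, x, y) {
  v <- image$values
  ps <- image$pixel_size
  nr <- nrow(v); nc <- ncol(v)
  cc <- x / ps + 0.5   # fractional column (pixel centres at 1..nc)
  rr <- y / ps + 0.5
  out <- rep(NA_real_, length(x))
  inside <- x >= 0 & x <= nc * ps & y >= 0 & y <= nr * ps
  cc <- pmax(1, pmin(cc[inside], nc))
  rr <- pmax(1, pmin(rr[inside], nr))
  c0 <- pmin(floor(cc), nc - 1); r0 <- pmin(floor(rr), nr - 1)
  if (nc == 1) c0 <- rep(1, length(cc))
  if (nr == 1) r0 <- rep(1, length(rr))
  tc <- cc - c0; tr <- rr - r0
  c1 <- pmin(c0 + 1, nc); r1 <- pmin(r0 + 1, nr)
  out[inside] <-
    v[cbind(r0, c0)] * (1 - tr) * (1 - tc) +
    v[cbind(r1, c0)] * tr * (1 - tc) +
    v[cbind(r0, c1)] * (1 - tr) * tc +
    v[cbind(r1, c1)] * tr * tc
  out
}

# µm coordinates of every pixel centre, as two matrices shaped like values
pixel_centres <- function(image) {
  ps <- image$pixel_size
  nr <- nrow(image$values); nc <- ncol(image$values)
  list(
    x = matrix((seq_len(nc) - 0.5) * ps, nr, nc, byrow = TRUE),
    y = matrix((seq_len(nr) - 0.5) * ps, nr, nc)
  )
}
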