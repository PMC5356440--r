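#' Cortical analysis box
#'
#' A square region of interest on a junction, the unit over which
#' perpendicular-approach percentages and comet counts are scored (10 x 10
#' µm by convention).
#'
#' @param centre Box centre `c(x, y)`, µm.
#' @param side Box side, µm (> 0; default 10).
#' @param junction_id Optional id of the associated junction.
#' @param box_id Optional identifier.
#' @return A `cortical_box` object.
#' @export
cortical_box <- function(centre, side = 10, junction_id = NULL,
                         box_id = NULL) {
  if (length(centre) != 2 || any(!is.finite(centre))) {
    stop_invalid("`centre` must be finite c(x, y)")
  }
  check_positive(side, "side")
  structure(list(centre = as.numeric(centre), side = side,
                 junction_id = junction_id, box_id = box_id),
            class = "cortical_box")
}

box_bounds <- function(box) {
  h <- box$side / 2
  c(x0 = box$centre[1] - h, y0 = box$centre[2] - h,
    x1 = box$centre[1] + h, y1 = box$centre[2] + h)
}

# left/top edges inclusive, right/bottom exclusive: tiled boxes never count
# a point twice
in_box <- function(box, x, y) {
  b <- box_bounds(box)
  x >= b["x0"] & x < b["x1"] & y >= b["y0"] & y < b["y1"]
}

# cortex-proximal end of a filament relative to a junction, with its local
# approach direction (from the proximal segment, which carries the
# "approaching the cortex" geometry)
proximal_end <- function(filament, junction) {
  n <- length(filament$x)
  ends <- rbind(c(filament$x[1], filament$y[1]),
                c(filament$x[n], filament$y[n]))
  nd <- nearest_on_path(junction, ends)
  if (nd$d[1] <= nd$d[2]) {
    list(pt = ends[1, ], d = nd$d[1], s = nd$s[1],
         dir = atan2(filament$y[1] - filament$y[2],
                     filament$x[1] - filament$x[2]) * 180 / pi)
  } else {
    list(pt = ends[2, ], d = nd$d[2], s = nd$s[2],
         dir = atan2(filament$y[n] - filament$y[n - 1],
                     filament$x[n] - filament$x[n - 1]) * 180 / pi)
  }
}

#' Approach angles of filaments to a junction
#'
#' For each filament, the acute angle in `[0, 90]` degrees between its
#' cortex-proximal segment and the junction tangent at the nearest junction
#' point.
#'
#' @param filaments List of filament [poly_path()]s.
#' @param junction Junction [poly_path()].
#' @return Tibble with `id`, `x`, `y` (proximal end), `dist_um` (distance to
#'   the junction) and `angle_deg`.
#' @export
approach_angles <- function(filaments, junction) {
  if (length(filaments) == 0) {
    return(tibble::tibble(id = character(0), x = numeric(0),
                          y = numeric(0), dist_um = numeric(0),
                          angle_deg = numeric(0)))
  }
  rows <- lapply(seq_along(filaments), function(k) {
    f <- filaments[[k]]
    pe <- proximal_end(f, junction)
    tg <- path_tangent(junction, pe$s)
    tibble::tibble(
      id = if (!is.null(f$id)) f$id else sprintf("f%04d", k),
      x = pe$pt[1], y = pe$pt[2], dist_um = pe$d,
      angle_deg = fold_acute(pe$dir - tg))
  })
  dplyr::bind_rows(rows)
}

#' Percentage of microtubules approaching the cortex perpendicularly
#'
#' Within a cortical box, the percentage of filaments (those whose
#' cortex-proximal end lies in the box) whose approach angle to the local
#' junction tangent falls in `[lo, hi]` degrees — by convention the
#' perpendicular range 45-90°, with both bounds inclusive.
#'
#' @param filaments List of filament [poly_path()]s.
#' @param junction Junction [poly_path()].
#' @param box A [cortical_box()].
#' @param lo,hi Angle range, degrees (`lo < hi <= 90`).
#' @return List with `percent` (NA when undefined), `n_in_box`, `n_in_range`
#'   and `defined` (FALSE when the box holds no filament; such boxes are
#'   excluded from group means).
#' @export
perpendicular_fraction <- function(filaments, junction, box,
                                   lo = 45, hi = 90) {
  stopifnot(inherits(box, "cortical_box"))
  if (!(lo < hi && hi <= 90 && lo >= 0)) {
    stop_invalid("need 0 <= lo < hi <= 90 degrees")
  }
  ang <- approach_angles(filaments, junction)
  sel <- ang[in_box(box, ang$x, ang$y), ]
  n <- nrow(sel)
  if (n == 0) {
    return(list(percent = NA_real_, n_in_box = 0L, n_in_range = 0L,
                defined = FALSE))
  }
  hit <- sum(sel$angle_deg >= lo & sel$angle_deg <= hi)
  list(percent = 100 * hit / n, n_in_box = n, n_in_range = hit,
       defined = TRUE)
}

#' Microtubule-junction contacts per 10 µm of junction
#'
#' A filament contacts the junction when its cortex-proximal endpoint lies
#' within `d_contact` of the junction polyline; each filament counts at most
#' once. The count is normalized to contacts per 10 µm of junction length.
#'
#' @param filaments List of filament [poly_path()]s.
#' @param junction Junction [poly_path()] (length > 0).
#' @param d_contact Contact distance, µm (> 0; default 0.25, about 2-3
#'   pixels at the default 0.1 µm/px calibration).
#' @return List with `per_10um`, `n_contacts`, `junction_length_um`.
#' @export
contacts_per_10um <- function(filaments, junction, d_contact = 0.25) {
  check_positive(d_contact, "d_contact")
  L <- path_length(junction)
  if (L <= 0) stop_invalid("junction has zero length")
  n <- if (length(filaments) == 0) 0L else {
    ang <- approach_angles(filaments, junction)
    sum(ang$dist_um <= d_contact)
  }
  list(per_10um = n * 10 / L, n_contacts = n, junction_length_um = L)
}

#' Dominant texture orientation and anisotropy (gradient structure tensor)
#'
#' Computes per-pixel intensity gradients (centred finite differences after
#' light Gaussian pre-smoothing), averages the second-moment tensor of the
#' gradients over the region of interest, and reports the fibril axis (the
#' axis perpendicular to the mean gradient axis) together with the
#' eigenvalue contrast of the tensor — an alignment score in `[0, 1]`. This
#' is the circular-average-of-gradients method used to score microtubule
#' orientation relative to junctions. A region with gradient energy below
#' `energy_floor` (e.g. a constant image) yields `defined = FALSE`.
#'
#' @param image An [image_grid()].
#' @param roi Region `c(x0, y0, x1, y1)` in µm, or `NULL` for the whole
#'   image; must cover at least 3 x 3 pixels.
#' @param smooth_sigma Pre-smoothing SD, pixels (default 1).
#' @param energy_floor Mean squared-gradient floor below which the
#'   orientation is reported undefined.
#' @return List with `orientation_deg` (fibril axis in `[0, 180)`; NA when
#'   undefined), `anisotropy` in `[0, 1]` and `defined`.
#' @export
nematic_orientation <- function(image, roi = NULL, smooth_sigma = 1,
                                energy_floor = 1e-8) {
  stopifnot(inherits(image, "image_grid"))
  v <- image$values
  ps <- image$pixel_size
  if (!is.null(roi)) {
    if (length(roi) != 4) stop_invalid("`roi` must be c(x0, y0, x1, y1)")
    c0 <- max(1L, floor(roi[1] / ps) + 1L)
    c1 <- min(ncol(v), ceiling(roi[3] / ps))
    r0 <- max(1L, floor(roi[2] / ps) + 1L)
    r1 <- min(nrow(v), ceiling(roi[4] / ps))
    if (c1 - c0 < 2 || r1 - r0 < 2) {
      stop_invalid("roi must contain at least 3 x 3 pixels inside the image")
    }
    v <- v[r0:r1, c0:c1]
  }
  if (nrow(v) < 3 || ncol(v) < 3) {
    stop_invalid("roi must contain at least 3 x 3 pixels")
  }
  if (smooth_sigma > 0) {
    v <- as.matrix(EBImage::gblur(EBImage::Image(v), sigma = smooth_sigma))
  }
  nr <- nrow(v); nc <- ncol(v)
  # centred differences on the interior; x along columns, y along rows
  gx <- (v[2:(nr - 1), 3:nc] - v[2:(nr - 1), 1:(nc - 2)]) / 2
  gy <- (v[3:nr, 2:(nc - 1)] - v[1:(nr - 2), 2:(nc - 1)]) / 2
  # trim one more pixel where the blur's border handling leaks
  if (nrow(gx) > 4 && ncol(gx) > 4) {
    gx <- gx[3:(nrow(gx) - 2), 3:(ncol(gx) - 2)]
    gy <- gy[3:(nrow(gy) - 2), 3:(ncol(gy) - 2)]
  }
  jxx <- mean(gx^2); jyy <- mean(gy^2); jxy <- mean(gx * gy)
  energy <- jxx + jyy
  scale2 <- mean(v^2)
  if (energy <= energy_floor * max(scale2, 1e-300)) {
    return(list(orientation_deg = NA_real_, anisotropy = 0, defined = FALSE))
  }
  grad_axis <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  anis <- sqrt((jxx - jyy)^2 + 4 * jxy^2) / energy
  list(orientation_deg = fold_axial(grad_axis + 90),
       anisotropy = anis, defined = TRUE)
}

#' Acute angle between a fibril orientation and a junction tangent
#'
#' @param result An orientation result from [nematic_orientation()] (or a
#'   bare orientation in degrees).
#' @param junction_tangent Junction tangent direction, degrees.
#' @return Acute angle in `[0, 90]` degrees; NA if the orientation is
#'   undefined.
#' @export
#' @examples
#' junction_relative_angle(170, 10) # 20
junction_relative_angle <- function(result, junction_tangent) {
  orientation <- if (is.list(result)) {
    if (!isTRUE(result$defined)) return(NA_real_)
    result$orientation_deg
  } else result
  if (is.na(orientation)) return(NA_real_)
  fold_acute(orientation - junction_tangent)
}
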