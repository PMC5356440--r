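#' Polyline path in micrometre coordinates
#'
#' A `poly_path` is an ordered vertex chain in the image plane (µm; origin at
#' the field's top-left corner, y increasing downward). It serves both as a
#' junction trace (the cortical reference line for profiles, contacts and
#' angles) and as a microtubule/filament trace.
#'
#' @param x,y Numeric vertex coordinates in µm (>= 2 vertices).
#' @param kind `"junction"` or `"filament"`.
#' @param id Optional identifier.
#' @param cells Optional integer pair: the two mosaic cells adjacent to a
#'   junction edge.
#' @return A `poly_path` object.
#' @export
#' @examples
#' p <- poly_path(c(0, 10), c(5, 5))
#' path_length(p)
poly_path <- function(x, y, kind = c("junction", "filament"), id = NULL,
                      cells = NULL) {
  kind <- match.arg(kind)
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("a poly_path needs >= 2 (x, y) vertices")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("poly_path vertices must be finite")
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) stop_invalid("consecutive poly_path vertices must be distinct")
  structure(
    list(x = as.numeric(x), y = as.numeric(y), kind = kind, id = id,
         cells = cells),
    class = "poly_path"
  )
}

#' @export
print.poly_path <- function(x, ...) {
  cat(sprintf("<poly_path %s%s: %d vertices, length %.3g um>\n",
              x$kind, if (!is.null(x$id)) paste0(" '", x$id, "'") else "",
              length(x$x), path_length(x)))
  invisible(x)
}

seg_lengths <- function(p) sqrt(diff(p$x)^2 + diff(p$y)^2)

#' Total arc length of a path (µm)
#' @param p A [poly_path()].
#' @return Length in µm.
#' @export
path_length <- function(p) sum(seg_lengths(p))

#' Point on a path at given arc-length positions
#' @param p A [poly_path()].
#' @param s Arc-length position(s) in µm, clamped to `[0, path_length(p)]`.
#' @return A matrix with columns `x`, `y`.
#' @export
path_point <- function(p, s) {
  cl <- c(0, cumsum(seg_lengths(p)))
  s <- pmax(0, pmin(s, cl[length(cl)]))
  i <- pmin(findInterval(s, cl, rightmost.closed = TRUE), length(cl) - 1)
  t <- (s - cl[i]) / (cl[i + 1] - cl[i])
  cbind(x = p$x[i] + t * (p$x[i + 1] - p$x[i]),
        y = p$y[i] + t * (p$y[i + 1] - p$y[i]))
}

#' Tangent direction of a path at arc-length positions
#'
#' Within a segment the tangent is the segment direction; at an interior
#' vertex the directions of the two adjacent segments are averaged.
#'
#' @param p A [poly_path()].
#' @param s Arc-length position(s) in µm.
#' @return Tangent angle(s) in degrees (direction of increasing arc length).
#' @export
path_tangent <- function(p, s) {
  cl <- c(0, cumsum(seg_lengths(p)))
  n_seg <- length(cl) - 1
  dx <- diff(p$x); dy <- diff(p$y)
  len <- seg_lengths(p)
  ux <- dx / len; uy <- dy / len
  s <- pmax(0, pmin(s, cl[length(cl)]))
  i <- pmin(findInterval(s, cl, rightmost.closed = TRUE), n_seg)
  vx <- ux[i]; vy <- uy[i]
  # interior vertex: average adjacent unit tangents
  at_vertex <- which(abs(s - cl[i]) < 1e-12 & i > 1)
  if (length(at_vertex) > 0) {
    j <- i[at_vertex]
    vx[at_vertex] <- (ux[j - 1] + ux[j]) / 2
    vy[at_vertex] <- (uy[j - 1] + uy[j]) / 2
  }
  atan2(vy, vx) * 180 / pi
}

#' Nearest point on a path to query points
#'
#' @param p A [poly_path()].
#' @param pts Matrix or data frame with columns `x`, `y` (µm).
#' @return A data frame with `s` (arc length of the nearest point, µm) and
#'   `d` (distance to it, µm), one row per query point.
#' @export
nearest_on_path <- function(p, pts) {
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  cl <- c(0, cumsum(seg_lengths(p)))
  best_d2 <- rep(Inf, nrow(pts))
  best_s <- rep(0, nrow(pts))
  for (i in seq_len(length(p$x) - 1)) {
    ax <- p$x[i]; ay <- p$y[i]
    bx <- p$x[i + 1]; by <- p$y[i + 1]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- pmax(0, pmin(1, ((pts[, 1] - ax) * vx + (pts[, 2] - ay) * vy) / L2))
    dx <- pts[, 1] - (ax + t * vx)
    dy <- pts[, 2] - (ay + t * vy)
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cl[i] + t[upd] * sqrt(L2)
  }
  data.frame(s = best_s, d = sqrt(best_d2))
}

#' Minimum distance from points to a path (µm)
#' @inheritParams nearest_on_path
#' @return Numeric distances, one per query point.
#' @export
dist_to_path <- function(p, pts) nearest_on_path(p, pts)$d

# Sutherland-Hodgman clip of polygon (n x 2 matrix) against the half-plane
# {q : (q - a) . nrm <= 0}.
clip_halfplane <- function(poly, a, nrm) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  side <- (poly[, 1] - a[1]) * nrm[1] + (poly[, 2] - a[2]) * nrm[2]
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- side[i] <= 1e-12
    pj_in <- side[j] <= 1e-12
    if (pi_in) out <- rbind(out, poly[i, ])
    if (pi_in != pj_in) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}
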