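#' Generate a polygonal cell mosaic with junction edges
#'
#' Emulates a confluent epithelial sheet as a Voronoi partition of the field
#' seeded from uniformly placed cell centres. Each internal cell-cell edge is
#' returned once, as a straight junction [poly_path()] tagged with the two
#' adjacent cell indices. Edges on the field border are not junctions and are
#' omitted, so a single cell yields an empty list.
#'
#' @param n_cells Number of cells (>= 1).
#' @param field Field size `c(width, height)` in µm (both > 0).
#' @param seed Integer seed; the mosaic is a pure function of
#'   `(n_cells, field, seed)`.
#' @return List of junction `poly_path`s; each carries `cells = c(i, j)`
#'   (`i < j`) and id `"j<i>_<j>"`. The cell seed points are attached as
#'   attribute `"sites"`.
#' @export
#' @examples
#' paths <- make_cell_mosaic(9, c(30, 30), seed = 1)
#' length(paths)
make_cell_mosaic <- function(n_cells, field, seed = NULL) {
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1 ||
      n_cells != round(n_cells)) {
    stop_invalid("`n_cells` must be a positive integer")
  }
  if (length(field) != 2) stop_invalid("`field` must be c(width, height)")
  check_positive(field, "field")
  w <- field[1]; h <- field[2]

  sites <- with_seed(seed, {
    # mild inset keeps degenerate slivers off the border
    cbind(runif(n_cells, 0.02 * w, 0.98 * w),
          runif(n_cells, 0.02 * h, 0.98 * h))
  })

  out <- list()
  if (n_cells >= 2) {
    rect <- cbind(c(0, w, w, 0), c(0, 0, h, h))
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      poly <- rect
      for (j in seq_len(n_cells)[-i]) {
        mid <- (sites[i, ] + sites[j, ]) / 2
        nrm <- sites[j, ] - sites[i, ]
        poly <- clip_halfplane(poly, mid, nrm)
        if (nrow(poly) == 0) break
      }
      cells[[i]] <- poly
    }
    # classify each polygon edge by the second-nearest site at its midpoint
    for (i in seq_len(n_cells)) {
      poly <- cells[[i]]
      n <- nrow(poly)
      if (n < 2) next
      for (e in seq_len(n)) {
        a <- poly[e, ]
        b <- poly[if (e == n) 1L else e + 1L, ]
        if (sum((a - b)^2) < 1e-16) next
        mid <- (a + b) / 2
        d <- sqrt((sites[, 1] - mid[1])^2 + (sites[, 2] - mid[2])^2)
        ord <- order(d)
        j <- if (ord[1] == i) ord[2] else ord[1]
        if (j > i && abs(d[j] - d[i]) < 1e-6 * max(1, d[i])) {
          out[[length(out) + 1]] <- poly_path(
            c(a[1], b[1]), c(a[2], b[2]), kind = "junction",
            id = sprintf("j%d_%d", i, j), cells = c(i, j))
        }
      }
    }
  }
  attr(out, "sites") <- sites
  out
}
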