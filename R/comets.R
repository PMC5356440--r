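# Fixed-image comet detection: background subtraction, threshold, connected
# components, area gate. One parameter set must be applied to every image of
# a comparison group; the pipeline enforces that, and the detector records
# its parameters in the returned object's attributes.

# 8-connected labelling of a logical mask (EBImage's bwlabel is 4-connected,
# so components are built on a pixel-adjacency graph instead)
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  id_of <- integer(nr * nc)
  id_of[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  c <- ((fg - 1L) %/% nr) + 1L
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (sh in shifts) {
    r2 <- r + sh[1]; c2 <- c + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    both <- mask[lin2]
    edges[[length(edges) + 1]] <- cbind(id_of[fg[ok]][both], id_of[lin2][both])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Detect comets with background subtraction, threshold and area gating
#'
#' Implements the fixed-image comet count: a background estimate is
#' subtracted, a binary mask is produced by a global threshold, 8-connected
#' components are extracted, and components whose calibrated area lies in
#' `[area_min, area_max]` µm² (both ends inclusive) are returned with
#' centroid and summed intensity. The same parameters must be applied to
#' every image in a comparison group.
#'
#' @param image An [image_grid()].
#' @param background_method `"median"` (median filter, window
#'   `bg_window_um`) or `"constant"` (subtract the 5th-percentile
#'   intensity).
#' @param threshold_method `"otsu"` (on the background-subtracted image) or
#'   a numeric threshold in intensity units.
#' @param area_min,area_max Area gate, µm² (defaults 0.2 and 1.2; at 0.1
#'   µm/px that is 20-120 px).
#' @param bg_window_um Median-filter window, µm (default 5).
#' @return Tibble of class `comet_detections`: `x_um`, `y_um`, `area_um2`,
#'   `n_px`, `intensity`, `frame`; detection parameters stored in attribute
#'   `"params"`. A blank or saturated image yields zero rows with a warning.
#' @export
detect_comets <- function(image, background_method = "median",
                          threshold_method = "otsu",
                          area_min = 0.2, area_max = 1.2,
                          bg_window_um = 5) {
  stopifnot(inherits(image, "image_grid"))
  if (!(area_min < area_max)) stop_invalid("need area_min < area_max")
  check_positive(area_min, "area_min")
  ps <- image$pixel_size
  v <- image$values
  params <- list(background_method = background_method,
                 threshold_method = threshold_method,
                 area_min = area_min, area_max = area_max,
                 bg_window_um = bg_window_um, pixel_size = ps)
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0), n_px = integer(0),
                          intensity = numeric(0), frame = integer(0))
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    warning("blank or saturated image: no detections", call. = FALSE)
    return(structure(empty, class = c("comet_detections", class(empty)),
                     params = params))
  }
  if (identical(background_method, "median")) {
    radius <- max(1L, as.integer(round(bg_window_um / (2 * ps))))
    radius <- min(radius, (min(dim(v)) - 1L) %/% 2L)
    norm <- (v - rng[1]) / diff(rng)
    bg <- as.matrix(EBImage::medianFilter(EBImage::Image(norm), radius))
    bg <- bg * diff(rng) + rng[1]
  } else if (identical(background_method, "constant")) {
    bg <- matrix(as.numeric(quantile(v, 0.05)), nrow(v), ncol(v))
  } else {
    stop_invalid("unknown background_method '", background_method, "'")
  }
  sub <- pmax(v - bg, 0)
  if (identical(threshold_method, "otsu")) {
    m <- max(sub)
    if (m <= 0) {
      warning("background subtraction left no signal: no detections",
              call. = FALSE)
      return(structure(empty, class = c("comet_detections", class(empty)),
                       params = params))
    }
    th <- EBImage::otsu(EBImage::Image(sub / m), range = c(0, 1)) * m
  } else if (is.numeric(threshold_method)) {
    th <- threshold_method
  } else {
    stop_invalid("unknown threshold_method")
  }
  mask <- sub > th
  lab <- label_components8(mask)
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(structure(empty, class = c("comet_detections", class(empty)),
                     params = params))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  r <- ((idx - 1L) %% nrow(v)) + 1L
  c <- ((idx - 1L) %/% nrow(v)) + 1L
  n_px <- tabulate(comp, n_comp)
  cx <- tapply((c - 0.5) * ps, comp, mean)
  cy <- tapply((r - 0.5) * ps, comp, mean)
  itot <- tapply(sub[idx], comp, sum)
  area <- n_px * ps^2
  tol <- 1e-9
  keep <- area >= area_min - tol & area <= area_max + tol
  det <- tibble::tibble(
    x_um = as.numeric(cx[keep]), y_um = as.numeric(cy[keep]),
    area_um2 = area[keep], n_px = n_px[keep],
    intensity = as.numeric(itot[keep]), frame = 0L)
  det <- det[order(det$y_um, det$x_um), ]
  structure(det, class = c("comet_detections", class(det)), params = params)
}

#' Count comets per cortical box
#'
#' Counts detections whose centroid falls in each box. Left/top box edges
#' are inclusive and right/bottom edges exclusive so that tiled boxes
#' partition the plane without double counting.
#'
#' @param detections A data frame with `x_um`, `y_um` (e.g. from
#'   [detect_comets()]).
#' @param boxes List of [cortical_box()]es.
#' @return Tibble with `box_id` and `n_comets`.
#' @export
comets_per_box <- function(detections, boxes) {
  rows <- lapply(seq_along(boxes), function(k) {
    b <- boxes[[k]]
    tibble::tibble(
      box_id = if (!is.null(b$box_id)) b$box_id else sprintf("box%02d", k),
      n_comets = sum(in_box(b, detections$x_um, detections$y_um)))
  })
  dplyr::bind_rows(rows)
}

#' Match detections to ground truth and score precision/recall
#'
#' Greedy nearest-pair matching within `max_dist`; each truth point and each
#' detection is used at most once.
#'
#' @param detections Data frame with `x_um`, `y_um`.
#' @param truth Data frame with `x`, `y` (µm).
#' @param max_dist Match radius, µm (default 0.3).
#' @return List with `precision`, `recall`, `n_matched`.
#' @export
match_detections <- function(detections, truth, max_dist = 0.3) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(precision = ifelse(nd == 0, NA_real_, 0),
                recall = ifelse(nt == 0, NA_real_, 0), n_matched = 0L))
  }
  dmat <- outer(detections$x_um, truth$x, "-")^2 +
    outer(detections$y_um, truth$y, "-")^2
  dmat <- sqrt(dmat)
  matched <- 0L
  repeat {
    m <- which.min(dmat)
    if (dmat[m] > max_dist) break
    i <- ((m - 1) %% nd) + 1
    j <- ((m - 1) %/% nd) + 1
    matched <- matched + 1L
    dmat[i, ] <- Inf
    dmat[, j] <- Inf
    if (!any(is.finite(dmat))) break
  }
  list(precision = matched / nd, recall = matched / nt, n_matched = matched)
}
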