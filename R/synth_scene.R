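# Seeded synthetic fluorescence scenes with ground truth. The generators
# emulate the structures the measurement modules quantify: junction ridges,
# junction-enriched puncta, filament fields with a controlled approach-angle
# distribution, and elliptical comet spots. Noise is additive Gaussian with a
# floor at zero intensity.

# minimum distance from every pixel centre to any of a set of poly_paths
min_dist_raster <- function(paths, field, pixel_size) {
  nc <- max(1L, round(field[1] / pixel_size))
  nr <- max(1L, round(field[2] / pixel_size))
  px <- (seq_len(nc) - 0.5) * pixel_size
  py <- (seq_len(nr) - 0.5) * pixel_size
  X <- matrix(px, nr, nc, byrow = TRUE)
  Y <- matrix(py, nr, nc)
  d2 <- matrix(Inf, nr, nc)
  for (p in paths) {
    for (i in seq_len(length(p$x) - 1)) {
      ax <- p$x[i]; ay <- p$y[i]
      vx <- p$x[i + 1] - ax; vy <- p$y[i + 1] - ay
      L2 <- vx^2 + vy^2
      t <- pmax(0, pmin(1, ((X - ax) * vx + (Y - ay) * vy) / L2))
      dx <- X - (ax + t * vx); dy <- Y - (ay + t * vy)
      d2 <- pmin(d2, dx^2 + dy^2)
    }
  }
  sqrt(d2)
}

add_noise_clip <- function(values, noise_sd) {
  if (noise_sd > 0) values <- values + rnorm(length(values), 0, noise_sd)
  pmax(values, 0)
}

#' Render junction traces as a ridge image
#'
#' Each path becomes a ridge with Gaussian cross-section (the intensity at
#' perpendicular distance d from the nearest path is
#' `background + amplitude * exp(-d^2 / (2 * profile_sigma^2))`), emulating a
#' fixed-exposure junction-marker image. Seeded Gaussian noise is added and
#' intensities are clipped at zero.
#'
#' @param paths List of [poly_path()]s (may be empty: blank image).
#' @param field Field size `c(width, height)`, µm.
#' @param profile_sigma Ridge cross-section SD, µm (> 0).
#' @param amplitude Ridge peak intensity above background (>= 0).
#' @param background Constant background intensity (>= 0).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param pixel_size µm/px.
#' @param seed Integer seed for the noise.
#' @param exposure_group Label propagated to the image.
#' @return An [image_grid()].
#' @export
render_junction_scene <- function(paths, field, profile_sigma,
                                  amplitude = 100, background = 0,
                                  noise_sd = 0, pixel_size = 0.1,
                                  seed = NULL, exposure_group = "default") {
  check_positive(profile_sigma, "profile_sigma")
  check_positive(pixel_size, "pixel_size")
  check_nonneg(amplitude, "amplitude")
  check_nonneg(background, "background")
  check_nonneg(noise_sd, "noise_sd")
  check_positive(field, "field")
  if (length(paths) == 0) {
    nc <- max(1L, round(field[1] / pixel_size))
    nr <- max(1L, round(field[2] / pixel_size))
    vals <- matrix(background, nr, nc)
  } else {
    d <- min_dist_raster(paths, field, pixel_size)
    vals <- background + amplitude * exp(-d^2 / (2 * profile_sigma^2))
  }
  vals <- with_seed(seed, add_noise_clip(vals, noise_sd))
  image_grid(vals, pixel_size, exposure_group)
}

# add isotropic Gaussian spots to an intensity matrix (local windows, max 4 sd)
render_spots <- function(vals, pixel_size, x, y, amplitude, sigma) {
  nr <- nrow(vals); nc <- ncol(vals)
  half <- ceiling(4 * sigma / pixel_size)
  for (k in seq_along(x)) {
    c0 <- floor(x[k] / pixel_size + 0.5)
    r0 <- floor(y[k] / pixel_size + 0.5)
    cs <- max(1, c0 - half):min(nc, c0 + half)
    rs <- max(1, r0 - half):min(nr, r0 + half)
    if (length(cs) == 0 || length(rs) == 0) next
    dx <- (cs - 0.5) * pixel_size - x[k]
    dy <- (rs - 0.5) * pixel_size - y[k]
    g <- amplitude[k] * outer(exp(-dy^2 / (2 * sigma^2)),
                              exp(-dx^2 / (2 * sigma^2)))
    vals[rs, cs] <- vals[rs, cs] + g
  }
  vals
}

#' Place cortical puncta with junctional enrichment
#'
#' Emulates a punctate cortical protein (e.g. a junction-recruited MTOC
#' component) over a cell mosaic: background puncta follow a homogeneous
#' Poisson process over the field, and junctional puncta follow a Poisson
#' process along the junction paths with linear density
#' `junction_density * enrichment_factor`, displaced off the path by a
#' centred normal with SD `band_width / 2`. Lowering `enrichment_factor`
#' is the generator's knob for a junctional-signal reduction.
#'
#' @param paths List of junction [poly_path()]s.
#' @inheritParams render_junction_scene
#' @param base_density Background puncta per µm² (>= 0).
#' @param junction_density Junctional puncta per µm of path at
#'   `enrichment_factor = 1` (>= 0).
#' @param band_width Junctional band width, µm (> 0); displacement SD is
#'   `band_width / 2`.
#' @param enrichment_factor Dimensionless >= 0; 0 means no junctional puncta.
#' @param amplitude Peak intensity of one punctum.
#' @param punct_sigma Punctum Gaussian SD, µm.
#' @return List with `puncta` (tibble `x`, `y`, `amplitude`, `on_junction`)
#'   and `image` (an [image_grid()]).
#' @export
place_cortical_puncta <- function(paths, field, base_density,
                                  junction_density, band_width,
                                  enrichment_factor, seed = NULL,
                                  amplitude = 100, punct_sigma = 0.15,
                                  background = 0, noise_sd = 0,
                                  pixel_size = 0.1,
                                  exposure_group = "default") {
  check_nonneg(base_density, "base_density")
  check_nonneg(junction_density, "junction_density")
  check_positive(band_width, "band_width")
  check_nonneg(enrichment_factor, "enrichment_factor")
  check_positive(field, "field")
  with_seed(seed, {
    n_bg <- rpois(1, base_density * field[1] * field[2])
    bg <- tibble::tibble(
      x = runif(n_bg, 0, field[1]), y = runif(n_bg, 0, field[2]),
      amplitude = rep(amplitude, n_bg), on_junction = FALSE)
    jx <- numeric(0); jy <- numeric(0)
    lam <- junction_density * enrichment_factor
    if (lam > 0) {
      for (p in paths) {
        L <- path_length(p)
        n_j <- rpois(1, lam * L)
        if (n_j == 0) next
        s <- runif(n_j, 0, L)
        pt <- path_point(p, s)
        tg <- path_tangent(p, s) * pi / 180
        off <- rnorm(n_j, 0, band_width / 2)
        jx <- c(jx, pt[, "x"] - off * sin(tg))
        jy <- c(jy, pt[, "y"] + off * cos(tg))
      }
    }
    jn <- tibble::tibble(x = jx, y = jy,
                         amplitude = rep(amplitude, length(jx)),
                         on_junction = TRUE)
    puncta <- dplyr::bind_rows(bg, jn)
    keep <- puncta$x >= 0 & puncta$x <= field[1] &
      puncta$y >= 0 & puncta$y <= field[2]
    puncta <- puncta[keep, ]
    nc <- max(1L, round(field[1] / pixel_size))
    nr <- max(1L, round(field[2] / pixel_size))
    vals <- matrix(background, nr, nc)
    vals <- render_spots(vals, pixel_size, puncta$x, puncta$y,
                         puncta$amplitude, punct_sigma)
    vals <- add_noise_clip(vals, noise_sd)
    list(puncta = puncta,
         image = image_grid(vals, pixel_size, exposure_group))
  })
}

#' Draw straight filaments approaching junctions at controlled angles
#'
#' Each filament is a straight [poly_path()] whose cortex-proximal end lies
#' just off a junction path; its approach angle to the local junction tangent
#' is drawn from an axial von Mises distribution centred at `target_angle`
#' (concentration `kappa`, folded into `[0, 90]` degrees; `kappa = 0` gives
#' the uniform distribution on `[0, 90]`). Ground-truth angles are recorded
#' per filament.
#'
#' @param paths List of junction [poly_path()]s.
#' @inheritParams render_junction_scene
#' @param n_filaments Number of filaments (0 allowed: empty outputs).
#' @param target_angle Central approach angle, degrees in `[0, 90]`.
#' @param kappa von Mises concentration (>= 0; capped at 1e6).
#' @param length_range Filament length range `c(min, max)`, µm.
#' @param filament_sigma Rendered ridge SD, µm.
#' @return List with `filaments` (list of `poly_path`, first vertex =
#'   cortex-proximal end), `truth` (tibble `id`, `x1`, `y1`, `x2`, `y2`,
#'   `angle_truth`) and `image`.
#' @export
draw_filament_set <- function(paths, n_filaments, target_angle, kappa,
                              length_range, field, seed = NULL,
                              pixel_size = 0.1, filament_sigma = 0.08,
                              amplitude = 100, background = 0, noise_sd = 0,
                              exposure_group = "default") {
  if (target_angle < 0 || target_angle > 90) {
    stop_invalid("`target_angle` must lie in [0, 90] degrees")
  }
  check_nonneg(kappa, "kappa")
  check_positive(field, "field")
  if (length(length_range) != 2 || any(length_range <= 0) ||
      length_range[1] > length_range[2]) {
    stop_invalid("`length_range` must be c(min, max) with 0 < min <= max")
  }
  if (n_filaments < 0 || n_filaments != round(n_filaments)) {
    stop_invalid("`n_filaments` must be a non-negative integer")
  }
  with_seed(seed, {
    filaments <- list()
    truth <- tibble::tibble(id = character(0), x1 = numeric(0),
                            y1 = numeric(0), x2 = numeric(0),
                            y2 = numeric(0), angle_truth = numeric(0))
    if (n_filaments > 0) {
      lens <- vapply(paths, path_length, numeric(1))
      pick <- sample.int(length(paths), n_filaments, replace = TRUE,
                         prob = lens)
      # axial von Mises: sample on the doubled circle so kappa = 0 is
      # uniform over orientations and large kappa concentrates at target
      dev <- rvonmises(n_filaments, 0, kappa) * 90 / pi
      ang <- fold_acute(target_angle + dev)
      L <- runif(n_filaments, length_range[1], length_range[2])
      d0 <- runif(n_filaments, 0.02, 0.15)
      side <- sample(c(-1, 1), n_filaments, replace = TRUE)
      for (k in seq_len(n_filaments)) {
        p <- paths[[pick[k]]]
        s <- runif(1, 0, path_length(p))
        J <- path_point(p, s)[1, ]
        tg <- path_tangent(p, s)
        phi <- (tg + side[k] * ang[k]) * pi / 180
        u <- c(cos(phi), sin(phi))
        # orient into the field if the ray exits immediately
        probe <- J + 0.5 * u
        if (probe[1] < 0 || probe[1] > field[1] ||
            probe[2] < 0 || probe[2] > field[2]) u <- -u
        E <- J + d0[k] * u
        # shorten so the far end stays inside the field
        t_max <- L[k]
        for (dim in 1:2) {
          if (u[dim] > 1e-12) t_max <- min(t_max, (field[dim] - E[dim]) / u[dim])
          if (u[dim] < -1e-12) t_max <- min(t_max, -E[dim] / u[dim])
        }
        t_max <- max(t_max, 0.3)
        F_ <- E + t_max * u
        E <- pmax(c(0, 0), pmin(E, field))
        F_ <- pmax(c(0, 0), pmin(F_, field))
        id <- sprintf("f%04d", k)
        filaments[[k]] <- poly_path(c(E[1], F_[1]), c(E[2], F_[2]),
                                    kind = "filament", id = id)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          id = id, x1 = E[1], y1 = E[2], x2 = F_[1], y2 = F_[2],
          angle_truth = ang[k]))
      }
    }
    if (length(filaments) > 0) {
      d <- min_dist_raster(filaments, field, pixel_size)
      vals <- background + amplitude * exp(-d^2 / (2 * filament_sigma^2))
    } else {
      nc <- max(1L, round(field[1] / pixel_size))
      nr <- max(1L, round(field[2] / pixel_size))
      vals <- matrix(background, nr, nc)
    }
    vals <- add_noise_clip(vals, noise_sd)
    list(filaments = filaments, truth = truth,
         image = image_grid(vals, pixel_size, exposure_group))
  })
}

#' Simulate comet spot fields
#'
#' Comet count per frame is Poisson with mean `density * field_area / 100`
#' (density is given per 100 µm², the area of one 10 x 10 µm box); each comet
#' is rendered as a filled ellipse (2:1 axis ratio, uniform orientation) with
#' true area uniform in `area_range`.
#'
#' @inheritParams render_junction_scene
#' @param density Comets per 100 µm² (>= 0).
#' @param area_range Comet area range `c(min, max)`, µm², inside the field
#'   area.
#' @param n_frames Number of independent frames.
#' @param amplitude Spot intensity above background.
#' @return List with `truth` (tibble `frame`, `x`, `y`, `area_um2`) and
#'   `images` (list of [image_grid()], one per frame).
#' @export
simulate_comet_frames <- function(density, area_range, field,
                                  pixel_size = 0.1, n_frames = 1,
                                  amplitude = 100, background = 10,
                                  noise_sd = 0, seed = NULL,
                                  exposure_group = "default") {
  check_nonneg(density, "density")
  check_positive(field, "field")
  if (length(area_range) != 2 || area_range[1] <= 0 ||
      area_range[1] > area_range[2] ||
      area_range[2] >= field[1] * field[2]) {
    stop_invalid("`area_range` must satisfy 0 < min <= max < field area")
  }
  nc <- max(1L, round(field[1] / pixel_size))
  nr <- max(1L, round(field[2] / pixel_size))
  with_seed(seed, {
    truth <- list(); images <- list()
    for (f in seq_len(n_frames)) {
      n <- rpois(1, density * field[1] * field[2] / 100)
      x <- runif(n, 0, field[1]); y <- runif(n, 0, field[2])
      area <- runif(n, area_range[1], area_range[2])
      theta <- runif(n, 0, pi)
      vals <- matrix(background, nr, nc)
      ratio <- 2
      a <- sqrt(area * ratio / pi); b <- sqrt(area / (ratio * pi))
      for (k in seq_len(n)) {
        half <- ceiling(a[k] / pixel_size) + 1
        c0 <- floor(x[k] / pixel_size + 0.5)
        r0 <- floor(y[k] / pixel_size + 0.5)
        cs <- max(1, c0 - half):min(nc, c0 + half)
        rs <- max(1, r0 - half):min(nr, r0 + half)
        dx <- outer(rep(1, length(rs)), (cs - 0.5) * pixel_size - x[k])
        dy <- outer((rs - 0.5) * pixel_size - y[k], rep(1, length(cs)))
        ct <- cos(theta[k]); st <- sin(theta[k])
        inside <- ((dx * ct + dy * st) / a[k])^2 +
          ((-dx * st + dy * ct) / b[k])^2 <= 1
        blk <- vals[rs, cs, drop = FALSE]
        blk[inside] <- pmax(blk[inside], background + amplitude)
        vals[rs, cs] <- blk
      }
      vals <- add_noise_clip(vals, noise_sd)
      truth[[f]] <- tibble::tibble(frame = f, x = x, y = y, area_um2 = area)
      images[[f]] <- image_grid(vals, pixel_size, exposure_group)
    }
    list(truth = dplyr::bind_rows(truth), images = images)
  })
}
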