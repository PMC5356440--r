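# Independent reference implementations (deliberately written as plain
# loops, separate from the package's vectorized code) plus small scene
# builders shared across tests.

# straight horizontal ridge image through y = y0
ridge_image <- function(width = 20, height = 20, y0 = 10, sigma = 0.3,
                        amplitude = 100, background = 0, pixel_size = 0.1) {
  p <- poly_path(c(1, width - 1), c(y0, y0))
  img <- render_junction_scene(list(p), c(width, height), sigma,
                               amplitude = amplitude,
                               background = background, noise_sd = 0,
                               pixel_size = pixel_size)
  list(image = img, path = p)
}

# track with prescribed per-segment displacements (µm), starting at origin
track_from_steps <- function(dx, dy, frame_interval = 1, id = "t1",
                             cell_id = "cell1", treatment = "control") {
  comet_track(seq_len(length(dx) + 1),
              c(0, cumsum(dx)), c(0, cumsum(dy)),
              frame_interval, track_id = id, cell_id = cell_id,
              treatment = treatment)
}

# reference bend splitter: explicit scan over consecutive segment pairs
oracle_split_frames <- function(track, theta_max = 30) {
  n <- length(track$frames)
  ang <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    ang[i] <- atan2(track$y[i + 1] - track$y[i],
                    track$x[i + 1] - track$x[i]) * 180 / pi
  }
  frags <- list()
  cur <- c(1L, 2L)
  for (i in seq_len(n - 2)) {
    d <- abs(ang[i + 1] - ang[i]) %% 360
    if (d > 180) d <- 360 - d
    if (d > theta_max) {
      frags[[length(frags) + 1]] <- cur
      cur <- c(i + 1L, i + 2L)
    } else {
      cur <- c(cur, i + 2L)
    }
  }
  frags[[length(frags) + 1]] <- cur
  Filter(function(ix) length(ix) >= 2, frags)
}

# reference event classifier: explicit state vector scan
oracle_event_states <- function(speeds, pause_speed_max = 1.5,
                                min_pause_frames = 2) {
  n <- length(speeds)
  state <- rep("growth", n)
  if (n < min_pause_frames) {
    return(rep(if (mean(speeds) < pause_speed_max) "pause" else "growth", n))
  }
  i <- 1
  while (i <= n) {
    if (speeds[i] < pause_speed_max) {
      j <- i
      while (j < n && speeds[j + 1] < pause_speed_max) j <- j + 1
      if (j - i + 1 >= min_pause_frames) state[i:j] <- "pause"
      i <- j + 1
    } else i <- i + 1
  }
  state
}

# exhaustive optimal partial matching between two small point sets: maximal
# number of links within max_dist, then minimal total distance
oracle_match <- function(p1, p2, max_dist) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  best <- list(n = -1, cost = Inf, assign = rep(NA_integer_, n1))
  assign <- rep(NA_integer_, n1)
  recurse <- function(i, used, n_match, cost) {
    if (i > n1) {
      if (n_match > best$n || (n_match == best$n && cost < best$cost)) {
        best <<- list(n = n_match, cost = cost, assign = assign)
      }
      return(invisible())
    }
    recurse(i + 1, used, n_match, cost)   # leave i unmatched
    for (j in seq_len(n2)) {
      if (used[j]) next
      d <- sqrt(sum((p1[i, ] - p2[j, ])^2))
      if (d <= max_dist) {
        assign[i] <<- j
        used[j] <- TRUE
        recurse(i + 1, used, n_match + 1, cost + d)
        used[j] <- FALSE
        assign[i] <<- NA_integer_
      }
    }
  }
  recurse(1, rep(FALSE, n2), 0L, 0)
  best$assign
}

# rotate a poly_path about a point
rotate_path <- function(p, theta_deg, centre = c(0, 0)) {
  th <- theta_deg * pi / 180
  dx <- p$x - centre[1]; dy <- p$y - centre[2]
  poly_path(centre[1] + dx * cos(th) - dy * sin(th),
            centre[2] + dx * sin(th) + dy * cos(th),
            kind = p$kind, id = p$id)
}
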