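#' Time-ordered comet trajectory
#'
#' The substrate of the dynamics analysis: comet positions per frame with
#' acquisition calibration. Frames must be strictly increasing; at least two
#' frames are required.
#'
#' @param frames Strictly increasing integer frame indices (>= 2).
#' @param x,y Positions per frame, µm.
#' @param frame_interval Time between consecutive frame indices, seconds
#'   (> 0).
#' @param track_id,cell_id,treatment Identifiers carried through the
#'   analysis.
#' @param state Optional per-frame ground-truth state labels
#'   (`"growth"`/`"pause"`), used by the simulator.
#' @return A `comet_track` object.
#' @export
comet_track <- function(frames, x, y, frame_interval,
                        track_id = "t1", cell_id = "cell1",
                        treatment = "control", state = NULL) {
  if (length(frames) < 2) stop_invalid("a comet_track needs >= 2 frames")
  if (any(diff(frames) <= 0)) stop_invalid("frames must be strictly increasing")
  if (length(x) != length(frames) || length(y) != length(frames)) {
    stop_invalid("x, y must match frames in length")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("positions must be finite")
  }
  check_positive(frame_interval, "frame_interval")
  if (!is.null(state) && length(state) != length(frames)) {
    stop_invalid("state labels must match frames in length")
  }
  structure(
    list(frames = as.integer(frames), x = as.numeric(x), y = as.numeric(y),
         frame_interval = frame_interval, track_id = track_id,
         cell_id = cell_id, treatment = treatment, state = state),
    class = "comet_track"
  )
}

#' @export
print.comet_track <- function(x, ...) {
  cat(sprintf("<comet_track '%s' (%s/%s): %d frames @ %gs>\n",
              x$track_id, x$cell_id, x$treatment, length(x$frames),
              x$frame_interval))
  invisible(x)
}

#' Flatten a list of comet tracks into a tidy table
#' @param tracks List of [comet_track()]s.
#' @return Tibble with `track_id`, `cell_id`, `treatment`, `frame`, `x_um`,
#'   `y_um` (and `state` when present).
#' @export
tracks_to_table <- function(tracks) {
  dplyr::bind_rows(lapply(tracks, function(tr) {
    tb <- tibble::tibble(track_id = tr$track_id, cell_id = tr$cell_id,
                         treatment = tr$treatment, frame = tr$frames,
                         x_um = tr$x, y_um = tr$y)
    if (!is.null(tr$state)) tb$state <- tr$state
    tb
  }))
}

#' Rebuild comet tracks from a tidy table
#' @param tab Data frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (optional `cell_id`, `treatment`, `state`).
#' @param frame_interval Seconds per frame.
#' @return List of [comet_track()]s.
#' @export
tracks_from_table <- function(tab, frame_interval) {
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop_invalid("track table is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  split_rows <- split(seq_len(nrow(tab)), tab$track_id)
  lapply(unname(split_rows), function(ix) {
    rows <- tab[ix, ][order(tab$frame[ix]), ]
    comet_track(
      frames = rows$frame, x = rows$x_um, y = rows$y_um,
      frame_interval = frame_interval,
      track_id = as.character(rows$track_id[1]),
      cell_id = if ("cell_id" %in% names(rows)) as.character(rows$cell_id[1]) else "cell1",
      treatment = if ("treatment" %in% names(rows)) as.character(rows$treatment[1]) else "control",
      state = if ("state" %in% names(rows)) as.character(rows$state) else NULL)
  })
}

# per-segment displacement (µm) and speed (µm/min); n - 1 entries
segment_speeds <- function(track) {
  dx <- diff(track$x); dy <- diff(track$y)
  dt_min <- diff(track$frames) * track$frame_interval / 60
  disp <- sqrt(dx^2 + dy^2)
  list(disp = disp, speed = disp / dt_min,
       angle = atan2(dy, dx) * 180 / pi)
}

#' Simulate two-state (growth/pause) comet trajectories
#'
#' Each track is a two-state Markov chain. The state of frame i governs the
#' displacement from frame i to i + 1: in growth, the step length is
#' `Normal(v_growth, v_sd)` µm/min times the frame interval, along a
#' persistent direction with small angular wobble; in pause, only isotropic
#' positional jitter. Per-frame state labels are emitted as ground truth
#' (the last frame repeats the label of the final interval).
#'
#' @param n_tracks Number of tracks.
#' @param v_growth Mean growth speed, µm/min (> 0).
#' @param v_sd SD of the growth speed, µm/min (>= 0).
#' @param p_gp,p_pg Per-frame transition probabilities growth->pause and
#'   pause->growth, each in `[0, 1]`.
#' @param frame_interval Seconds per frame.
#' @param n_frames Frames per track (>= 2).
#' @param seed Integer seed.
#' @param field Field size `c(width, height)`, µm; starting points are
#'   uniform over it (positions may wander outside; the dynamics analysis
#'   does not require containment).
#' @param pause_jitter_sd Positional jitter SD per frame in pause, µm.
#' @param dir_wobble_sd Angular wobble SD per growth step, degrees.
#' @param cell_id,treatment Labels attached to every track.
#' @return List of [comet_track()]s with ground-truth `state` labels.
#' @export
simulate_dynamic_tracks <- function(n_tracks, v_growth, v_sd, p_gp, p_pg,
                                    frame_interval, n_frames, seed = NULL,
                                    field = c(50, 50),
                                    pause_jitter_sd = 0.01,
                                    dir_wobble_sd = 3,
                                    cell_id = "cell1",
                                    treatment = "control") {
  check_positive(v_growth, "v_growth")
  check_nonneg(v_sd, "v_sd")
  check_prob(p_gp, "p_gp")
  check_prob(p_pg, "p_pg")
  check_positive(frame_interval, "frame_interval")
  if (n_frames < 2) stop_invalid("`n_frames` must be >= 2")
  dt_min <- frame_interval / 60
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(k) {
      x <- numeric(n_frames); y <- numeric(n_frames)
      st <- character(n_frames)
      x[1] <- runif(1, 0, field[1]); y[1] <- runif(1, 0, field[2])
      dir <- runif(1, 0, 2 * pi)
      s <- "growth"
      for (i in seq_len(n_frames - 1)) {
        st[i] <- s
        if (s == "growth") {
          step <- max(0, rnorm(1, v_growth, v_sd)) * dt_min
          dir <- dir + rnorm(1, 0, dir_wobble_sd * pi / 180)
          x[i + 1] <- x[i] + step * cos(dir)
          y[i + 1] <- y[i] + step * sin(dir)
          if (runif(1) < p_gp) s <- "pause"
        } else {
          x[i + 1] <- x[i] + rnorm(1, 0, pause_jitter_sd)
          y[i + 1] <- y[i] + rnorm(1, 0, pause_jitter_sd)
          if (runif(1) < p_pg) s <- "growth"
        }
      }
      st[n_frames] <- st[n_frames - 1]
      comet_track(seq_len(n_frames), x, y, frame_interval,
                  track_id = sprintf("sim%04d", k), cell_id = cell_id,
                  treatment = treatment, state = st)
    })
  })
}
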