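# Comet-track linking (plumbing) and the post-tracking dynamics analysis:
# bend-based splitting, growth/pause event classification, per-cell
# summaries and the four-speed-group distribution with the fastest-cell
# vmax rule.

#' Link per-frame detections into tracks (greedy nearest neighbour)
#'
#' Frame-to-frame assignment by repeatedly linking the globally closest
#' (track head, detection) pair — a mutual-nearest greedy rule. A track may
#' bridge up to `max_gap` missing frames; across a gap of g frames the
#' allowed linking distance is `max_disp * (g + 1)` (per-frame rate times
#' elapsed frames). Unassigned detections seed new tracks; tracks with a
#' single frame are dropped. This is a deliberately simple linker for
#' low-density data, not a re-implementation of multi-hypothesis tracking.
#'
#' @param per_frame List of data frames (one per frame, empty allowed) with
#'   columns `x_um`, `y_um`.
#' @param max_disp Maximum displacement per frame, µm (> 0).
#' @param max_gap Maximum bridged gap, frames (>= 0).
#' @param frame_interval Seconds per frame.
#' @param cell_id,treatment Labels attached to the tracks.
#' @return List of [comet_track()]s.
#' @export
link_detections <- function(per_frame, max_disp, max_gap = 0,
                            frame_interval = 1, cell_id = "cell1",
                            treatment = "control") {
  check_positive(max_disp, "max_disp")
  if (max_gap < 0) stop_invalid("`max_gap` must be >= 0")
  active <- list()   # each: list(frames, x, y, last_frame)
  done <- list()
  for (t in seq_along(per_frame)) {
    det <- per_frame[[t]]
    nd <- if (is.null(det)) 0L else nrow(det)
    # retire tracks whose gap can no longer be bridged
    if (length(active) > 0) {
      gap <- t - vapply(active, function(a) a$last_frame, numeric(1))
      retire <- gap > max_gap + 1
      done <- c(done, active[retire])
      active <- active[!retire]
    }
    assigned_det <- rep(FALSE, nd)
    if (length(active) > 0 && nd > 0) {
      hx <- vapply(active, function(a) a$x[length(a$x)], numeric(1))
      hy <- vapply(active, function(a) a$y[length(a$y)], numeric(1))
      gap <- t - vapply(active, function(a) a$last_frame, numeric(1))
      dmat <- sqrt(outer(hx, det$x_um, "-")^2 + outer(hy, det$y_um, "-")^2)
      allowed <- max_disp * gap
      dmat[dmat > matrix(allowed, nrow(dmat), nd)] <- Inf
      na <- length(active)
      repeat {
        m <- which.min(dmat)
        if (!is.finite(dmat[m])) break
        i <- ((m - 1) %% na) + 1
        j <- ((m - 1) %/% na) + 1
        active[[i]]$frames <- c(active[[i]]$frames, t)
        active[[i]]$x <- c(active[[i]]$x, det$x_um[j])
        active[[i]]$y <- c(active[[i]]$y, det$y_um[j])
        active[[i]]$last_frame <- t
        assigned_det[j] <- TRUE
        dmat[i, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    if (nd > 0) {
      for (j in which(!assigned_det)) {
        active[[length(active) + 1]] <- list(
          frames = t, x = det$x_um[j], y = det$y_um[j], last_frame = t)
      }
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$frames) >= 2, done)
  lapply(seq_along(done), function(k) {
    a <- done[[k]]
    comet_track(a$frames, a$x, a$y, frame_interval,
                track_id = sprintf("trk%04d", k),
                cell_id = cell_id, treatment = treatment)
  })
}

#' Split tracks at sharp bends
#'
#' Filters out abnormally bendy trajectories by splitting a track wherever
#' the orientations of consecutive frame-to-frame segments differ by
#' strictly more than `theta_max` degrees (differences folded into
#' `[0, 180]`). Fragments with fewer than 2 frames are discarded; fragment
#' ids derive from the parent id.
#'
#' @param track A [comet_track()].
#' @param theta_max Bend threshold, degrees (default 30).
#' @return List of [comet_track()] fragments (the unchanged track when no
#'   bend exceeds the threshold).
#' @export
split_on_bend <- function(track, theta_max = 30) {
  stopifnot(inherits(track, "comet_track"))
  ss <- segment_speeds(track)
  n_seg <- length(ss$angle)
  cut_after_seg <- which(direction_diff(ss$angle[-1], ss$angle[-n_seg]) >
                           theta_max)
  if (length(cut_after_seg) == 0) return(list(track))
  # a cut between segments i and i+1 starts a new fragment at frame i+1
  starts <- c(1L, cut_after_seg + 1L)
  ends <- c(cut_after_seg + 1L, length(track$frames))
  frags <- list()
  for (k in seq_along(starts)) {
    ix <- starts[k]:ends[k]
    if (length(ix) < 2) next
    frags[[length(frags) + 1]] <- comet_track(
      track$frames[ix], track$x[ix], track$y[ix], track$frame_interval,
      track_id = sprintf("%s.%d", track$track_id, k),
      cell_id = track$cell_id, treatment = track$treatment,
      state = if (!is.null(track$state)) track$state[ix] else NULL)
  }
  frags
}

#' Classify a track into growth and pause events
#'
#' Per-frame speeds (µm/min) are computed from consecutive positions;
#' maximal runs of at least `min_pause_frames` consecutive segments slower
#' than `pause_speed_max` become pause events, and all remaining segments
#' form growth events. Events tile the track contiguously. A track with
#' fewer than `min_pause_frames` segments becomes a single event classified
#' by its mean speed.
#'
#' @param track A [comet_track()].
#' @param pause_speed_max Pause speed threshold, µm/min (> 0; default 1.5).
#' @param min_pause_frames Minimum consecutive slow segments for a pause
#'   (default 2).
#' @return Tibble with `track_id`, `event_index`, `state`, `start_frame`,
#'   `end_frame`, `n_segments`, `mean_speed_um_min`, `length_um`.
#' @export
segment_events <- function(track, pause_speed_max = 1.5,
                           min_pause_frames = 2) {
  stopifnot(inherits(track, "comet_track"))
  check_positive(pause_speed_max, "pause_speed_max")
  ss <- segment_speeds(track)
  n_seg <- length(ss$speed)
  slow <- ss$speed < pause_speed_max
  if (n_seg < min_pause_frames) {
    state <- rep(if (mean(ss$speed) < pause_speed_max) "pause" else "growth",
                 n_seg)
  } else {
    state <- rep("growth", n_seg)
    r <- rle(slow)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_pause_frames) {
        state[starts[k]:ends[k]] <- "pause"
      }
    }
  }
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(
    track_id = track$track_id,
    event_index = seq_along(r$lengths),
    state = r$values,
    start_frame = track$frames[starts],
    end_frame = track$frames[ends + 1L],
    n_segments = r$lengths,
    mean_speed_um_min = vapply(seq_along(r$lengths), function(k) {
      mean(ss$speed[starts[k]:ends[k]])
    }, numeric(1)),
    length_um = vapply(seq_along(r$lengths), function(k) {
      sum(ss$disp[starts[k]:ends[k]])
    }, numeric(1)))
}

#' Per-cell and per-treatment comet dynamics summary
#'
#' Summarizes growth/pause events per cell — mean growth-event speed
#' (µm/min), mean growth length (µm), the percentage of events in each
#' state and, as a secondary convention, the percentage of track time in
#' each state — then averages cell values per treatment (cells are the
#' replication unit).
#'
#' @param tracks List of [comet_track()]s carrying `cell_id` and
#'   `treatment`.
#' @param events Optional precomputed events table; when `NULL`,
#'   [segment_events()] is run per track with `...` passed through.
#' @param ... Passed to [segment_events()].
#' @return List with `cells` and `treatments` tibbles.
#' @export
dynamics_summary <- function(tracks, events = NULL, ...) {
  meta <- tibble::tibble(
    track_id = vapply(tracks, function(t) t$track_id, character(1)),
    cell_id = vapply(tracks, function(t) t$cell_id, character(1)),
    treatment = vapply(tracks, function(t) t$treatment, character(1)))
  if (anyDuplicated(meta$track_id)) {
    stop_invalid("track ids must be unique across the track list")
  }
  if (is.null(events)) {
    events <- dplyr::bind_rows(lapply(tracks, segment_events, ...))
  }
  ev <- dplyr::inner_join(events, meta, by = "track_id")
  if (nrow(ev) == 0) stop_invalid("no events to summarize")
  cells <- ev |>
    dplyr::group_by(.data$treatment, .data$cell_id) |>
    dplyr::summarise(
      n_tracks = dplyr::n_distinct(.data$track_id),
      n_events = dplyr::n(),
      mean_growth_speed_um_min =
        mean(.data$mean_speed_um_min[.data$state == "growth"]),
      mean_growth_length_um =
        mean(.data$length_um[.data$state == "growth"]),
      pct_events_growth = 100 * mean(.data$state == "growth"),
      pct_events_pause = 100 * mean(.data$state == "pause"),
      pct_time_growth = 100 *
        sum(.data$n_segments[.data$state == "growth"]) /
        sum(.data$n_segments),
      pct_time_pause = 100 *
        sum(.data$n_segments[.data$state == "pause"]) /
        sum(.data$n_segments),
      .groups = "drop")
  no_growth <- !is.finite(cells$mean_growth_speed_um_min)
  if (any(no_growth)) {
    warning(sum(no_growth), " cell(s) without growth events excluded",
            call. = FALSE)
    cells <- cells[!no_growth, ]
  }
  treatments <- cells |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_growth_speed_um_min = mean(.data$mean_growth_speed_um_min),
      mean_growth_length_um = mean(.data$mean_growth_length_um),
      pct_events_growth = mean(.data$pct_events_growth),
      pct_events_pause = mean(.data$pct_events_pause),
      pct_time_growth = mean(.data$pct_time_growth),
      pct_time_pause = mean(.data$pct_time_pause),
      .groups = "drop")
  list(cells = cells, treatments = treatments)
}

#' Four-speed-group distribution with the fastest-cell vmax rule
#'
#' The maximum speed of the analysis is `vmax = mean + 1 SD` of the
#' growth-event speeds of the fastest cell (the cell with the highest mean
#' growth speed across all treatments). `[0, vmax]` is partitioned into
#' four equal-width bins (very slow / slow / fast / very fast); the last
#' bin is right-closed and speeds above vmax count into it. Percentages are
#' per treatment over growth events.
#'
#' @param event_speeds Tibble with `cell_id`, `treatment`, `speed`
#'   (growth-event mean speeds, µm/min, >= 0).
#' @param bin_labels Labels for the four bins.
#' @return Tibble of class `speed_group_table`: `treatment`, `group`, `lo`,
#'   `hi`, `n`, `percentage`; attributes `vmax`, `fastest_cell`.
#' @export
speed_groups <- function(event_speeds,
                         bin_labels = c("very slow", "slow", "fast",
                                        "very fast")) {
  need <- c("cell_id", "treatment", "speed")
  miss <- setdiff(need, names(event_speeds))
  if (length(miss) > 0) {
    stop_invalid("event_speeds is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  if (nrow(event_speeds) == 0) stop_invalid("no speeds supplied")
  check_nonneg(event_speeds$speed, "speed")
  cell_means <- event_speeds |>
    dplyr::group_by(.data$treatment, .data$cell_id) |>
    dplyr::summarise(mean_speed = mean(.data$speed),
                     sd_speed = sd(.data$speed), .groups = "drop")
  fastest <- cell_means[which.max(cell_means$mean_speed), ]
  vsd <- fastest$sd_speed
  if (!is.finite(vsd)) vsd <- 0
  vmax <- fastest$mean_speed + vsd
  if (vmax <= 0) stop_invalid("vmax is not positive; cannot bin speeds")
  edges <- seq(0, vmax, length.out = 5)
  bin <- pmin(findInterval(event_speeds$speed, edges), 4L)
  bin[event_speeds$speed < 0] <- 1L
  out <- list()
  for (tr in unique(event_speeds$treatment)) {
    sel <- event_speeds$treatment == tr
    counts <- tabulate(bin[sel], 4L)
    out[[tr]] <- tibble::tibble(
      treatment = tr, group = bin_labels,
      lo = edges[1:4], hi = edges[2:5],
      n = counts, percentage = 100 * counts / sum(counts))
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("speed_group_table", class(res)),
            vmax = vmax,
            fastest_cell = paste(fastest$treatment, fastest$cell_id,
                                 sep = "/"))
}
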