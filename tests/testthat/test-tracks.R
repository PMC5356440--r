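# Track linking plumbing and the post-tracking analysis: bend splitting,
# event classification, dynamics summaries and speed groups.

test_that("a single drifting detection links into one track", {
  frames <- lapply(1:10, function(t) {
    tibble::tibble(x_um = 0.3 * t, y_um = 0.1 * t)
  })
  tks <- link_detections(frames, max_disp = 0.5, frame_interval = 2)
  expect_length(tks, 1)
  expect_equal(tks[[1]]$frames, 1:10)
})

test_that("a gap longer than max_gap terminates the track", {
  pos <- lapply(1:9, function(t) tibble::tibble(x_um = 0.2 * t, y_um = 1))
  pos[[5]] <- pos[[6]] <- tibble::tibble(x_um = numeric(0), y_um = numeric(0))
  tks <- link_detections(pos, max_disp = 0.5, max_gap = 1,
                         frame_interval = 2)
  expect_length(tks, 2)
  expect_equal(tks[[1]]$frames, 1:4)
  expect_equal(tks[[2]]$frames, 7:9)
  # with max_gap = 2 the gap is bridged
  tks2 <- link_detections(pos, max_disp = 0.5, max_gap = 2,
                          frame_interval = 2)
  expect_length(tks2, 1)
  expect_equal(tks2[[1]]$frames, c(1:4, 7:9))
})

test_that("crossing trajectories match the exhaustive matching oracle", {
  # two opposite walkers whose paths cross mid-sequence; their separation
  # at the crossing (0.3 um) exceeds max_disp, so identities cannot swap
  fA <- function(t) c(0.25 * t, 4.85)
  fB <- function(t) c(10 - 0.25 * t, 5.15)
  per_frame <- lapply(1:40, function(t) {
    a <- fA(t); b <- fB(t)
    tibble::tibble(x_um = c(a[1], b[1]), y_um = c(a[2], b[2]))
  })
  for (md in c(0.27, 0.45)) {
    tks <- link_detections(per_frame, max_disp = md, frame_interval = 2)
    expect_length(tks, 2)
    expect_true(all(vapply(tks, function(t) length(t$frames), integer(1))
                    == 40))
    # frame-by-frame assignments equal the exhaustive optimum
    for (t in 1:39) {
      p1 <- as.matrix(per_frame[[t]])
      p2 <- as.matrix(per_frame[[t + 1]])
      opt <- oracle_match(p1, p2, md)
      for (tr in tks) {
        i <- match(t, tr$frames)
        if (is.na(i) || i == length(tr$frames)) next
        from <- which(p1[, 1] == tr$x[i] & p1[, 2] == tr$y[i])
        to <- which(p2[, 1] == tr$x[i + 1] & p2[, 2] == tr$y[i + 1])
        expect_equal(opt[from], to)
      }
    }
  }
})

test_that("collinear tracks are not split", {
  tr <- track_from_steps(rep(0.4, 9), rep(0, 9))
  expect_length(split_on_bend(tr), 1)
  expect_identical(split_on_bend(tr)[[1]], tr)
})

test_that("bend splitting brackets the strict 30 degree threshold", {
  mk_bend <- function(turn_deg) {
    a <- turn_deg * pi / 180
    track_from_steps(c(0.4, 0.4, 0.4 * cos(a), 0.4 * cos(a)),
                     c(0, 0, 0.4 * sin(a), 0.4 * sin(a)))
  }
  expect_length(split_on_bend(mk_bend(25)), 1)   # 25 <= 30: no split
  frag40 <- split_on_bend(mk_bend(40))           # 40 > 30: split
  expect_length(frag40, 2)
  expect_equal(frag40[[1]]$frames, 1:3)
  expect_equal(frag40[[2]]$frames, 3:5)
  expect_match(frag40[[2]]$track_id, "\\.2$")
  # exactly 30 does not split (strictly greater)
  expect_length(split_on_bend(mk_bend(30)), 1)
})

test_that("bend splitting agrees with the brute-force scan on random walks", {
  withr::with_seed(99, {
    for (k in 1:1000) {
      n_steps <- sample(3:12, 1)
      tr <- track_from_steps(rnorm(n_steps, 0, 0.3), rnorm(n_steps, 0, 0.3),
                             id = sprintf("rw%d", k))
      frags <- split_on_bend(tr)
      oracle <- oracle_split_frames(tr)
      expect_equal(lapply(frags, function(f) match(f$frames, tr$frames)),
                   oracle)
    }
  })
})

test_that("event classification reproduces run-length hand enumeration", {
  # frame speeds in um/min with frame_interval 60 s: displacement = speed
  mk <- function(speeds) track_from_steps(speeds, rep(0, length(speeds)),
                                          frame_interval = 60)
  one <- segment_events(mk(rep(10, 6)), pause_speed_max = 1.5)
  expect_equal(one$state, "growth")
  expect_equal(one$mean_speed_um_min, 10)
  three <- segment_events(mk(c(12, 12, 0.5, 0.5, 12)),
                          pause_speed_max = 1.5, min_pause_frames = 2)
  expect_equal(three$state, c("growth", "pause", "growth"))
  expect_equal(three$start_frame, c(1, 3, 5))
  expect_equal(three$end_frame, c(3, 5, 6))
  expect_equal(three$mean_speed_um_min, c(12, 0.5, 12))
  allp <- segment_events(mk(rep(0.5, 5)), pause_speed_max = 1.5)
  expect_equal(allp$state, "pause")
  # an isolated slow segment shorter than min_pause_frames stays in growth
  iso <- segment_events(mk(c(12, 0.5, 12)), pause_speed_max = 1.5,
                        min_pause_frames = 2)
  expect_equal(iso$state, "growth")
  # a track shorter than min_pause_frames becomes one event by mean speed
  short <- segment_events(mk(0.4), pause_speed_max = 1.5,
                          min_pause_frames = 2)
  expect_equal(short$state, "pause")
})

test_that("events tile every track contiguously", {
  withr::with_seed(7, {
    for (k in 1:200) {
      n_steps <- sample(2:20, 1)
      sp <- sample(c(0.3, 0.8, 5, 12), n_steps, replace = TRUE)
      tr <- track_from_steps(sp, rep(0, n_steps), frame_interval = 60)
      ev <- segment_events(tr)
      expect_equal(ev$start_frame[1], tr$frames[1])
      expect_equal(ev$end_frame[nrow(ev)], tr$frames[length(tr$frames)])
      if (nrow(ev) > 1) {
        expect_equal(ev$start_frame[-1], ev$end_frame[-nrow(ev)])
      }
      expect_equal(sum(ev$n_segments), n_steps)
      # oracle agreement on the per-segment states
      states <- rep(ev$state, ev$n_segments)
      expect_equal(states, oracle_event_states(sp))
    }
  })
})

test_that("speed units convert correctly from pixels and frames", {
  # 2 px/frame at 0.1 um/px and 1 s/frame = 0.2 um/s = 12 um/min
  tr <- track_from_steps(rep(0.2, 5), rep(0, 5), frame_interval = 1)
  ev <- segment_events(tr, pause_speed_max = 1.5)
  expect_equal(ev$mean_speed_um_min, 12)
  expect_equal(ev$length_um, 1.0)  # single growth event: full path length
})

test_that("dynamics summary aggregates per cell then per treatment", {
  t1 <- track_from_steps(rep(0.4, 8), rep(0, 8), frame_interval = 2,
                         id = "a1", cell_id = "c1")
  t2 <- track_from_steps(rep(0.2, 8), rep(0, 8), frame_interval = 2,
                         id = "a2", cell_id = "c2")
  out <- dynamics_summary(list(t1, t2))
  expect_equal(nrow(out$cells), 2)
  expect_equal(sort(out$cells$mean_growth_speed_um_min), c(6, 12))
  expect_equal(out$treatments$mean_growth_speed_um_min, 9)
  expect_equal(out$cells$pct_events_growth, c(100, 100))
  expect_error(dynamics_summary(list(t1, t1)), "unique")
})

test_that("the vmax rule is mean + 1 SD of the fastest cell", {
  sp <- tibble::tibble(
    cell_id = c(rep("c1", 4), rep("c2", 3)),
    treatment = "control",
    speed = c(10, 10, 10, 10, 9, 12, 15))  # c2: mean 12, sd 3
  gs <- speed_groups(sp)
  expect_equal(attr(gs, "vmax"), 15)
  expect_equal(attr(gs, "fastest_cell"), "control/c2")
})

test_that("speed binning partitions [0, vmax] into four equal groups", {
  # fastest cell mean 12, sd 4 -> vmax 16; bins [0,4) [4,8) [8,12) [12,16]
  sp <- tibble::tibble(
    cell_id = "c1", treatment = "control",
    speed = c(1, 5, 9, 14, 8, 16, 12))
  # engineer vmax = 16 exactly: mean 9.285..., sd... use explicit two cells
  sp <- tibble::tibble(
    cell_id = c(rep("fast", 2), rep("c1", 4)),
    treatment = c(rep("t", 2), rep("c", 4)),
    speed = c(10, 14, 1, 5, 9, 14))  # fast: mean 12, sd 2.828 -> vmax 14.83
  gs <- speed_groups(sp)
  vmax <- attr(gs, "vmax")
  expect_equal(vmax, 12 + sd(c(10, 14)))
  cbin <- gs[gs$treatment == "c", ]
  expect_equal(sum(cbin$percentage), 100)
  expect_equal(cbin$hi[4], vmax)
  # direct binning example with constructed vmax 16
  sp2 <- tibble::tibble(
    cell_id = c("f", "f", rep("c1", 4)),
    treatment = c("x", "x", rep("c", 4)),
    speed = c(12, 16, 1, 5, 9, 14))  # f: mean 14, sd 2.828 -> vmax 16.83
  gs2 <- speed_groups(sp2)
  cb <- gs2[gs2$treatment == "c", ]
  expect_equal(cb$percentage, rep(25, 4))
  # speeds above vmax land in the top bin; percentages still sum to 100
  sp3 <- tibble::tibble(cell_id = "c", treatment = "c",
                        speed = c(2, 2, 2, 50))
  gs3 <- speed_groups(sp3)
  expect_equal(sum(gs3$percentage), 100)
  expect_equal(gs3$percentage[4], 25)
})

test_that("slowing every comet increases the very-slow share", {
  base <- simulate_dynamic_tracks(60, 12, 1.5, 0.1, 0.3, 2, 40, seed = 31,
                                  cell_id = "c1")
  slow <- simulate_dynamic_tracks(60, 3, 1.5, 0.1, 0.3, 2, 40, seed = 32,
                                  cell_id = "c2", treatment = "inhibited")
  all_t <- c(base, slow)
  for (i in seq_along(all_t)) all_t[[i]]$track_id <- sprintf("t%03d", i)
  ev <- dplyr::bind_rows(lapply(all_t, segment_events))
  meta <- tibble::tibble(
    track_id = vapply(all_t, function(t) t$track_id, character(1)),
    cell_id = vapply(all_t, function(t) t$cell_id, character(1)),
    treatment = vapply(all_t, function(t) t$treatment, character(1)))
  g <- dplyr::inner_join(ev, meta, by = "track_id")
  g <- g[g$state == "growth", ]
  gs <- speed_groups(tibble::tibble(cell_id = g$cell_id,
                                    treatment = g$treatment,
                                    speed = g$mean_speed_um_min))
  vs_control <- gs$percentage[gs$treatment == "control" &
                                gs$group == "very slow"]
  vs_inhib <- gs$percentage[gs$treatment == "inhibited" &
                              gs$group == "very slow"]
  expect_gt(vs_inhib, vs_control)
})

test_that("split fragments inherit calibration and preserve frames", {
  withr::with_seed(12, {
    for (k in 1:50) {
      tr <- track_from_steps(rnorm(10, 0, 0.3), rnorm(10, 0, 0.3),
                             frame_interval = 2)
      frags <- split_on_bend(tr)
      expect_true(all(vapply(frags, function(f) f$frame_interval,
                             numeric(1)) == 2))
      # total frames = parent frames + duplicated boundary frames
      n_frames <- sum(vapply(frags, function(f) length(f$frames),
                             integer(1)))
      expect_equal(n_frames, length(tr$frames) + length(frags) - 1)
    }
  })
})
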