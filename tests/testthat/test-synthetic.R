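# Generators: determinism, ground-truth completeness and the distributional
# contracts (Poisson counts, von Mises angles, Markov state occupancy).

test_that("cell mosaic handles degenerate and small cases", {
  expect_length(make_cell_mosaic(1, c(20, 20), seed = 1), 0)
  two <- make_cell_mosaic(2, c(20, 20), seed = 5)
  expect_length(two, 1)
  expect_setequal(two[[1]]$cells, c(1, 2))
  expect_error(make_cell_mosaic(0, c(20, 20), seed = 1), "positive")
  expect_error(make_cell_mosaic(3, c(-1, 20), seed = 1), "positive")
})

test_that("cell mosaic is deterministic and edges stay in the field", {
  a <- make_cell_mosaic(25, c(50, 50), seed = 7)
  b <- make_cell_mosaic(25, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_gt(length(a), 25)  # a 25-cell mosaic has many internal edges
  for (p in a) {
    expect_true(all(p$x >= -1e-9 & p$x <= 50 + 1e-9))
    expect_true(all(p$y >= -1e-9 & p$y <= 50 + 1e-9))
    expect_length(p$cells, 2)
  }
})

test_that("junction rendering matches the analytic ridge profile", {
  rg <- ridge_image(sigma = 0.3, amplitude = 100, background = 7)
  # perpendicular distances probed off the ridge centre
  for (d in c(0, 0.15, 0.3, 0.6, 1.0)) {
    # within bilinear-interpolation tolerance (2% of amplitude)
    expect_lt(abs(interp_bilinear(rg$image, 10, 10 + d) -
                    (7 + 100 * exp(-d^2 / (2 * 0.3^2)))), 2)
  }
  blank <- render_junction_scene(list(rg$path), c(20, 20), 0.3,
                                 amplitude = 0, background = 3,
                                 noise_sd = 0)
  expect_true(all(blank$values == 3))
  empty <- render_junction_scene(list(), c(10, 10), 0.3, background = 2)
  expect_true(all(empty$values == 2))
  n1 <- render_junction_scene(list(rg$path), c(20, 20), 0.3, noise_sd = 5,
                              seed = 3)
  n2 <- render_junction_scene(list(rg$path), c(20, 20), 0.3, noise_sd = 5,
                              seed = 3)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0))
  expect_error(render_junction_scene(list(rg$path), c(20, 20), 0.3,
                                     amplitude = -1), "non-negative")
})

test_that("puncta placement follows the Poisson contracts", {
  p <- poly_path(c(0, 100), c(5, 5))   # 100 um of junction
  zero <- place_cortical_puncta(list(p), c(100, 10), base_density = 0.1,
                                junction_density = 2, band_width = 0.3,
                                enrichment_factor = 0, seed = 1)
  expect_equal(sum(zero$puncta$on_junction), 0)
  # junctional count ~ Poisson(2 * 0.5 * 100 = 100) over 200 seeds
  counts <- vapply(1:200, function(s) {
    res <- place_cortical_puncta(list(p), c(100, 10), base_density = 0,
                                 junction_density = 2, band_width = 0.3,
                                 enrichment_factor = 0.5, seed = s,
                                 pixel_size = 1)
    nrow(res$puncta)
  }, numeric(1))
  se <- sqrt(100 / 200)
  expect_lt(abs(mean(counts) - 100), 3 * se + 1)  # +1: border clipping
  r1 <- place_cortical_puncta(list(p), c(100, 10), 0.1, 2, 0.3, 1, seed = 9)
  r2 <- place_cortical_puncta(list(p), c(100, 10), 0.1, 2, 0.3, 1, seed = 9)
  expect_identical(r1$puncta, r2$puncta)
})

test_that("filament angles follow the folded von Mises contract", {
  paths <- make_cell_mosaic(6, c(30, 30), seed = 2)
  perp <- draw_filament_set(paths, 60, target_angle = 90, kappa = 1e6,
                            length_range = c(2, 5), field = c(30, 30),
                            seed = 4)
  expect_length(perp$filaments, 60)
  expect_equal(nrow(perp$truth), 60)
  expect_true(all(abs(perp$truth$angle_truth - 90) < 0.5))
  unif <- draw_filament_set(paths, 1000, 45, kappa = 0,
                            length_range = c(2, 5), field = c(30, 30),
                            seed = 5)
  frac <- mean(unif$truth$angle_truth >= 45 & unif$truth$angle_truth <= 90)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
  none <- draw_filament_set(paths, 0, 45, 1, c(2, 5), c(30, 30), seed = 1)
  expect_length(none$filaments, 0)
  expect_error(draw_filament_set(paths, 5, 95, 1, c(2, 5), c(30, 30)),
               "target_angle")
})

test_that("comet frame counts are Poisson with the stated mean", {
  none <- simulate_comet_frames(0, c(0.3, 0.8), c(10, 10), seed = 1)
  expect_equal(nrow(none$truth), 0)
  expect_true(all(none$images[[1]]$values >= 0))
  counts <- vapply(1:200, function(s) {
    nrow(simulate_comet_frames(30, c(0.3, 0.8), c(10, 10), seed = s,
                               pixel_size = 0.5)$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 200))
  sim <- simulate_comet_frames(10, c(0.4, 0.9), c(20, 20), seed = 3)
  expect_true(all(sim$truth$area_um2 >= 0.4 & sim$truth$area_um2 <= 0.9))
  expect_error(simulate_comet_frames(5, c(0, 1), c(10, 10)), "area_range")
})

test_that("two-state track simulator honours the Markov contract", {
  pure <- simulate_dynamic_tracks(5, 12, 1, p_gp = 0, p_pg = 0.3,
                                  frame_interval = 2, n_frames = 30,
                                  seed = 1)
  for (tr in pure) expect_true(all(tr$state == "growth"))
  long <- simulate_dynamic_tracks(5, 12, 1, p_gp = 0.1, p_pg = 0.3,
                                  frame_interval = 2, n_frames = 2000,
                                  seed = 2)
  states <- unlist(lapply(long, function(t) t$state))
  pause_frac <- mean(states == "pause")
  expected <- 0.1 / (0.1 + 0.3)
  expect_lt(abs(pause_frac - expected), 3 * sqrt(0.25 / 1e4) + 0.02)
  a <- simulate_dynamic_tracks(3, 12, 1, 0.1, 0.3, 2, 40, seed = 7)
  b <- simulate_dynamic_tracks(3, 12, 1, 0.1, 0.3, 2, 40, seed = 7)
  expect_identical(tracks_to_table(a), tracks_to_table(b))
  expect_error(simulate_dynamic_tracks(1, 12, 1, 0.1, 0.3, 2, n_frames = 1),
               "n_frames")
})
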