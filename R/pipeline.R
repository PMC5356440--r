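# Orchestration: run the synthetic -> measurement -> statistics pipeline
# from one declarative YAML config into a run directory, with every
# parameter echoed into run metadata so any number in any output CSV is
# reproducible from the config alone.

default_stages <- c("simulate", "profiles", "targeting", "comets",
                    "tracks", "stats")

#' Validate a pipeline configuration
#'
#' Checks the declarative config against the pipeline schema before any
#' computation: stage names, field/pixel geometry, the comet area gate
#' (`area_min < area_max`), transition probabilities and the presence of a
#' seed (mandatory: every stochastic stage derives its RNG stream from it).
#'
#' @param config A list (parsed YAML) or a path to a YAML file.
#' @return The validated config list, invisibly on error-free return.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("config must be a list or YAML path")
  if (is.null(config$seed)) stop_invalid("config must declare `seed`")
  stages <- config$stages %||% default_stages
  bad <- setdiff(stages, default_stages)
  if (length(bad) > 0) {
    stop_invalid("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  if (length(config$field %||% c(30, 30)) != 2) {
    stop_invalid("`field` must be c(width, height)")
  }
  check_positive(unlist(config$field %||% c(30, 30)), "field")
  check_positive(config$pixel_size %||% 0.1, "pixel_size")
  cm <- config$comets
  if (!is.null(cm)) {
    amin <- cm$area_min %||% 0.2
    amax <- cm$area_max %||% 1.2
    if (!(amin < amax)) {
      stop_invalid("comets: need area_min < area_max (got ", amin,
                   " >= ", amax, ")")
    }
  }
  tr <- config$tracks
  if (!is.null(tr)) {
    check_prob(tr$p_gp %||% 0.1, "tracks$p_gp")
    check_prob(tr$p_pg %||% 0.3, "tracks$p_pg")
  }
  config$stages <- stages
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_line <- function(log_file, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_file, append = TRUE)
}

#' Run the pipeline from a config into a run directory
#'
#' Executes the requested stages in dependency order:
#' `simulate` (mosaic, junction-enriched puncta for each treatment arm,
#' filament field, comet frames, two-state comet tracks), `profiles`
#' (junction-normal profiles and peaks per arm), `targeting`
#' (perpendicular fraction per cortical box, contacts per 10 µm, nematic
#' orientation), `comets` (detection and per-box counts), `tracks`
#' (bend splitting, event classification, dynamics summary, speed groups)
#' and `stats` (normality-routed comparison of normalized junctional
#' peaks). All outputs are plain CSV plus TIFF images with sidecars; the
#' full config is echoed into `run_metadata.yaml`.
#'
#' @param config Config list or YAML path (see [validate_config()] and the
#'   bundled demo: `system.file("extdata", "demo_config.yaml", package =
#'   "cortexmt")`).
#' @param out_dir Run directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline.log")
  cat("", file = log_file)
  seed <- as.integer(config$seed)
  field <- as.numeric(unlist(config$field %||% c(30, 30)))
  ps <- config$pixel_size %||% 0.1
  yaml::write_yaml(
    list(package_version = as.character(utils::packageVersion("cortexmt")),
         config = config),
    file.path(out_dir, "run_metadata.yaml"))
  stages <- config$stages
  pth <- function(f) file.path(out_dir, f)

  if ("simulate" %in% stages) {
    log_line(log_file, "stage simulate: seed ", seed)
    mos <- config$mosaic %||% list()
    junctions <- make_cell_mosaic(mos$n_cells %||% 6, field, seed = seed)
    write_polypaths(junctions, pth("junctions.csv"))

    pc <- config$puncta %||% list()
    arms <- pc$arms %||% list(control = 1.0, treated = 0.5)
    for (i in seq_along(arms)) {
      arm <- names(arms)[i]
      res <- place_cortical_puncta(
        junctions, field,
        base_density = pc$base_density %||% 0.2,
        junction_density = pc$junction_density %||% 8,
        band_width = pc$band_width %||% 0.4,
        enrichment_factor = arms[[i]],
        seed = seed + 100 + i,
        amplitude = pc$amplitude %||% 100,
        punct_sigma = pc$punct_sigma %||% 0.15,
        background = pc$background %||% 5,
        noise_sd = pc$noise_sd %||% 2,
        pixel_size = ps, exposure_group = "puncta")
      write_csv_quiet(res$puncta, pth(sprintf("puncta_%s.csv", arm)))
      write_image_tiff(res$image, pth(sprintf("puncta_%s.tif", arm)))
    }

    fl <- config$filaments %||% list()
    fil <- draw_filament_set(
      junctions, n_filaments = fl$n_filaments %||% 150,
      target_angle = fl$target_angle %||% 70, kappa = fl$kappa %||% 2,
      length_range = as.numeric(unlist(fl$length_range %||% c(2, 6))),
      field = field, seed = seed + 200, pixel_size = ps,
      noise_sd = fl$noise_sd %||% 0, exposure_group = "filaments")
    write_csv_quiet(fil$truth, pth("filament_truth.csv"))
    write_polypaths(fil$filaments, pth("filaments.csv"))
    write_image_tiff(fil$image, pth("filaments.tif"))

    cm <- config$comets %||% list()
    com <- simulate_comet_frames(
      density = cm$density %||% 25,
      area_range = as.numeric(unlist(cm$area_range %||% c(0.3, 1.0))),
      field = field, pixel_size = ps,
      noise_sd = cm$noise_sd %||% 2, seed = seed + 300,
      exposure_group = "comets")
    write_csv_quiet(com$truth, pth("comet_truth.csv"))
    write_image_tiff(com$images[[1]], pth("comets.tif"))

    tr <- config$tracks %||% list()
    arms_v <- list(control = tr$v_growth %||% 12,
                   treated = tr$treated_v_growth %||% 6.3)
    tracks <- list()
    n_cells_tr <- tr$cells_per_treatment %||% 4
    for (i in seq_along(arms_v)) {
      for (cc in seq_len(n_cells_tr)) {
        tks <- simulate_dynamic_tracks(
          n_tracks = tr$tracks_per_cell %||% 12,
          v_growth = arms_v[[i]], v_sd = tr$v_sd %||% 1.5,
          p_gp = tr$p_gp %||% 0.1, p_pg = tr$p_pg %||% 0.3,
          frame_interval = tr$frame_interval %||% 2,
          n_frames = tr$n_frames %||% 40,
          seed = seed + 400 + 10 * i + cc, field = field,
          cell_id = sprintf("%s_cell%d", names(arms_v)[i], cc),
          treatment = names(arms_v)[i])
        tks <- lapply(tks, function(t) {
          t$track_id <- paste0(t$cell_id, "_", t$track_id); t
        })
        tracks <- c(tracks, tks)
      }
    }
    write_tracks(tracks, pth("tracks_truth.csv"))
  }

  if ("profiles" %in% stages) {
    log_line(log_file, "stage profiles")
    junctions <- read_polypaths(pth("junctions.csv"))
    pf <- config$profiles %||% list()
    span <- pf$span %||% 2
    arms <- names(config$puncta$arms %||% list(control = 1, treated = 0.5))
    peaks_all <- list()
    for (arm in arms) {
      img <- read_image_tiff(pth(sprintf("puncta_%s.tif", arm)))
      prof_arm <- list()
      for (j in seq_along(junctions)) {
        if (path_length(junctions[[j]]) < span) next
        prof <- extract_profiles(
          img, junctions[[j]],
          n_positions = pf$n_positions %||% 10, span = span,
          n_samples = pf$n_samples %||% 21,
          background = pf$background)
        if (nrow(prof) == 0) next
        prof$path_id <- junctions[[j]]$id
        prof_arm[[length(prof_arm) + 1]] <- prof
        pk <- peak_intensities(prof)$peaks
        pk$path_id <- junctions[[j]]$id
        pk$group <- arm
        peaks_all[[length(peaks_all) + 1]] <- pk
      }
      write_csv_quiet(dplyr::bind_rows(prof_arm),
                      pth(sprintf("profiles_%s.csv", arm)))
    }
    peaks <- dplyr::bind_rows(peaks_all)
    write_csv_quiet(peaks[, c("group", "path_id", "position_index", "peak")],
                    pth("peaks.csv"))
    if (length(arms) >= 2) {
      rel <- relative_peak_change(peaks$peak[peaks$group == arms[1]],
                                  peaks$peak[peaks$group == arms[2]])
      write_csv_quiet(tibble::tibble(
        control = arms[1], treated = arms[2], ratio = rel$ratio,
        percent_reduction = rel$percent_reduction),
        pth("peak_change.csv"))
      log_line(log_file, sprintf("junctional peak reduction: %.1f%%",
                                 rel$percent_reduction))
    }
  }

  if ("targeting" %in% stages) {
    log_line(log_file, "stage targeting")
    junctions <- read_polypaths(pth("junctions.csv"))
    filaments <- read_polypaths(pth("filaments.csv"))
    tg <- config$targeting %||% list()
    box_side <- tg$box_side %||% 10
    rows_box <- list(); rows_ct <- list()
    for (j in seq_along(junctions)) {
      jp <- junctions[[j]]
      mid <- path_point(jp, path_length(jp) / 2)[1, ]
      box <- cortical_box(mid, side = box_side, junction_id = jp$id,
                          box_id = sprintf("box_%s", jp$id))
      pf <- perpendicular_fraction(filaments, jp, box,
                                   lo = tg$lo %||% 45, hi = tg$hi %||% 90)
      rows_box[[j]] <- tibble::tibble(
        box_id = box$box_id, junction_id = jp$id,
        n_filaments = pf$n_in_box, pct_perpendicular = pf$percent,
        defined = pf$defined)
      ct <- contacts_per_10um(filaments, jp,
                              d_contact = tg$d_contact %||% 0.25)
      rows_ct[[j]] <- tibble::tibble(
        junction_id = jp$id, contacts_per_10um = ct$per_10um,
        n_contacts = ct$n_contacts, junction_length_um = ct$junction_length_um)
    }
    write_csv_quiet(dplyr::bind_rows(rows_box), pth("perpendicular_boxes.csv"))
    write_csv_quiet(dplyr::bind_rows(rows_ct), pth("contacts.csv"))

    img <- read_image_tiff(pth("filaments.tif"))
    rows_or <- list()
    for (j in seq_along(junctions)) {
      jp <- junctions[[j]]
      mid <- path_point(jp, path_length(jp) / 2)[1, ]
      half <- box_side / 2
      roi <- c(mid[1] - half, mid[2] - half, mid[1] + half, mid[2] + half)
      roi <- pmax(roi, 0)
      roi[c(1, 3)] <- pmin(roi[c(1, 3)], field[1])
      roi[c(2, 4)] <- pmin(roi[c(2, 4)], field[2])
      res <- tryCatch(nematic_orientation(img, roi),
                      error = function(e) NULL)
      if (is.null(res)) next
      tangent <- path_tangent(jp, path_length(jp) / 2)
      rows_or[[length(rows_or) + 1]] <- tibble::tibble(
        roi_id = sprintf("roi_%s", jp$id),
        orientation_deg = res$orientation_deg,
        anisotropy = res$anisotropy, defined = res$defined,
        angle_to_junction_deg = junction_relative_angle(res, tangent))
    }
    write_csv_quiet(dplyr::bind_rows(rows_or), pth("orientation.csv"))
  }

  if ("comets" %in% stages) {
    log_line(log_file, "stage comets")
    img <- read_image_tiff(pth("comets.tif"))
    cm <- config$comets %||% list()
    det <- detect_comets(img,
                         background_method = cm$background_method %||% "median",
                         threshold_method = cm$threshold_method %||% "otsu",
                         area_min = cm$area_min %||% 0.2,
                         area_max = cm$area_max %||% 1.2)
    write_detections(det, pth("detections.csv"))
    side <- cm$box_side %||% 10
    boxes <- list()
    for (bx in seq_len(max(1, floor(field[1] / side)))) {
      for (by in seq_len(max(1, floor(field[2] / side)))) {
        boxes[[length(boxes) + 1]] <- cortical_box(
          c((bx - 0.5) * side, (by - 0.5) * side), side,
          box_id = sprintf("tile_%d_%d", bx, by))
      }
    }
    write_csv_quiet(comets_per_box(det, boxes), pth("comet_counts.csv"))
    log_line(log_file, nrow(det), " comet detections")
  }

  if ("tracks" %in% stages) {
    log_line(log_file, "stage tracks")
    tr <- config$tracks %||% list()
    tracks <- read_tracks(pth("tracks_truth.csv"),
                          frame_interval = tr$frame_interval %||% 2)
    split_tracks <- unlist(lapply(tracks, split_on_bend,
                                  theta_max = tr$theta_max %||% 30),
                           recursive = FALSE)
    events <- dplyr::bind_rows(lapply(
      split_tracks, segment_events,
      pause_speed_max = tr$pause_speed_max %||% 1.5,
      min_pause_frames = tr$min_pause_frames %||% 2))
    write_csv_quiet(events, pth("events.csv"))
    summ <- dynamics_summary(split_tracks, events)
    write_csv_quiet(summ$cells, pth("cells_summary.csv"))
    write_csv_quiet(summ$treatments, pth("treatments_summary.csv"))
    meta <- tibble::tibble(
      track_id = vapply(split_tracks, function(t) t$track_id, character(1)),
      cell_id = vapply(split_tracks, function(t) t$cell_id, character(1)),
      treatment = vapply(split_tracks, function(t) t$treatment, character(1)))
    ev <- dplyr::inner_join(events, meta, by = "track_id")
    gs <- speed_groups(tibble::tibble(
      cell_id = ev$cell_id[ev$state == "growth"],
      treatment = ev$treatment[ev$state == "growth"],
      speed = ev$mean_speed_um_min[ev$state == "growth"]))
    gs_out <- tibble::as_tibble(gs)
    gs_out$vmax <- attr(gs, "vmax")
    write_csv_quiet(gs_out, pth("speed_groups.csv"))
    log_line(log_file, sprintf("vmax = %.2f um/min (fastest cell %s)",
                               attr(gs, "vmax"), attr(gs, "fastest_cell")))
  }

  if ("stats" %in% stages) {
    log_line(log_file, "stage stats")
    peaks <- read_checked_csv(pth("peaks.csv"), c("group", "peak"))
    st <- config$stats %||% list()
    cmp <- choose_and_run_test(
      split(peaks$peak, peaks$group),
      alpha_normality = st$alpha_normality %||% 0.05)
    write_csv_quiet(tibble::tibble(
      test = cmp$test, statistic = cmp$statistic, p_value = cmp$p_value),
      pth("comparison.csv"))
    writeLines(cmp$trace, pth("comparison_trace.txt"))
    for (ln in cmp$trace) log_line(log_file, ln)
  }

  log_line(log_file, "done")
  invisible(out_dir)
}
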