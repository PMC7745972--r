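#' Production-run configuration
#'
#' Mirrors the rig's production settings: number of floor locations imaged,
#' stepper pulse rates and stepping mode, settle pause and imaging time, the
#' routing algorithm, plus the simulation-only knobs (render down-scale
#' factor, pose rings per plant, tight packing). Settings are validated
#' against the hardware limits (pulse rate at most 4000 pulses/s; locations
#' at most the number of marked positions).
#'
#' @param gantry a `gantry_config`.
#' @param n_locations floor positions imaged per run; default 9.
#' @param rings data.frame of pose rings (`height`, `radius`, `count`) per
#'   plant; default one ring of 4 poses at 500 mm height, 130 mm radius — a
#'   radius small enough that no candidate pose leaves the travel volume
#'   from any marked position.
#' @param pulse_rate,acceleration,step_mode,parallel_axes stepper settings;
#'   defaults 3000 pulses/s, 10000 pulses/s^2, half-stepping, sequential.
#' @param pause_before_trigger,imaging_time seconds; defaults 3 and 2.7.
#' @param routing routing algorithm; only `"nested-zigzag"`.
#' @param slab_width,column_width zig-zag partition widths, mm; default a
#'   quarter of the volume extent on each axis.
#' @param downscale render-scale factor applied to the camera resolution for
#'   the simulated captures; default 0.2 (800 x 600).
#' @param seed integer master seed.
#' @param sphere_radius bounding-sphere radius per plant, mm.
#' @param tight_packing logical; cluster plants so boxes overlap.
#' @param download_per_master,crop_per_sub simulated bulk-download seconds
#'   per master image and cropping seconds per subimage entering the
#'   production-rate accounting.
#' @param room,institute,camera,lens metadata strings.
#' @param box_origin box convention written to metadata.
#' @param start_time capture-clock start (`POSIXct` or string, UTC); fix it
#'   to obtain byte-stable outputs.
#' @return object of class `run_config`.
#' @export
run_config <- function(gantry = gantry_config(),
                       n_locations = 9,
                       rings = data.frame(height = 500, radius = 130, count = 4),
                       pulse_rate = 3000, acceleration = 10000,
                       step_mode = 0.5, parallel_axes = FALSE,
                       pause_before_trigger = 3, imaging_time = 2.7,
                       routing = "nested-zigzag",
                       slab_width = NULL, column_width = NULL,
                       downscale = 0.2, seed = 1L,
                       sphere_radius = 100, tight_packing = FALSE,
                       download_per_master = 2760 / 2149,
                       crop_per_sub = 2040 / 3494,
                       room = "simlab", institute = "virtual",
                       camera = "simulated", lens = "rectilinear",
                       box_origin = "upper-right",
                       start_time = "2020-06-15 09:00:00") {
  routing <- match.arg(routing, "nested-zigzag")
  if (pulse_rate > 4000)
    stop("pulse_rate exceeds the controller's maximum of 4000 pulses/second")
  mp <- marked_positions(gantry)
  if (!tight_packing && n_locations > nrow(mp))
    stop("n_locations exceeds the ", nrow(mp), " marked positions")
  if (is.null(slab_width)) slab_width <- gantry$volume[1] / 4
  if (is.null(column_width)) column_width <- gantry$volume[2] / 4
  profile <- motion_profile(pulse_rate = pulse_rate, acceleration = acceleration,
                            step_mode = step_mode, parallel_axes = parallel_axes)
  structure(list(gantry = gantry, n_locations = as.integer(n_locations),
                 rings = rings, profile = profile,
                 pause_before_trigger = pause_before_trigger,
                 imaging_time = imaging_time, routing = routing,
                 slab_width = slab_width, column_width = column_width,
                 downscale = downscale, seed = as.integer(seed),
                 sphere_radius = sphere_radius,
                 tight_packing = isTRUE(tight_packing),
                 download_per_master = download_per_master,
                 crop_per_sub = crop_per_sub,
                 room = room, institute = institute,
                 camera = camera, lens = lens, box_origin = box_origin,
                 start_time = as.POSIXct(start_time, tz = "UTC")),
            class = "run_config")
}

# down-scaled camera model for simulated captures
capture_model <- function(cfg) {
  camera_model(width = max(16L, as.integer(round(cfg$gantry$model$width * cfg$downscale))),
               height = max(12L, as.integer(round(cfg$gantry$model$height * cfg$downscale))),
               fov_diagonal = cfg$gantry$model$fov_diagonal)
}

#' Does a box clear the excluded outer margin?
#'
#' Boxes whose edges come within `margin` (a fraction of image width/height)
#' of the image border are rejected by the labeling pipeline: crops there
#' are the least reliable, and on a physical lens that zone carries the
#' worst distortion.
#'
#' @param box an `image_box`.
#' @param margin fraction in \[0, 0.5); 0 accepts everything.
#' @return logical.
#' @export
margin_ok <- function(box, margin) {
  if (margin <= 0) return(TRUE)
  box[["x_min"]] >= margin && box[["x_max"]] <= 1 - margin &&
    box[["y_min"]] >= margin && box[["y_max"]] <= 1 - margin
}

#' Run the full simulated production pipeline
#'
#' Generates a random scene, builds the pose set for every plant, orders all
#' poses with the nested zig-zag route, schedules travel with the trapezoidal
#' motion model, renders a master image per pose, projects every plant's
#' bounding sphere to a box, crops and writes subimages, writes the overlay
#' copy and the v1.5 metadata record per master, files subimages by position
#' class, and writes a run manifest. Fully reproducible from (config, seed).
#'
#' @param cfg a `run_config`.
#' @param out_dir run directory to create.
#' @param write_images logical; `FALSE` skips the JPEG writing (metadata and
#'   manifest are still produced), for fast scheduling-only runs.
#' @return invisibly, a list: `manifest`, `records`, `route`, `scene`.
#' @export
run_pipeline <- function(cfg, out_dir, write_images = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "subimages"), showWarnings = FALSE)

  scene <- random_scene(cfg$n_locations, seed = cfg$seed,
                        sphere_radius = cfg$sphere_radius,
                        tight_packing = cfg$tight_packing)
  poses <- list()
  for (pl in scene$plants) {
    ps <- generate_pose_set(pl$position, pl$position_class, cfg$rings,
                            volume = cfg$gantry)
    poses <- c(poses, ps)
  }
  ordered <- plan_zigzag(poses, cfg$slab_width, cfg$column_width)
  route <- route_plan(ordered, cfg$profile,
                      pause_before_trigger = cfg$pause_before_trigger,
                      imaging_time = cfg$imaging_time)
  t_p <- schedule(route)
  model <- capture_model(cfg)
  per_pose <- cfg$pause_before_trigger + cfg$imaging_time
  elapsed <- cumsum(c(0, route$leg_times)) +
    per_pose * seq_along(route$poses)
  capture_times <- cfg$start_time + elapsed

  records <- list()
  n_sub <- 0L
  for (i in seq_along(route$poses)) {
    pose <- route$poses[[i]]
    rend <- render_master(scene, pose, model)
    keep <- list(); boxes <- list()
    for (pl in scene$plants) {
      box <- tryCatch(
        project_sphere(pose, cfg$gantry$model,
                       bounding_sphere(pl$position, pl$sphere_radius)),
        error = function(e) NULL)
      if (is.null(box)) next
      if (!margin_ok(box, cfg$gantry$margin_exclusion)) next
      keep[[length(keep) + 1]] <- pl
      boxes[[length(boxes) + 1]] <- box
    }
    rec <- metadata_record(capture_times[i], i, pose, boxes, keep,
                           room = cfg$room, institute = cfg$institute,
                           camera = cfg$camera, lens = cfg$lens,
                           box_origin = cfg$box_origin)
    write_metadata(rec, file.path(out_dir, paste0(
      tools::file_path_sans_ext(rec$file_name), ".json")))
    if (write_images) {
      EBImage::writeImage(EBImage::Image(rend$image, colormode = "Color"),
                          file.path(out_dir, rec$file_name), quality = 92)
      EBImage::writeImage(
        EBImage::Image(draw_overlay(rend$image, boxes), colormode = "Color"),
        file.path(out_dir, rec$bb_file_name), quality = 92)
      crops <- crop_subimages(rend$image, boxes)
      for (j in seq_along(crops))
        EBImage::writeImage(EBImage::Image(crops[[j]], colormode = "Color"),
                            file.path(out_dir, "subimages",
                                      rec$bounding_boxes[[j]]$subimage_file_name),
                            quality = 92)
    }
    n_sub <- n_sub + length(boxes)
    records[[i]] <- rec
  }
  classes <- stats::setNames(
    vapply(scene$plants, `[[`, character(1), "position_class"),
    vapply(scene$plants, function(p) as.character(p$position_id), character(1)))
  organize_outputs(records, out_dir, classes)

  manifest <- list(
    package = "plantgantry", seed = cfg$seed,
    routing = "Nested Zig-Zag",
    n_locations = cfg$n_locations,
    n_master = length(records), n_sub = n_sub,
    t_p = t_p,
    t_d = cfg$download_per_master * length(records),
    t_c = cfg$crop_per_sub * n_sub,
    pulse_rate = cfg$profile$pulse_rate,
    acceleration = cfg$profile$acceleration,
    step_mode = cfg$profile$step_mode,
    parallel_axes = cfg$profile$parallel_axes,
    pause_before_trigger = cfg$pause_before_trigger,
    imaging_time = cfg$imaging_time,
    downscale = cfg$downscale,
    start_time = format(cfg$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    position_classes = as.list(classes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, records = records,
                 route = route, scene = scene))
}

#' Validate a completed run directory
#'
#' Checks that the manifest is present, every metadata record validates,
#' every referenced image file exists (when images were written), and every
#' subimage file on disk is referenced by exactly one record.
#'
#' @param run_dir run directory.
#' @return character vector of problems; empty when the run validates.
#' @export
validate_run <- function(run_dir) {
  problems <- character(0)
  if (!file.exists(file.path(run_dir, "manifest.json")))
    return("manifest.json missing")
  recs <- list.files(run_dir, pattern = "-pose[0-9]+\\.json$", full.names = TRUE)
  referenced <- character(0)
  have_images <- length(list.files(run_dir, pattern = "\\.jpg$")) > 0
  for (f in recs) {
    rec <- tryCatch(read_metadata(f), error = function(e) {
      problems <<- c(problems, conditionMessage(e)); NULL })
    if (is.null(rec)) next
    if (have_images) {
      for (img in c(rec$file_name, rec$bb_file_name))
        if (!file.exists(file.path(run_dir, img)))
          problems <- c(problems, paste0("referenced image missing: ", img))
      for (bb in rec$bounding_boxes) {
        hits <- list.files(run_dir, pattern = paste0("^", bb$subimage_file_name, "$"),
                           recursive = TRUE)
        if (length(hits) != 1)
          problems <- c(problems, paste0("subimage referenced ", length(hits),
                                         " times on disk: ", bb$subimage_file_name))
      }
    }
    referenced <- c(referenced,
                    vapply(rec$bounding_boxes, `[[`, character(1),
                           "subimage_file_name"))
  }
  if (have_images) {
    on_disk <- basename(list.files(run_dir, pattern = "^[0-9]{15,}\\.jpg$",
                                   recursive = TRUE))
    extra <- setdiff(on_disk, referenced)
    if (length(extra))
      problems <- c(problems, paste0("unreferenced subimage on disk: ", extra))
  }
  if (anyDuplicated(referenced))
    problems <- c(problems, "subimage referenced by more than one record")
  problems
}

#' Report the production statistics of a run
#'
#' Emits the run's counts, simulated times, average production rates per
#' master and subimage, and per-species subimage counts.
#'
#' @param run_dir run directory.
#' @param path optional file to also write the plain-text report to.
#' @return invisibly, a list with `n_master`, `n_sub`, `t_p`, `t_d`, `t_c`,
#'   `t_m`, `t_s`, `routing`, `counts`.
#' @export
run_report <- function(run_dir, path = NULL) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("incomplete run: manifest.json missing")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  summ <- dataset_summary(run_dir)
  rates <- if (mf$n_master > 0 && mf$n_sub > 0)
    production_rates(production_log(mf$t_p, mf$t_d, mf$t_c, mf$n_master, mf$n_sub))
  else c(t_m = 0, t_s = 0)
  lines <- c(
    "Production report",
    sprintf("Routing Algorithm       %s", mf$routing),
    sprintf("Locations Imaged        %d", mf$n_locations),
    sprintf("Total Images            %d", mf$n_master),
    sprintf("Total Subimages         %d", mf$n_sub),
    sprintf("Time for Imaging t_p    %.1f s", mf$t_p),
    sprintf("Download Time t_d       %.1f s", mf$t_d),
    sprintf("Cropping Time t_c       %.1f s", mf$t_c),
    sprintf("Rate (Images) t_m       %.2f s/image", rates[["t_m"]]),
    sprintf("Rate (Subimages) t_s    %.2f s/image", rates[["t_s"]]),
    "",
    sprintf("%-28s %8s", "Label", "Images"),
    sprintf("%-28s %8d", summ$counts$label, summ$counts$n_subimages),
    sprintf("%-28s %8d", "Total", summ$total))
  if (!is.null(path)) writeLines(lines, path) else writeLines(lines)
  invisible(list(n_master = mf$n_master, n_sub = mf$n_sub,
                 t_p = mf$t_p, t_d = mf$t_d, t_c = mf$t_c,
                 t_m = rates[["t_m"]], t_s = rates[["t_s"]],
                 routing = mf$routing, counts = summ$counts))
}
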