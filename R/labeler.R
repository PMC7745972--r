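# pixel rectangle of a fractional box on a W x H raster:
# 0-based half-open [floor(min*dim), ceil(max*dim)) per axis
box_pixels <- function(box, W, H) {
  x0 <- floor(box[["x_min"]] * W); x1 <- ceiling(box[["x_max"]] * W)
  y0 <- floor(box[["y_min"]] * H); y1 <- ceiling(box[["y_max"]] * H)
  if (x1 <= x0 || y1 <= y0)
    stop("zero-area crop after rounding: degenerate bounding box")
  list(x = (x0 + 1):x1, y = (y0 + 1):y1)
}

#' Crop labeled subimages out of a master raster
#'
#' Each fractional box maps to the pixel rectangle
#' `[floor(min * dim), ceil(max * dim))` (half-open) on each axis; output
#' crops may therefore differ in size from box to box.
#'
#' @param master numeric array width x height x channels (or width x height
#'   matrix).
#' @param boxes list of `image_box` (internal top-left-origin fractions).
#' @return list of cropped arrays.
#' @export
crop_subimages <- function(master, boxes) {
  d <- dim(master)
  if (is.null(d) || d[1] < 1 || d[2] < 1) stop("master raster is empty")
  if (inherits(boxes, "image_box")) boxes <- list(boxes)
  lapply(boxes, function(b) {
    px <- box_pixels(b, d[1], d[2])
    if (length(d) == 3) master[px$x, px$y, , drop = FALSE] else master[px$x, px$y, drop = FALSE]
  })
}

#' File-name builders for the dataset naming scheme
#'
#' Master images are named `yyyymmddhhmmss-pose#.jpg` (capture timestamp plus
#' the pose number of the acquisition run), the bounding-box overlay copy
#' carries `-bb` after the pose number, and subimages are named
#' `yyyymmddhhmmss#.jpg` where `#` is the position id.
#'
#' @param time a `POSIXct` capture time.
#' @param pose_number,position_id integers.
#' @return file name string.
#' @export
master_file_name <- function(time, pose_number) {
  sprintf("%s-pose%d.jpg", format(time, "%Y%m%d%H%M%S"), as.integer(pose_number))
}

#' @rdname master_file_name
#' @export
bb_file_name <- function(time, pose_number) {
  sprintf("%s-pose%d-bb.jpg", format(time, "%Y%m%d%H%M%S"), as.integer(pose_number))
}

#' @rdname master_file_name
#' @export
subimage_file_name <- function(time, position_id) {
  sprintf("%s%d.jpg", format(time, "%Y%m%d%H%M%S"), as.integer(position_id))
}

#' Assemble a v1.5 metadata record for one master image
#'
#' One record per master image: identity and capture time, rig and location
#' information, the camera pose (position plus polar and azimuthal angles),
#' and the list of labeled bounding boxes. Box fractions are stored in the
#' declared `box_origin` convention: `"upper-right"` (the production
#' datasets' literal convention: x = 0, y = 0 is the image's upper right
#' corner, x = 1, y = 1 the lower left) or `"upper-left"` (u rightward,
#' v downward — the package's internal convention).
#'
#' @param time capture time (`POSIXct`).
#' @param pose_number pose index within the acquisition run.
#' @param pose the `camera_pose` of the capture.
#' @param boxes named list of `image_box` in the internal (upper-left)
#'   convention; names are ignored.
#' @param plants list of plant-target lists (as in a `scene_spec`), aligned
#'   with `boxes`.
#' @param room,institute,camera,lens strings from configuration.
#' @param box_origin `"upper-right"` (default) or `"upper-left"`.
#' @return a validated metadata record (class `metadata_record`).
#' @export
metadata_record <- function(time, pose_number, pose, boxes, plants,
                            room = "unspecified", institute = "unspecified",
                            camera = "simulated", lens = "rectilinear",
                            box_origin = c("upper-right", "upper-left")) {
  box_origin <- match.arg(box_origin)
  stopifnot(length(boxes) == length(plants))
  bbs <- lapply(seq_along(boxes), function(i) {
    b <- boxes[[i]]; pl <- plants[[i]]
    if (box_origin == "upper-right") {
      b <- c(x_min = 1 - b[["x_max"]], x_max = 1 - b[["x_min"]],
             y_min = b[["y_min"]], y_max = b[["y_max"]])
    }
    list(plant_id = pl$plant_id, label = pl$label,
         scientific_name = pl$scientific_name,
         position_id = as.integer(pl$position_id),
         subimage_file_name = subimage_file_name(time, pl$position_id),
         date_planted = as.character(pl$date_planted),
         x_min = unname(b[["x_min"]]), x_max = unname(b[["x_max"]]),
         y_min = unname(b[["y_min"]]), y_max = unname(b[["y_max"]]))
  })
  rec <- structure(list(
    version = "1.5",
    file_name = master_file_name(time, pose_number),
    bb_file_name = bb_file_name(time, pose_number),
    date = format(time, "%Y-%m-%d"),
    time = format(time, "%H:%M:%S"),
    room = room, institute = institute, camera = camera, lens = lens,
    camera_pose = list(x = unname(as.numeric(pose$position)[1]),
                       y = unname(as.numeric(pose$position)[2]),
                       z = unname(as.numeric(pose$position)[3]),
                       polar_angle = pose$tilt + 90,
                       azimuthal_angle = pose$pan),
    box_origin = box_origin,
    bounding_boxes = bbs
  ), class = "metadata_record")
  problems <- validate_metadata(rec)
  if (length(problems)) stop("invalid metadata record: ", paste(problems, collapse = "; "))
  rec
}

#' Validate a metadata record against the v1.5 schema
#'
#' @param rec a metadata record (list).
#' @return character vector of problems; empty when valid.
#' @export
validate_metadata <- function(rec) {
  problems <- character(0)
  need <- c("version", "file_name", "bb_file_name", "date", "time", "room",
            "institute", "camera", "lens", "camera_pose", "bounding_boxes")
  missing <- setdiff(need, names(rec))
  if (length(missing))
    problems <- c(problems, paste0("missing field: ", missing))
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  if (!"version" %in% missing) chk(identical(as.character(rec$version), "1.5"),
                                   "version must be \"1.5\"")
  if (!"file_name" %in% missing)
    chk(grepl("^[0-9]{14}-pose[0-9]+\\.jpg$", rec$file_name),
        "file_name must match yyyymmddhhmmss-pose#.jpg")
  if (!"bb_file_name" %in% missing)
    chk(grepl("^[0-9]{14}-pose[0-9]+-bb\\.jpg$", rec$bb_file_name),
        "bb_file_name must match yyyymmddhhmmss-pose#-bb.jpg")
  if (!"camera_pose" %in% missing) {
    cp <- rec$camera_pose
    for (f in c("x", "y", "z", "polar_angle", "azimuthal_angle"))
      chk(is.numeric(cp[[f]]) && is.finite(cp[[f]]),
          paste0("camera_pose missing/invalid: ", f))
  }
  if (!"bounding_boxes" %in% missing) {
    subnames <- character(0)
    for (j in seq_along(rec$bounding_boxes)) {
      bb <- rec$bounding_boxes[[j]]
      for (f in c("plant_id", "label", "scientific_name", "position_id",
                  "subimage_file_name", "date_planted",
                  "x_min", "x_max", "y_min", "y_max"))
        if (is.null(bb[[f]]))
          problems <- c(problems, sprintf("bounding_boxes[%d] missing field: %s", j, f))
      for (f in c("x_min", "x_max", "y_min", "y_max"))
        if (!is.null(bb[[f]]) &&
            (!is.numeric(bb[[f]]) || bb[[f]] < 0 || bb[[f]] > 1))
          problems <- c(problems, sprintf("bounding_boxes[%d] %s outside [0,1]", j, f))
      if (!is.null(bb$x_min) && !is.null(bb$x_max) && is.numeric(bb$x_min) &&
          is.numeric(bb$x_max) && bb$x_min > bb$x_max)
        problems <- c(problems, sprintf("bounding_boxes[%d] x_min > x_max", j))
      if (!is.null(bb$y_min) && !is.null(bb$y_max) && is.numeric(bb$y_min) &&
          is.numeric(bb$y_max) && bb$y_min > bb$y_max)
        problems <- c(problems, sprintf("bounding_boxes[%d] y_min > y_max", j))
      if (!is.null(bb$subimage_file_name)) {
        if (!grepl("^[0-9]{15,}\\.jpg$", bb$subimage_file_name))
          problems <- c(problems, sprintf(
            "bounding_boxes[%d] subimage_file_name must match yyyymmddhhmmss#.jpg", j))
        subnames <- c(subnames, bb$subimage_file_name)
      }
    }
    if (anyDuplicated(subnames))
      problems <- c(problems, "duplicate subimage_file_name within record")
  }
  if (!is.null(rec$box_origin) &&
      !rec$box_origin %in% c("upper-right", "upper-left"))
    problems <- c(problems, "box_origin must be \"upper-right\" or \"upper-left\"")
  problems
}

#' Write / read a metadata record as JSON
#'
#' Writing validates first; reading validates after parsing, so a
#' write-then-read round trip is the identity on valid records.
#'
#' @param rec a metadata record.
#' @param path file path (`.json`).
#' @export
write_metadata <- function(rec, path) {
  problems <- validate_metadata(rec)
  if (length(problems)) stop("invalid metadata record: ", paste(problems, collapse = "; "))
  jsonlite::write_json(unclass(rec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metadata
#' @return `read_metadata` returns a validated `metadata_record`.
#' @export
read_metadata <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = FALSE)
  problems <- validate_metadata(rec)
  if (length(problems)) stop("invalid metadata record at ", path, ": ",
                             paste(problems, collapse = "; "))
  structure(rec, class = "metadata_record")
}

#' Bounding boxes of a record in the internal convention
#'
#' Honors the record's declared `box_origin` (records without the field are
#' taken to be in the production upper-right convention).
#'
#' @param rec a metadata record.
#' @return list of `image_box` in the internal upper-left convention.
#' @export
record_boxes <- function(rec) {
  origin <- if (is.null(rec$box_origin)) "upper-right" else rec$box_origin
  lapply(rec$bounding_boxes, function(bb) {
    if (origin == "upper-right")
      image_box(1 - bb$x_max, 1 - bb$x_min, bb$y_min, bb$y_max)
    else
      image_box(bb$x_min, bb$x_max, bb$y_min, bb$y_max)
  })
}

#' Draw bounding-box outlines on a copy of the master image
#'
#' The overlay differs from the master only on the one-pixel perimeter
#' rows/columns of each box's pixel rectangle.
#'
#' @param master numeric array width x height x 3.
#' @param boxes list of `image_box` (internal convention), or a metadata
#'   record (whose declared convention is honored).
#' @param color RGB triple of the outline; default red.
#' @return the overlay array.
#' @export
draw_overlay <- function(master, boxes, color = c(1, 0, 0)) {
  if (inherits(boxes, "metadata_record") ||
      (is.list(boxes) && !is.null(boxes$bounding_boxes)))
    boxes <- record_boxes(boxes)
  if (inherits(boxes, "image_box")) boxes <- list(boxes)
  d <- dim(master)
  out <- master
  for (b in boxes) {
    px <- box_pixels(b, d[1], d[2])
    xr <- range(px$x); yr <- range(px$y)
    for (ch in 1:3) {
      out[xr[1]:xr[2], c(yr[1], yr[2]), ch] <- color[ch]
      out[c(xr[1], xr[2]), yr[1]:yr[2], ch] <- color[ch]
    }
  }
  out
}

#' File subimages into per-position-class subfolders
#'
#' Subimages referenced by the records are moved from the run root's
#' `subimages/` staging folder into `interior/` or `edge/` according to each
#' box's position class. Re-running is idempotent: files already in place
#' are left alone and never duplicated.
#'
#' @param records list of metadata records.
#' @param run_root run directory.
#' @param position_classes named character vector mapping `position_id` to
#'   `"edge"` or `"interior"`; defaults to the classes of
#'   [marked_positions()] (tight-packing ids >= 100 are interior).
#' @return invisibly, a data.frame of `file`, `class` placements.
#' @export
organize_outputs <- function(records, run_root, position_classes = NULL) {
  if (is.null(position_classes)) {
    mp <- marked_positions()
    position_classes <- stats::setNames(mp$class, mp$position_id)
  }
  placements <- list()
  for (rec in records) {
    for (bb in rec$bounding_boxes) {
      pid <- as.character(bb$position_id)
      cls <- if (as.integer(bb$position_id) >= 100L) "interior"
             else unname(position_classes[pid])
      if (is.null(cls) || is.na(cls))
        stop("unknown position_id with no class assignment: ", pid)
      dest_dir <- file.path(run_root, cls)
      dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
      src <- file.path(run_root, "subimages", bb$subimage_file_name)
      dest <- file.path(dest_dir, bb$subimage_file_name)
      if (file.exists(src) && !file.exists(dest)) file.rename(src, dest)
      placements[[length(placements) + 1]] <-
        data.frame(file = bb$subimage_file_name, class = cls,
                   stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, c(placements,
                             list(make.row.names = FALSE))))
}

#' Flag pairs of bounding boxes with positive overlap
#'
#' In tight-packing arrangements neighbouring plants' boxes intersect; this
#' reports every such pair within one master image.
#'
#' @param boxes list of `image_box`.
#' @return data.frame with columns `i`, `j`, `area` (intersection area in
#'   squared image fractions); zero rows when no pair overlaps.
#' @export
box_overlaps <- function(boxes) {
  out <- data.frame(i = integer(0), j = integer(0), area = numeric(0))
  n <- length(boxes)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- boxes[[i]]; b <- boxes[[j]]
    w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
    h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
    if (w > 0 && h > 0)
      out <- rbind(out, data.frame(i = i, j = j, area = w * h))
  }
  out
}
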