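# a minimal valid record for reuse
make_record <- function(box_origin = "upper-right", nbox = 1) {
  pose <- camera_pose(world_point(100, 200, 500), pan = 45, tilt = 30)
  plants <- random_scene(max(nbox, 1), seed = 3)$plants[seq_len(nbox)]
  boxes <- lapply(seq_len(nbox), function(i)
    image_box(0.1 * i, 0.1 * i + 0.2, 0.3, 0.6))
  metadata_record(as.POSIXct("2020-06-15 09:00:00", tz = "UTC"), pose_number = 4,
                  pose = pose, boxes = boxes, plants = plants,
                  room = "G19", institute = "UW", camera = "simcam",
                  lens = "rect35", box_origin = box_origin)
}

test_that("crop_subimages applies the floor/ceil half-open pixel rule", {
  master <- array(runif(100 * 100 * 3), dim = c(100, 100, 3))
  # identity box: exact copy
  expect_identical(crop_subimages(master, image_box(0, 1, 0, 1))[[1]], master)
  # hand-computed rectangle: 50x50 at offset (25, 25)
  crop <- crop_subimages(master, image_box(0.25, 0.75, 0.25, 0.75))[[1]]
  expect_equal(dim(crop), c(50, 50, 3))
  expect_identical(crop, master[26:75, 26:75, , drop = FALSE])
  # fractional edges round outward
  crop <- crop_subimages(master, image_box(0.249, 0.751, 0, 1))[[1]]
  expect_equal(dim(crop)[1], ceiling(75.1) - floor(24.9))
  # degenerate box errors
  expect_error(crop_subimages(master, image_box(0.5, 0.5, 0.2, 0.8)),
               "zero-area")
  # differing box sizes in one call
  crops <- crop_subimages(master, list(image_box(0, 0.5, 0, 0.5),
                                       image_box(0.2, 0.9, 0.1, 0.4)))
  expect_equal(dim(crops[[1]])[1:2], c(50, 50))
  expect_equal(dim(crops[[2]])[1:2], c(70, 30))
})

test_that("metadata records round-trip through JSON and validate strictly", {
  rec <- make_record(nbox = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_metadata(rec, tmp)
  back <- read_metadata(tmp)
  expect_equal(unclass(back), unclass(rec), tolerance = 1e-12)

  # file-name patterns
  expect_match(rec$file_name, "^[0-9]{14}-pose4\\.jpg$")
  expect_match(rec$bb_file_name, "^[0-9]{14}-pose4-bb\\.jpg$")
  expect_equal(rec$camera_pose$polar_angle, 120)  # tilt 30 down-from-horizontal

  # schema violations name the offending field
  bad <- unclass(rec)
  bad$bounding_boxes[[1]]$scientific_name <- NULL
  expect_match(paste(validate_metadata(bad), collapse = "; "),
               "scientific_name")
  bad <- unclass(rec); bad$camera_pose$z <- NULL
  expect_match(paste(validate_metadata(bad), collapse = "; "), "camera_pose.*z")
  bad <- unclass(rec); bad$file_name <- "notaname.jpg"
  expect_match(paste(validate_metadata(bad), collapse = "; "), "file_name")
  bad <- unclass(rec); bad$bounding_boxes[[1]]$x_min <- 1.2
  expect_match(paste(validate_metadata(bad), collapse = "; "), "x_min")
})

test_that("the writer's box convention flips x and the reader undoes it", {
  internal <- image_box(0.1, 0.3, 0.25, 0.6)
  pose <- camera_pose(world_point(0, 0, 500))
  plants <- random_scene(1, seed = 3)$plants
  t0 <- as.POSIXct("2020-06-15 09:00:00", tz = "UTC")

  rec_ur <- metadata_record(t0, 1, pose, list(internal), plants,
                            box_origin = "upper-right")
  # upper-right origin: x measured from the right edge
  expect_equal(rec_ur$bounding_boxes[[1]]$x_min, 1 - 0.3)
  expect_equal(rec_ur$bounding_boxes[[1]]$x_max, 1 - 0.1)
  expect_equal(rec_ur$bounding_boxes[[1]]$y_min, 0.25)
  expect_equal(unclass(record_boxes(rec_ur)[[1]]), unclass(internal))

  rec_ul <- metadata_record(t0, 1, pose, list(internal), plants,
                            box_origin = "upper-left")
  expect_equal(rec_ul$bounding_boxes[[1]]$x_min, 0.1)
  expect_equal(unclass(record_boxes(rec_ul)[[1]]), unclass(internal))
})

test_that("draw_overlay touches exactly the box perimeter", {
  master <- array(0.5, dim = c(60, 40, 3))
  expect_identical(draw_overlay(master, list()), master)

  b <- image_box(0.25, 0.75, 0.25, 0.75)
  out <- draw_overlay(master, b, color = c(1, 0, 0))
  changed <- which(out[, , 1] != master[, , 1], arr.ind = TRUE)
  xr <- c(floor(0.25 * 60) + 1, ceiling(0.75 * 60))
  yr <- c(floor(0.25 * 40) + 1, ceiling(0.75 * 40))
  perim <- unique(rbind(
    expand.grid(row = xr[1]:xr[2], col = yr),
    expand.grid(row = xr, col = yr[1]:yr[2])))
  expect_setequal(paste(changed[, 1], changed[, 2]),
                  paste(perim$row, perim$col))
})

test_that("organize_outputs files subimages by class, conserving counts, idempotently", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "subimages"))
  rec <- make_record(nbox = 3)
  for (bb in rec$bounding_boxes)
    writeLines("x", file.path(root, "subimages", bb$subimage_file_name))
  classes <- stats::setNames(
    c("edge", "interior", "interior"),
    vapply(rec$bounding_boxes, function(b) as.character(b$position_id), character(1)))
  placed <- organize_outputs(list(rec), root, classes)
  expect_equal(nrow(placed), 3)
  expect_equal(sum(placed$class == "edge") + sum(placed$class == "interior"), 3)
  n_edge <- length(list.files(file.path(root, "edge")))
  n_int <- length(list.files(file.path(root, "interior")))
  expect_equal(n_edge + n_int, 3)

  # idempotent: re-running moves nothing and duplicates nothing
  placed2 <- organize_outputs(list(rec), root, classes)
  expect_equal(length(list.files(file.path(root, "edge"))), n_edge)
  expect_equal(length(list.files(file.path(root, "interior"))), n_int)
  expect_equal(nrow(placed2), 3)

  expect_error(organize_outputs(list(rec), root,
                                c("999" = "interior")), "unknown position")
})

test_that("box_overlaps matches brute-force pairwise intersection", {
  set.seed(81)
  for (trial in 1:10) {
    boxes <- lapply(1:6, function(i) {
      x <- sort(runif(2)); y <- sort(runif(2))
      image_box(x[1], x[2], y[1], y[2])
    })
    ov <- box_overlaps(boxes)
    for (i in 1:5) for (j in (i + 1):6) {
      a <- boxes[[i]]; b <- boxes[[j]]
      w <- min(a[["x_max"]], b[["x_max"]]) - max(a[["x_min"]], b[["x_min"]])
      h <- min(a[["y_max"]], b[["y_max"]]) - max(a[["y_min"]], b[["y_min"]])
      hit <- any(ov$i == i & ov$j == j)
      expect_equal(hit, w > 0 && h > 0)
      if (hit) expect_equal(ov$area[ov$i == i & ov$j == j], w * h)
    }
  }
})
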