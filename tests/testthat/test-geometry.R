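test_that("world_to_camera matches identities and the rotation-matrix oracle", {
  origin <- camera_pose(world_point(0, 0, 0), pan = 0, tilt = 0)
  expect_equal(as.numeric(world_to_camera(origin, world_point(100, 0, 0))),
               c(100, 0, 0))
  pose <- camera_pose(world_point(312, 87, 455), pan = 123, tilt = 34)
  expect_equal(as.numeric(world_to_camera(pose, pose$position)), c(0, 0, 0))

  set.seed(11)
  for (i in 1:25) {
    pose <- camera_pose(world_point(runif(1, 0, 1150), runif(1, 0, 840),
                                    runif(1, 0, 718)),
                        pan = runif(1, 0, 360), tilt = runif(1, -89, 89))
    p <- world_point(runif(1, -500, 1500), runif(1, -500, 1200),
                     runif(1, -200, 900))
    expect_equal(as.numeric(world_to_camera(pose, p)),
                 oracle_world_to_camera(pose, p), tolerance = 1e-12)
  }
  # the spec example: pan 30 degrees, tilt 20 below horizontal
  pose <- camera_pose(world_point(100, 200, 300), pan = 30, tilt = 20)
  p <- world_point(600, 450, 80)
  expect_equal(as.numeric(world_to_camera(pose, p)),
               oracle_world_to_camera(pose, p), tolerance = 1e-12)
})

test_that("world_to_camera is a rigid transform (distances preserved)", {
  set.seed(21)
  for (i in 1:50) {
    pose <- camera_pose(world_point(runif(1, 0, 1150), runif(1, 0, 840),
                                    runif(1, 0, 718)),
                        runif(1, 0, 360), runif(1, -90, 90))
    a <- runif(3, -1000, 2000); b <- runif(3, -1000, 2000)
    qa <- as.numeric(world_to_camera(pose, world_point(a[1], a[2], a[3])))
    qb <- as.numeric(world_to_camera(pose, world_point(b[1], b[2], b[3])))
    d_world <- sqrt(sum((a - b)^2)); d_cam <- sqrt(sum((qa - qb)^2))
    expect_lt(abs(d_world - d_cam) / d_world, 1e-9)
  }
})

test_that("camera_to_image maps the optical axis, the FOV boundary, and generic angles", {
  m <- camera_model()
  expect_equal(unname(camera_to_image(m, c(123.4, 0, 0))), c(0.5, 0.5))
  expect_equal(unname(camera_to_image(m, c(1, 0, 0))), c(0.5, 0.5))

  # bearing at exactly half the horizontal FOV lands on the image border
  hf <- half_fov(m)[["h"]]
  q <- c(cos(hf * pi / 180), sin(hf * pi / 180), 0)  # bearing towards +y (left)
  expect_equal(unname(camera_to_image(m, q)[1]), 0, tolerance = 1e-9)
  q <- c(cos(hf * pi / 180), -sin(hf * pi / 180), 0)
  expect_equal(unname(camera_to_image(m, q)[1]), 1, tolerance = 1e-9)
  vf <- half_fov(m)[["v"]]
  q <- c(cos(vf * pi / 180), 0, sin(vf * pi / 180))
  expect_equal(unname(camera_to_image(m, q)[2]), 0, tolerance = 1e-9)

  # generic bearing/elevation against the closed-form tan-projection oracle
  b <- 10; e <- 5
  d <- c(cos(e * pi / 180) * cos(b * pi / 180),
         cos(e * pi / 180) * sin(b * pi / 180),
         sin(e * pi / 180))
  expect_equal(camera_to_image(m, d), oracle_project_angles(m, b, e),
               tolerance = 1e-12)

  expect_error(camera_to_image(m, c(-1, 0, 0)), "behind")
  expect_error(camera_to_image(m, c(0, 1, 1)), "behind")
})

test_that("project_sphere handles degenerate, boundary, and error cases", {
  m <- camera_model()
  pose <- camera_pose(world_point(0, 0, 500), pan = 0, tilt = 0)
  # zero radius: zero-area box at the projected center
  ctr <- world_point(800, 30, 520)
  box <- project_sphere(pose, m, bounding_sphere(ctr, 0))
  uv <- camera_to_image(m, world_to_camera(pose, ctr))
  expect_equal(unname(box[["x_min"]]), unname(uv[["u"]]))
  expect_equal(unname(box[["x_max"]]), unname(uv[["u"]]))
  expect_equal(unname(box[["y_min"]]), unname(uv[["v"]]))

  # on-axis sphere subtending the half horizontal FOV spans full image width
  hf <- half_fov(m)[["h"]] * pi / 180
  D <- 1000; R <- D * sin(hf)
  box <- project_sphere(pose, m, bounding_sphere(world_point(D, 0, 500), R))
  expect_equal(unname(box[["x_min"]]), 0)
  expect_equal(unname(box[["x_max"]]), 1)

  expect_error(project_sphere(pose, m, bounding_sphere(world_point(10, 0, 500), 50)),
               "inside")
  expect_error(project_sphere(pose, m, bounding_sphere(world_point(-500, 0, 500), 50)),
               "not visible")
})

test_that("project_sphere boxes contain dense surface samples and are tight", {
  set.seed(31)
  m <- camera_model()
  done <- 0
  while (done < 30) {
    ctr <- c(runif(1, 100, 1050), runif(1, 100, 740), runif(1, 0, 150))
    R <- runif(1, 30, 140)
    pose <- random_aimed_pose(ctr)
    D <- sqrt(sum((as.numeric(pose$position) - ctr)^2))
    if (D <= R * 1.5) next
    box <- project_sphere(pose, m, bounding_sphere(ctr, R))
    if (is.null(box)) next
    pts <- sphere_samples(ctr, R, 10000)
    q <- world_to_camera(pose, pts)
    q <- q[q[, 1] > 0, , drop = FALSE]
    uv <- camera_to_image(m, q)
    inside_img <- uv[, 1] >= 0 & uv[, 1] <= 1 & uv[, 2] >= 0 & uv[, 2] <= 1
    uv <- uv[inside_img, , drop = FALSE]
    # exact containment of every projected surface sample
    expect_true(all(uv[, 1] >= box[["x_min"]] - 1e-12 &
                    uv[, 1] <= box[["x_max"]] + 1e-12 &
                    uv[, 2] >= box[["y_min"]] - 1e-12 &
                    uv[, 2] <= box[["y_max"]] + 1e-12))
    # tightness: unclamped edges within 1% of image width of the sample hull
    if (box[["x_min"]] > 0) expect_lt(min(uv[, 1]) - box[["x_min"]], 0.01)
    if (box[["x_max"]] < 1) expect_lt(box[["x_max"]] - max(uv[, 1]), 0.01)
    if (box[["y_min"]] > 0) expect_lt(min(uv[, 2]) - box[["y_min"]], 0.01)
    if (box[["y_max"]] < 1) expect_lt(box[["y_max"]] - max(uv[, 2]), 0.01)
    done <- done + 1
  }
})

test_that("image_to_ground inverts the forward chain and matches ray marching", {
  m <- camera_model()
  # nadir: camera pointing straight down sees the point directly below
  pose <- camera_pose(world_point(400, 300, 650), pan = 0, tilt = 90)
  g <- image_to_ground(pose, m, 0.5, 0.5, 0)
  expect_equal(as.numeric(g), c(400, 300, 0), tolerance = 1e-9)

  # round trip on ground-plane points
  set.seed(41)
  pose <- random_aimed_pose(c(500, 400, 0))
  for (i in 1:100) {
    p <- c(runif(1, 0, 1150), runif(1, 0, 840), 0)
    q <- world_to_camera(pose, world_point(p[1], p[2], p[3]))
    if (q[1] <= 0) next
    uv <- camera_to_image(m, q)
    g <- image_to_ground(pose, m, uv[["u"]], uv[["v"]], 0)
    expect_lt(max(abs(as.numeric(g) - p)), 1e-6)
  }

  # oblique pose, corner pixel, vs the numeric ray-marching oracle
  pose <- camera_pose(world_point(200, 700, 500), pan = 295, tilt = 40)
  g <- image_to_ground(pose, m, 0.999, 0.999, 0)
  expect_equal(as.numeric(g), oracle_ray_ground(pose, m, 0.999, 0.999, 0),
               tolerance = 1e-6)

  # errors: ray away from or parallel to the plane
  up <- camera_pose(world_point(400, 300, 650), pan = 0, tilt = -90)
  expect_error(image_to_ground(up, m, 0.5, 0.5, 0), "away|parallel")
  level <- camera_pose(world_point(400, 300, 650), pan = 0, tilt = 0)
  expect_error(image_to_ground(level, m, 0.5, 0.5, 0), "parallel|away")
})

test_that("generate_pose_set aims at the target and respects class and volume", {
  target <- world_point(480, 320, 0)
  rings <- data.frame(height = 500, radius = 130, count = 1)
  ps <- generate_pose_set(target, "interior", rings)
  expect_length(ps, 1)
  q <- world_to_camera(ps[[1]], target)
  expect_lt(max(abs(q[c("y_f", "z_f")])), 1e-6)
  expect_gt(q[["x_f"]], 0)

  # counting with no volume clipping
  rings <- data.frame(height = c(450, 550), radius = c(100, 130), count = c(5, 7))
  ps <- generate_pose_set(target, "interior", rings)
  expect_length(ps, 12)

  # edge class: all position azimuths within a 180-degree half-range
  edge_target <- world_point(455, 30, 0)
  ps <- generate_pose_set(edge_target, "edge",
                          data.frame(height = 500, radius = 120, count = 8))
  az <- vapply(ps, function(p) {
    d <- as.numeric(p$position) - as.numeric(edge_target)
    atan2(d[2], d[1]) * 180 / pi
  }, numeric(1))
  expect_true(all(az >= -1e-9 & az <= 180 + 1e-9))

  # every returned position lies inside the travel volume
  ps <- generate_pose_set(world_point(175, 30, 0), "edge",
                          data.frame(height = 500, radius = 300, count = 16))
  expect_true(all(vapply(ps, function(p) in_volume(p$position, c(1150, 840, 718)),
                         logical(1))))

  expect_error(generate_pose_set(target, "interior",
                                 data.frame(height = 5000, radius = 10, count = 2)),
               "no candidate")
})

test_that("invalid poses, models, and boxes are rejected", {
  expect_error(camera_pose(world_point(0, 0, 0), pan = 0, tilt = 120), "tilt")
  expect_error(camera_model(width = 0), "width")
  expect_error(camera_model(fov_diagonal = 200), "fov")
  expect_error(image_box(0.5, 0.2, 0, 1), "min <= max")
  expect_error(image_box(-0.1, 0.2, 0, 1), "\\[0, 1\\]")
  expect_error(world_point(Inf, 0, 0), "finite")
  expect_true(in_volume(c(0, 0, 0), c(1150, 840, 718)))
  expect_false(in_volume(c(-1, 0, 0), c(1150, 840, 718)))
})
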