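#' World-frame point
#'
#' A point in the gantry's fixed world frame: millimetres, origin at the base
#' corner of the first column, z pointing up.
#'
#' @param x,y,z coordinates in mm.
#' @return object of class `world_point` (named numeric length 3).
#' @export
world_point <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) stop("world_point coordinates must be finite")
  structure(p, class = "world_point")
}

#' Test containment of a point in the travel volume
#'
#' @param p a `world_point` (or numeric length 3).
#' @param volume numeric length-3 volume extents (mm), or a `gantry_config`.
#' @return logical.
#' @export
in_volume <- function(p, volume) {
  if (inherits(volume, "gantry_config")) volume <- volume$volume
  p <- as.numeric(p)
  all(p >= 0) && all(p <= volume)
}

#' Camera pose: optical-center position plus pan and tilt
#'
#' Pan is the azimuthal angle in degrees, wrapped into \[0, 360); pan = 0
#' points the optical axis along world +x, increasing counter-clockwise
#' (towards +y). Tilt is measured from the horizontal in degrees, positive
#' pointing downward, in \[-90, 90\]; the equivalent polar angle (0 = zenith)
#' is `tilt + 90` and is what the metadata writer emits.
#'
#' @param position a `world_point` (optical center, mm).
#' @param pan,tilt degrees.
#' @return object of class `camera_pose`.
#' @export
camera_pose <- function(position, pan = 0, tilt = 0) {
  if (!inherits(position, "world_point")) position <- world_point(position[1], position[2], position[3])
  pan <- as.numeric(pan) %% 360
  tilt <- as.numeric(tilt)
  if (!is.finite(pan) || !is.finite(tilt)) stop("pan/tilt must be finite")
  if (tilt < -90 || tilt > 90) stop("tilt must lie in [-90, 90] degrees (down-positive from horizontal)")
  structure(list(position = position, pan = pan, tilt = tilt), class = "camera_pose")
}

#' Camera intrinsics: resolution and rectilinear field of view
#'
#' The single supported projection is rectilinear (pinhole): straight world
#' lines stay straight and off-axis displacement is proportional to the
#' tangent of the off-axis angle. The focal length in pixels is derived from
#' the diagonal field of view and the pixel diagonal,
#' `f = (sqrt(w^2 + h^2)/2) / tan(fov/2)`.
#'
#' @param width,height resolution in pixels; default 4000 x 3000.
#' @param fov_diagonal diagonal field of view in degrees; default 98.7.
#' @param projection projection model; only `"rectilinear"`.
#' @return object of class `camera_model` with derived `focal_px`.
#' @export
camera_model <- function(width = 4000L, height = 3000L, fov_diagonal = 98.7,
                         projection = "rectilinear") {
  projection <- match.arg(projection)
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width > 0, height > 0, fov_diagonal > 0, fov_diagonal < 180)
  diag_px <- sqrt(as.numeric(width)^2 + as.numeric(height)^2)
  focal_px <- (diag_px / 2) / tan(fov_diagonal * pi / 360)
  structure(list(width = width, height = height,
                 fov_diagonal = as.numeric(fov_diagonal),
                 projection = projection, focal_px = focal_px),
            class = "camera_model")
}

#' Horizontal / vertical half field of view (degrees)
#' @param model a `camera_model`.
#' @return named numeric `c(h = , v = )` half-FOV in degrees.
#' @export
half_fov <- function(model) {
  c(h = atan2(model$width / 2, model$focal_px),
    v = atan2(model$height / 2, model$focal_px)) * 180 / pi
}

# 3x3 rotation matrix taking world vectors into the camera frame of `pose`.
# Rows are the camera axes expressed in world coordinates:
#   x_f forward (optical axis), y_f left, z_f up.
rotation_w2c <- function(pose) {
  p <- pose$pan * pi / 180
  t <- pose$tilt * pi / 180
  ct <- cos(t); st <- sin(t); cp <- cos(p); sp <- sin(p)
  fwd <- c(ct * cp, ct * sp, -st)
  left <- c(-sp, cp, 0)
  up <- c(st * cp, st * sp, ct)
  rbind(fwd, left, up, deparse.level = 0)
}

#' Transform a world point into the camera frame
#'
#' Rigid transform: translation by minus the optical-center position followed
#' by the inverse pan rotation about the vertical axis and the inverse tilt
#' rotation about the camera's transverse axis. In the camera frame the
#' optical axis is +x (forward), y points left and z up; a point is visible
#' only if its forward coordinate is positive.
#'
#' @param pose a `camera_pose`.
#' @param p a `world_point`, or an n x 3 matrix of world coordinates.
#' @return a `camera_frame_point` (named numeric `x_f`, `y_f`, `z_f`) or an
#'   n x 3 matrix with those columns.
#' @export
world_to_camera <- function(pose, p) {
  stopifnot(inherits(pose, "camera_pose"))
  R <- rotation_w2c(pose)
  if (is.matrix(p)) {
    q <- t(R %*% (t(p) - as.numeric(pose$position)))
    colnames(q) <- c("x_f", "y_f", "z_f")
    return(q)
  }
  q <- as.numeric(R %*% (as.numeric(p) - as.numeric(pose$position)))
  structure(c(x_f = q[1], y_f = q[2], z_f = q[3]), class = "camera_frame_point")
}

#' Project a camera-frame point to fractional image coordinates
#'
#' Rectilinear mapping with the optical axis at (0.5, 0.5). The internal
#' image convention is origin top-left: u grows rightward, v grows downward.
#' Since camera-frame +y points left and +z up,
#' `u = 0.5 - f * (y_f/x_f) / width` and `v = 0.5 - f * (z_f/x_f) / height`.
#'
#' @param model a `camera_model`.
#' @param q camera-frame point (`x_f`, `y_f`, `z_f`) or n x 3 matrix.
#' @return named numeric `c(u = , v = )` in fractions of image width/height
#'   (or an n x 2 matrix). Values outside \[0,1\] mean outside the frame.
#' @export
camera_to_image <- function(model, q) {
  stopifnot(inherits(model, "camera_model"))
  if (is.matrix(q)) {
    if (any(q[, 1] <= 0)) stop("point behind camera: x_f must be > 0")
    u <- 0.5 - model$focal_px * (q[, 2] / q[, 1]) / model$width
    v <- 0.5 - model$focal_px * (q[, 3] / q[, 1]) / model$height
    return(cbind(u = u, v = v))
  }
  q <- as.numeric(q)
  if (q[1] <= 0) stop("point behind camera: x_f must be > 0")
  c(u = 0.5 - model$focal_px * (q[2] / q[1]) / model$width,
    v = 0.5 - model$focal_px * (q[3] / q[1]) / model$height)
}

#' Bounding sphere standing in for a plant
#'
#' For box computation a plant is replaced by a sphere, centred at its world
#' position, with radius large enough to contain it.
#'
#' @param center a `world_point`.
#' @param radius sphere radius in mm, `>= 0`.
#' @return object of class `bounding_sphere`.
#' @export
bounding_sphere <- function(center, radius) {
  if (!inherits(center, "world_point")) center <- world_point(center[1], center[2], center[3])
  radius <- as.numeric(radius)
  stopifnot(is.finite(radius), radius >= 0)
  structure(list(center = center, radius = radius), class = "bounding_sphere")
}

#' Fractional image-space bounding box
#'
#' Coordinates are unitless fractions of image width/height in the internal
#' top-left-origin convention (u rightward, v downward).
#'
#' @param x_min,x_max,y_min,y_max fractions in \[0,1\], min <= max.
#' @return object of class `image_box` (named numeric length 4).
#' @export
image_box <- function(x_min, x_max, y_min, y_max) {
  b <- c(x_min = as.numeric(x_min), x_max = as.numeric(x_max),
         y_min = as.numeric(y_min), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("image_box coordinates must be finite")
  if (b["x_min"] > b["x_max"] || b["y_min"] > b["y_max"])
    stop("image_box requires min <= max")
  if (any(b < 0) || any(b > 1)) stop("image_box coordinates must lie in [0, 1]")
  structure(b, class = "image_box")
}

#' Project a bounding sphere to an image-space bounding box
#'
#' The sphere subtends a half-angle `asin(R/D)` from the camera (D the
#' optical-center-to-center distance). Its silhouette is the tangent cone
#' about the center direction; under rectilinear projection that cone's
#' boundary maps to a conic in the image plane. The box returned is the exact
#' axis-aligned extent of that conic (closed-form roots of a quadratic per
#' image axis), clamped to \[0,1\] — the tightest axis-aligned box containing
#' the whole projected sphere. If the clamped box has zero area (sphere
#' entirely outside the frame), `NULL` is returned rather than an error.
#'
#' @param pose a `camera_pose`.
#' @param model a `camera_model`.
#' @param s a `bounding_sphere`.
#' @return an `image_box`, or `NULL` when the projection falls fully outside
#'   the image.
#' @export
project_sphere <- function(pose, model, s) {
  stopifnot(inherits(s, "bounding_sphere"))
  q <- as.numeric(world_to_camera(pose, s$center))
  D <- sqrt(sum(q^2))
  if (D <= s$radius) stop("camera lies inside the bounding sphere (D <= R)")
  if (q[1] <= 0) stop("sphere center not visible: x_f must be > 0")
  ctr <- camera_to_image(model, q)
  if (s$radius == 0) {
    b <- pmin(pmax(c(ctr["u"], ctr["u"], ctr["v"], ctr["v"]), 0), 1)
    if (b[1] >= 1 || b[2] <= 0 || b[3] >= 1 || b[4] <= 0) return(NULL)
    return(image_box(b[1], b[2], b[3], b[4]))
  }
  cdir <- q / D
  k <- 1 - (s$radius / D)^2            # cos^2(alpha), alpha = asin(R/D)
  # Tangent-plane coordinates: Y = y_f/x_f (left), Z = z_f/x_f (up).
  # Cone boundary: (c1 + c2 Y + c3 Z)^2 = k (1 + Y^2 + Z^2), a conic F(Y,Z)=0.
  c1 <- cdir[1]; c2 <- cdir[2]; c3 <- cdir[3]
  Fc <- function(Y, Z) (c1 + c2 * Y + c3 * Z)^2 - k * (1 + Y^2 + Z^2)
  # Extremes of Y: dF/dZ = 0 gives Z linear in Y; substitution gives a
  # quadratic in Y whose coefficients we recover by evaluation at -1, 0, 1.
  extremes_of <- function(which) {
    if (which == "Y") {
      den <- c3^2 - k
      f <- function(Y) {
        Z <- if (abs(den) < 1e-300) 0 else -c3 * (c1 + c2 * Y) / den
        Fc(Y, Z)
      }
    } else {
      den <- c2^2 - k
      f <- function(Z) {
        Y <- if (abs(den) < 1e-300) 0 else -c2 * (c1 + c3 * Z) / den
        Fc(Y, Z)
      }
    }
    f0 <- f(0); f1 <- f(1); fm1 <- f(-1)
    a <- (f1 + fm1) / 2 - f0
    b <- (f1 - fm1) / 2
    cc <- f0
    if (!is.finite(a) || a >= 0) return(NULL)   # not an ellipse: unbounded extent
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NULL)
    r <- sqrt(disc)
    sort(c((-b - r) / (2 * a), (-b + r) / (2 * a)))
  }
  ey <- extremes_of("Y")  # range of y_f/x_f
  ez <- extremes_of("Z")
  fx <- model$focal_px / model$width
  fy <- model$focal_px / model$height
  # u = 0.5 - fx * Y: Y max -> u min
  if (is.null(ey)) { u_lo <- 0; u_hi <- 1 } else {
    u_lo <- 0.5 - fx * ey[2]; u_hi <- 0.5 - fx * ey[1]
  }
  if (is.null(ez)) { v_lo <- 0; v_hi <- 1 } else {
    v_lo <- 0.5 - fy * ez[2]; v_hi <- 0.5 - fy * ez[1]
  }
  b <- c(max(u_lo, 0), min(u_hi, 1), max(v_lo, 0), min(v_hi, 1))
  if (b[1] >= b[2] || b[3] >= b[4]) return(NULL)
  image_box(b[1], b[2], b[3], b[4])
}

#' Back-project an image point onto a horizontal ground plane
#'
#' Inverts the projection chain for points of known height: the pixel ray is
#' expressed in world coordinates and intersected with the plane
#' `z = ground_z`. Exact inverse of `world_to_camera` + `camera_to_image` for
#' points on that plane.
#'
#' @param pose a `camera_pose`.
#' @param model a `camera_model`.
#' @param u,v fractional image coordinates.
#' @param ground_z plane height in mm (default 0).
#' @return a `world_point` on the plane.
#' @export
image_to_ground <- function(pose, model, u, v, ground_z = 0) {
  # direction in camera frame for fractional (u, v)
  d_cam <- c(1,
             (0.5 - u) * model$width / model$focal_px,
             (0.5 - v) * model$height / model$focal_px)
  d_world <- as.numeric(t(rotation_w2c(pose)) %*% d_cam)
  pz <- as.numeric(pose$position)[3]
  if (d_world[3] == 0) {
    if (pz != ground_z) stop("ray parallel to the ground plane: no intersection")
    stop("ray lies in the ground plane: intersection undefined")
  }
  t_hit <- (ground_z - pz) / d_world[3]
  if (t_hit <= 0) stop("ray points away from the ground plane: no intersection in front of the camera")
  g <- as.numeric(pose$position) + t_hit * d_world
  world_point(g[1], g[2], g[3])
}

#' Generate a set of camera poses aimed at a target
#'
#' Poses lie on circles ("rings") centred above the target, evenly spaced in
#' azimuth, each oriented so the optical axis passes through the target.
#' Interior positions are imaged from full circles; edge positions only from
#' the half-range of azimuths facing into the travel volume (half a cylinder).
#' Candidate positions falling outside the travel volume are dropped.
#'
#' @param target a `world_point` (typically a plant position on the floor).
#' @param position_class `"interior"` or `"edge"`.
#' @param rings data.frame (or list of length-3 vectors) with columns
#'   `height` (absolute z, mm), `radius` (mm), `count` (poses on the ring).
#' @param volume travel-volume extents (length-3) or a `gantry_config`.
#' @return list of `camera_pose`; error if every candidate is dropped.
#' @export
generate_pose_set <- function(target, position_class = c("interior", "edge"),
                              rings, volume = c(1150, 840, 718)) {
  position_class <- match.arg(position_class)
  if (inherits(volume, "gantry_config")) volume <- volume$volume
  if (!inherits(target, "world_point")) target <- world_point(target[1], target[2], target[3])
  if (is.data.frame(rings)) {
    rings <- lapply(seq_len(nrow(rings)), function(i)
      c(height = rings$height[i], radius = rings$radius[i], count = rings$count[i]))
  }
  if (length(rings) == 0) stop("rings must be non-empty")
  tx <- as.numeric(target)
  # edge positions face the interior: centre the half-range of azimuths on
  # the inward normal of the nearest side face of the travel volume
  face_dist <- c(tx[1], volume[1] - tx[1], tx[2], volume[2] - tx[2])
  phi_c <- c(0, pi, pi / 2, -pi / 2)[which.min(face_dist)]
  poses <- list()
  for (ring in rings) {
    h <- as.numeric(ring[["height"]]); r <- as.numeric(ring[["radius"]])
    n <- as.integer(ring[["count"]])
    if (n <= 0) stop("ring counts must be > 0")
    phis <- if (position_class == "interior") {
      seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
    } else if (n == 1) phi_c else {
      phi_c + seq(-pi / 2, pi / 2, length.out = n)
    }
    for (phi in phis) {
      pos <- c(tx[1] + r * cos(phi), tx[2] + r * sin(phi), h)
      if (!in_volume(pos, volume)) next
      aim <- tx - pos
      pan <- (atan2(aim[2], aim[1]) * 180 / pi) %% 360
      horiz <- sqrt(aim[1]^2 + aim[2]^2)
      tilt <- atan2(-aim[3], horiz) * 180 / pi   # camera above target -> positive (down)
      poses[[length(poses) + 1]] <- camera_pose(world_point(pos[1], pos[2], pos[3]), pan, tilt)
    }
  }
  if (length(poses) == 0) stop("no candidate pose lies inside the travel volume")
  poses
}
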