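# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths: explicit elementary rotation matrices,
# closed-form tan projection, numeric ray marching, dense sphere sampling,
# and a hand-written sRGB -> CIELAB conversion.

# elementary rotations
Rz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
Ry <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# oracle for world_to_camera: translate, undo pan about the vertical axis,
# undo tilt about the camera's transverse (y) axis
oracle_world_to_camera <- function(pose, p) {
  q1 <- Rz(-pose$pan) %*% (as.numeric(p) - as.numeric(pose$position))
  as.numeric(Ry(-pose$tilt) %*% q1)
}

# oracle for camera_to_image from bearing/elevation via the tan law
oracle_project_angles <- function(model, bearing_deg, elev_deg) {
  f <- (sqrt(model$width^2 + model$height^2) / 2) /
    tan(model$fov_diagonal * pi / 360)
  b <- bearing_deg * pi / 180; e <- elev_deg * pi / 180
  # direction at bearing b (towards +y = left) and elevation e
  d <- c(cos(e) * cos(b), cos(e) * sin(b), sin(e))
  c(u = 0.5 - f * (d[2] / d[1]) / model$width,
    v = 0.5 - f * (d[3] / d[1]) / model$height)
}

# oracle for image_to_ground: march along the pixel ray until the ground
# plane is crossed, then bisect
oracle_ray_ground <- function(pose, model, u, v, ground_z = 0, step = 1) {
  d_cam <- c(1, (0.5 - u) * model$width / model$focal_px,
             (0.5 - v) * model$height / model$focal_px)
  # rows are the camera-frame images of the world basis vectors, so this
  # matrix is the transpose of the world-to-camera rotation
  p0pose <- camera_pose(world_point(0, 0, 0), pose$pan, pose$tilt)
  Rt <- rbind(oracle_world_to_camera(p0pose, c(1, 0, 0)),
              oracle_world_to_camera(p0pose, c(0, 1, 0)),
              oracle_world_to_camera(p0pose, c(0, 0, 1)))
  d_world <- as.numeric(Rt %*% d_cam)
  p0 <- as.numeric(pose$position)
  zfun <- function(t) p0[3] + t * d_world[3] - ground_z
  t_lo <- 0; t_hi <- step
  while (sign(zfun(t_hi)) == sign(zfun(t_lo)) && t_hi < 1e7) t_hi <- t_hi * 2
  if (t_hi >= 1e7) stop("oracle: ray never crosses the plane")
  t_hit <- uniroot(zfun, c(t_lo, t_hi), tol = 1e-13)$root
  p0 + t_hit * d_world
}

# dense sphere-surface sample (deterministic Fibonacci lattice)
sphere_samples <- function(center, radius, n = 10000) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * r * cos(phi),
        center[2] + radius * r * sin(phi),
        center[3] + radius * z)
}

# hand-written sRGB (D65) -> CIELAB reference
oracle_lab_b <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  white <- c(0.95047, 1, 1.08883)
  tf <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- tf(xyz / white)
  200 * (fx[2] - fx[3])
}

# Clopper-Pearson cross-check by root finding on the binomial tails
oracle_clopper_pearson <- function(k, n, alpha = 0.05) {
  lower <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# a random pose aimed at a target, guaranteed visible
random_aimed_pose <- function(target, dist_range = c(300, 650),
                              tilt_range = c(15, 80)) {
  phi <- runif(1, 0, 2 * pi)
  tilt <- runif(1, tilt_range[1], tilt_range[2])
  d <- runif(1, dist_range[1], dist_range[2])
  horiz <- d * cos(tilt * pi / 180)
  pos <- c(target[1] + horiz * cos(phi), target[2] + horiz * sin(phi),
           target[3] + d * sin(tilt * pi / 180))
  pan <- (atan2(target[2] - pos[2], target[1] - pos[1]) * 180 / pi) %% 360
  camera_pose(world_point(pos[1], pos[2], pos[3]), pan, tilt)
}

# small camera model shared by rendering tests
test_model <- function(w = 400, h = 300) camera_model(w, h)
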