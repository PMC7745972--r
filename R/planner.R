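#' Stepper-motion profile of the gantry axes
#'
#' Encodes the actuator drive train: a pulse at rate `pulse_rate` advances a
#' stepper by `step_fraction` of a revolution, geared down by `gear_ratio`,
#' moving the axis `dist_per_rev` mm per full actuator revolution, so the
#' axis speed is `v = pulse_rate * dist_per_rev * step_fraction * gear_ratio *
#' step_mode` mm/s — 0.105 mm per pulse at the default constants in
#' full-stepping mode. Acceleration follows a linear (trapezoidal velocity)
#' ramp at `acceleration` pulses/s^2.
#'
#' @param pulse_rate peak pulse rate, pulses/s (> 0).
#' @param acceleration pulses/s^2 (> 0).
#' @param dist_per_rev mm travelled per actuator revolution; default 105.
#' @param step_fraction fraction of a revolution per step; default 1.8/360.
#' @param gear_ratio gearbox reduction; default 0.2.
#' @param step_mode `1` for full-stepping, `0.5` for half-stepping.
#' @param parallel_axes if `TRUE` the three axes move simultaneously (leg
#'   time is the slowest axis); if `FALSE` they move one after another (sum).
#' @return object of class `motion_profile`.
#' @export
motion_profile <- function(pulse_rate = 3000, acceleration = 10000,
                           dist_per_rev = 105, step_fraction = 1.8 / 360,
                           gear_ratio = 0.2, step_mode = 0.5,
                           parallel_axes = FALSE) {
  stopifnot(pulse_rate > 0, acceleration > 0,
            dist_per_rev > 0, step_fraction > 0, gear_ratio > 0)
  if (!step_mode %in% c(1, 0.5)) stop("step_mode must be 1 (full) or 0.5 (half)")
  structure(list(pulse_rate = as.numeric(pulse_rate),
                 acceleration = as.numeric(acceleration),
                 dist_per_rev = as.numeric(dist_per_rev),
                 step_fraction = as.numeric(step_fraction),
                 gear_ratio = as.numeric(gear_ratio),
                 step_mode = as.numeric(step_mode),
                 parallel_axes = isTRUE(parallel_axes)),
            class = "motion_profile")
}

#' Millimetres of axis travel per pulse
#' @param profile a `motion_profile`.
#' @return mm/pulse.
#' @export
mm_per_pulse <- function(profile) {
  profile$dist_per_rev * profile$step_fraction * profile$gear_ratio * profile$step_mode
}

#' Axis speed at the peak pulse rate
#'
#' `v = p_r * d * s * r * m` mm/s.
#'
#' @param profile a `motion_profile`.
#' @return speed in mm/s.
#' @export
axis_speed <- function(profile) profile$pulse_rate * mm_per_pulse(profile)

#' Travel time of one leg under a trapezoidal velocity profile
#'
#' Distances are converted to pulses; each axis ramps linearly up to the peak
#' pulse rate and back down. For a move of `D` pulses the time is
#' `D/p_r + p_r/a` when the peak rate is reached (`D >= p_r^2/a`), else the
#' triangular profile `2*sqrt(D/a)`. The leg time is the maximum over axes
#' when they move in parallel, the sum when sequential.
#'
#' @param distances numeric length-3 (or shorter), per-axis travel in mm,
#'   non-negative.
#' @param profile a `motion_profile`.
#' @return time in seconds.
#' @export
leg_time <- function(distances, profile) {
  distances <- abs(as.numeric(distances))
  pulses <- distances / mm_per_pulse(profile)
  p_r <- profile$pulse_rate; a <- profile$acceleration
  t_axis <- ifelse(pulses >= p_r^2 / a,
                   pulses / p_r + p_r / a,
                   2 * sqrt(pulses / a))
  if (profile$parallel_axes) max(t_axis, 0) else sum(t_axis)
}

# coordinates of a pose list as an n x 3 matrix
pose_coords <- function(poses) {
  do.call(rbind, lapply(poses, function(p) as.numeric(p$position)))
}

#' Order camera positions with the nested zig-zag route
#'
#' The travel volume is partitioned into slabs of equal width along x, each
#' slab into columns along y. Slabs are visited in +x order. Within a slab
#' the columns are traversed serpentine in y: +y in the first slab, direction
#' alternating per slab. Within a column the positions are visited in order
#' of z, the direction alternating between consecutive non-empty columns
#' (continuing across slab boundaries), starting ascending in the first
#' column — the route begins at the bottom left near corner. Ties in z are
#' broken deterministically by (y, x) ascending.
#'
#' @param poses list of `camera_pose` (or an n x 3 coordinate matrix).
#' @param slab_width,column_width partition widths in mm (> 0).
#' @return the input, reordered; a permutation of the input.
#' @export
plan_zigzag <- function(poses, slab_width, column_width) {
  stopifnot(slab_width > 0, column_width > 0)
  n <- if (is.matrix(poses)) nrow(poses) else length(poses)
  if (n == 0) return(poses)
  xyz <- if (is.matrix(poses)) poses else pose_coords(poses)
  slab <- floor(xyz[, 1] / slab_width)
  col <- floor(xyz[, 2] / column_width)
  ord <- integer(0)
  up <- TRUE                       # z-direction of the next non-empty column
  for (s in sort(unique(slab))) {
    in_slab <- which(slab == s)
    cols <- sort(unique(col[in_slab]))
    s_rank <- match(s, sort(unique(slab))) - 1L
    if (s_rank %% 2L == 1L) cols <- rev(cols)   # serpentine in y per slab
    for (cl in cols) {
      idx <- in_slab[col[in_slab] == cl]
      o <- idx[order(xyz[idx, 3] * (if (up) 1 else -1), xyz[idx, 2], xyz[idx, 1])]
      ord <- c(ord, o)
      up <- !up
    }
  }
  if (is.matrix(poses)) poses[ord, , drop = FALSE] else poses[ord]
}

#' Route plan: ordered poses with per-leg travel times
#'
#' @param poses ordered list of `camera_pose`.
#' @param profile a `motion_profile` used for the leg times.
#' @param pause_before_trigger settle pause before the camera fires at each
#'   pose, seconds; default 3.
#' @param imaging_time camera exposure/processing time per image, seconds;
#'   default 2.7.
#' @return object of class `route_plan` with `poses`, `leg_times` (length
#'   `length(poses) - 1`), and the two per-pose time constants.
#' @export
route_plan <- function(poses, profile = motion_profile(),
                       pause_before_trigger = 3, imaging_time = 2.7) {
  stopifnot(pause_before_trigger >= 0, imaging_time >= 0)
  leg_times <- numeric(0)
  if (length(poses) >= 2) {
    xyz <- pose_coords(poses)
    leg_times <- vapply(seq_len(nrow(xyz) - 1), function(i)
      leg_time(xyz[i + 1, ] - xyz[i, ], profile), numeric(1))
  }
  structure(list(poses = poses, leg_times = leg_times,
                 pause_before_trigger = as.numeric(pause_before_trigger),
                 imaging_time = as.numeric(imaging_time)),
            class = "route_plan")
}

#' Total scheduled time of a route
#'
#' Sum of all leg travel times plus, per pose, the settle pause and the
#' imaging time. Pan/tilt motion runs in parallel with (and faster than) the
#' axis moves and is neglected.
#'
#' @param route a `route_plan`.
#' @return total seconds.
#' @export
schedule <- function(route) {
  stopifnot(inherits(route, "route_plan"))
  sum(route$leg_times) +
    length(route$poses) * (route$pause_before_trigger + route$imaging_time)
}

#' Production log of one imaging run
#'
#' @param t_p total imaging time including robotic movement, seconds.
#' @param t_d bulk download time, seconds.
#' @param t_c subimage cropping time, seconds.
#' @param n_master number of master images.
#' @param n_sub number of cropped subimages.
#' @return object of class `production_log`.
#' @export
production_log <- function(t_p, t_d = 0, t_c = 0, n_master, n_sub = 0) {
  stopifnot(t_p >= 0, t_d >= 0, t_c >= 0, n_master >= 0, n_sub >= 0,
            n_master == round(n_master), n_sub == round(n_sub))
  structure(list(t_p = as.numeric(t_p), t_d = as.numeric(t_d),
                 t_c = as.numeric(t_c),
                 n_master = as.integer(n_master), n_sub = as.integer(n_sub)),
            class = "production_log")
}

#' Average production times per master image and per subimage
#'
#' `t_m = (t_p + t_d) / N_m` and `t_s = (t_p + t_d + t_c) / N_s` seconds per
#' image: the effective rates at which the rig turns wall-clock time into
#' labeled images.
#'
#' @param log a `production_log`.
#' @return named numeric `c(t_m = , t_s = )`.
#' @export
production_rates <- function(log) {
  stopifnot(inherits(log, "production_log"))
  if (log$n_master == 0) stop("t_m undefined: no master images (N_m = 0)")
  if (log$n_sub == 0) stop("t_s undefined: no subimages (N_s = 0)")
  c(t_m = (log$t_p + log$t_d) / log$n_master,
    t_s = (log$t_p + log$t_d + log$t_c) / log$n_sub)
}
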