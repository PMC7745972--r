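#' Species table for the synthetic weed scenes
#'
#' Eight weed species common in Manitoban fields, with the common-name label,
#' the plant-id prefix (first letters of the scientific name), whether the
#' species is a monocot (grass) or dicot, and the base color used by the
#' sprite renderer.
#'
#' @return data.frame with columns `scientific_name`, `label`, `prefix`,
#'   `monocot`.
#' @export
weed_species <- function() {
  data.frame(
    scientific_name = c("Echinochloa crus-galli", "Cirsium arvense",
                        "Brassica napus", "Taraxacum officinale",
                        "Persicaria spp.", "Fallopia convolvulus",
                        "Avena fatua", "Setaria pumila"),
    label = c("BarnyardGrass", "CanadaThistle", "VolunteerCanola",
              "Dandelion", "Smartweed", "WildBuckwheat",
              "WildOat", "YellowFoxtail"),
    prefix = c("echcru", "cirarv", "branap", "taroff",
               "perspp", "falcon", "avefat", "setpum"),
    monocot = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Marked floor positions inside the travel volume
#'
#' Twelve measured-and-marked target locations on the floor: four on the
#' edge of the coverable volume (imageable from half a cylinder of poses)
#' and eight in the interior (imageable from full circles).
#'
#' @param volume travel-volume extents (length-3 mm) or a `gantry_config`.
#' @return data.frame with columns `position_id`, `x`, `y`, `z`, `class`.
#' @export
marked_positions <- function(volume = c(1150, 840, 718)) {
  if (inherits(volume, "gantry_config")) volume <- volume$volume
  sx <- volume[1] / 1150; sy <- volume[2] / 840
  edge_x <- c(175, 455, 735, 1015) * sx
  int_x <- c(240, 480, 720, 960) * sx
  data.frame(
    position_id = 1:12,
    x = c(edge_x, rep(int_x, 2)),
    y = c(rep(30 * sy, 4), rep(320 * sy, 4), rep(600 * sy, 4)),
    z = 0,
    class = c(rep("edge", 4), rep("interior", 8)),
    stringsAsFactors = FALSE
  )
}

# deterministic sprite parameters for one plant
make_sprite <- function(rng_draws) {
  # rng_draws: 6 uniform(0,1) numbers
  list(
    n_lobes = 4L + as.integer(floor(rng_draws[1] * 6)),       # 4..9 leaves
    theta0 = rng_draws[2] * 2 * pi,                           # rotation
    gap = 0.2 + 0.2 * rng_draws[3],                           # inter-leaf floor
    sharp = 0.4 + 0.8 * rng_draws[4],                         # lobe exponent
    extent_frac = 0.7 + 0.25 * rng_draws[5],                  # of sphere radius
    color = c(0.10 + 0.15 * rng_draws[6],                     # greenish base
              0.45 + 0.35 * rng_draws[6],
              0.08 + 0.10 * (1 - rng_draws[6]))
  )
}

#' Generate a random synthetic scene
#'
#' Draws `n_plants` species (with replacement) from the species table and
#' assigns them to marked floor positions sampled without replacement;
#' sprite appearance parameters are drawn deterministically from `seed`.
#' In tight-packing mode the plants are instead clustered around the volume
#' centre at a spacing close to the bounding-sphere radius, so that
#' neighbouring bounding boxes overlap in the images.
#'
#' @param n_plants number of plants; at most the number of marked positions.
#' @param seed integer master seed; the scene is a pure function of it.
#' @param species_table as from [weed_species()].
#' @param positions marked positions, as from [marked_positions()].
#' @param sphere_radius bounding-sphere radius per plant, mm; default 100 —
#'   generous for a seedling in a small pot, and small enough relative to
#'   the marked-position spacing that plants stay well separated.
#' @param background RGB triple in \[0,1\] of the keying fabric; default a
#'   saturated blue.
#' @param tight_packing logical; see above.
#' @param date_planted_start earliest planting date (`Date` or string).
#' @return object of class `scene_spec`: list with `plants` (list of
#'   plant-target lists), `background`, `floor_z`, `seed`.
#' @export
random_scene <- function(n_plants, seed = 1L,
                         species_table = weed_species(),
                         positions = marked_positions(),
                         sphere_radius = 100,
                         background = c(0.05, 0.22, 0.80),
                         tight_packing = FALSE,
                         date_planted_start = as.Date("2020-05-20")) {
  if (!tight_packing && n_plants > nrow(positions))
    stop(sprintf("n_plants (%d) exceeds the %d marked positions", n_plants, nrow(positions)))
  stopifnot(n_plants >= 0, sphere_radius > 0, length(background) == 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  if (tight_packing) {
    # cluster around the volume centre at ~1.4 R spacing: boxes overlap
    spacing <- 1.4 * sphere_radius
    ncol_ <- ceiling(sqrt(max(n_plants, 1)))
    idx <- seq_len(n_plants) - 1L
    pos <- data.frame(
      position_id = 100L + seq_len(n_plants),
      x = 575 + ((idx %% ncol_) - (ncol_ - 1) / 2) * spacing,
      y = 420 + ((idx %/% ncol_) - (ncol_ - 1) / 2) * spacing,
      z = 0, class = "interior", stringsAsFactors = FALSE)
  } else {
    pos <- positions[sample.int(nrow(positions), n_plants), , drop = FALSE]
  }
  sp_idx <- if (n_plants > 0) sample.int(nrow(species_table), n_plants, replace = TRUE) else integer(0)
  counter <- integer(nrow(species_table))
  plants <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    si <- sp_idx[i]
    counter[si] <- counter[si] + 1L
    sprite <- make_sprite(stats::runif(6))
    plants[[i]] <- list(
      plant_id = sprintf("%s%03d", species_table$prefix[si], counter[si]),
      label = species_table$label[si],
      scientific_name = species_table$scientific_name[si],
      position_id = pos$position_id[i],
      position_class = pos$class[i],
      position = world_point(pos$x[i], pos$y[i], pos$z[i]),
      sphere_radius = sphere_radius,
      date_planted = format(as.Date(date_planted_start) + sample.int(10, 1) - 1L),
      sprite = sprite
    )
  }
  structure(list(plants = plants, background = as.numeric(background),
                 floor_z = 0, seed = as.integer(seed)),
            class = "scene_spec")
}

# lobed rosette footprint: radius of the sprite outline at polar angle theta,
# as a fraction of its maximal extent (max over theta is exactly 1)
sprite_outline <- function(theta, sprite) {
  sprite$gap + (1 - sprite$gap) *
    abs(cos(sprite$n_lobes * (theta - sprite$theta0) / 2))^sprite$sharp
}

#' Render a master image of a scene through the virtual camera
#'
#' Pure-geometry renderer: each pixel-centre ray is back-projected onto the
#' floor plane; a pixel belongs to a plant when the intersection lies inside
#' that plant's lobed-rosette footprint (a flat sprite contained strictly
#' within its bounding sphere). Overlapping footprints are resolved to the
#' nearest plant centre, so per-plant ground-truth masks are disjoint. All
#' other pixels show the uniform keying background (the fabric also covers
#' the floor).
#'
#' @param scene a `scene_spec`.
#' @param pose a `camera_pose`.
#' @param model a `camera_model` (use a down-scaled resolution for tests).
#' @return list with `image` (numeric array width x height x 3, values in
#'   \[0,1\]), `label` (integer width x height matrix, 0 = background, i =
#'   index of `scene$plants`), and `masks` (named list of logical matrices,
#'   one per plant, named by `plant_id`).
#' @export
render_master <- function(scene, pose, model) {
  stopifnot(inherits(scene, "scene_spec"), inherits(pose, "camera_pose"),
            inherits(model, "camera_model"))
  W <- model$width; H <- model$height
  f <- model$focal_px
  u <- (seq_len(W) - 0.5) / W
  v <- (seq_len(H) - 0.5) / H
  Y <- matrix((0.5 - u) * W / f, W, H)               # y_f/x_f per pixel
  Z <- matrix((0.5 - v) * H / f, W, H, byrow = TRUE) # z_f/x_f per pixel
  R <- rotation_w2c(pose)
  fwd <- R[1, ]; left <- R[2, ]; up <- R[3, ]
  dwx <- fwd[1] + left[1] * Y + up[1] * Z
  dwy <- fwd[2] + left[2] * Y + up[2] * Z
  dwz <- fwd[3] + left[3] * Y + up[3] * Z
  cam <- as.numeric(pose$position)
  tt <- (scene$floor_z - cam[3]) / dwz
  valid <- is.finite(tt) & (tt > 0)
  gx <- cam[1] + tt * dwx
  gy <- cam[2] + tt * dwy

  img <- array(rep(scene$background, each = W * H), dim = c(W, H, 3))
  label <- matrix(0L, W, H)
  bestd <- matrix(Inf, W, H)
  shade <- matrix(0, W, H)
  for (i in seq_along(scene$plants)) {
    pl <- scene$plants[[i]]
    ppos <- as.numeric(pl$position)
    rmax <- 0.95 * pl$sphere_radius * pl$sprite$extent_frac
    dx <- gx - ppos[1]; dy <- gy - ppos[2]
    r2 <- dx * dx + dy * dy
    cand <- which(valid & (r2 <= rmax^2))
    if (length(cand) == 0) next
    theta <- atan2(dy[cand], dx[cand])
    rsh <- rmax * sprite_outline(theta, pl$sprite)
    inside <- sqrt(r2[cand]) <= rsh
    hit <- cand[inside]
    closer <- r2[hit] < bestd[hit]
    hit <- hit[closer]
    if (length(hit) == 0) next
    label[hit] <- i
    bestd[hit] <- r2[hit]
    shade[hit] <- 0.55 + 0.45 * (1 - sqrt(r2[hit]) / (rsh[inside][closer]))^0.7
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    for (i in seq_along(scene$plants)) {
      sel <- label == i
      plane[sel] <- scene$plants[[i]]$sprite$color[ch] * shade[sel]
    }
    img[, , ch] <- plane
  }
  masks <- lapply(seq_along(scene$plants), function(i) label == i)
  names(masks) <- vapply(scene$plants, `[[`, character(1), "plant_id")
  list(image = img, label = label, masks = masks)
}

#' Render the background-only companion image
#'
#' The same capture with every plant removed: pixel-identical background to
#' [render_master()], for use with [background_subtract()].
#'
#' @inheritParams render_master
#' @return numeric array width x height x 3.
#' @export
render_background_only <- function(scene, pose, model) {
  empty <- scene
  empty$plants <- list()
  render_master(empty, pose, model)$image
}

#' Write a scene specification to JSON (and read it back)
#' @param scene a `scene_spec`.
#' @param path file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  ser <- scene
  ser$plants <- lapply(scene$plants, function(pl) {
    pl$position <- as.list(as.numeric(pl$position))
    names(pl$position) <- c("x", "y", "z")
    pl
  })
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$plants <- lapply(x$plants, function(pl) {
    pl$position <- world_point(pl$position$x, pl$position$y, pl$position$z)
    pl$sprite <- lapply(pl$sprite, function(z) if (is.list(z)) unlist(z) else z)
    pl
  })
  x$background <- unlist(x$background)
  structure(x, class = "scene_spec")
}
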