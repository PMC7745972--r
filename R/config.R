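#' Gantry and camera rig configuration
#'
#' Bundles the physical constants of the rig: the cuboid travel volume the
#' camera's optical center can reach, the camera resolution and field of view,
#' the displacement between the gantry-head attachment point and the optical
#' center, and the margin-exclusion fraction used to reject bounding boxes
#' that touch the outer image margin (where lens distortion would be worst on
#' a physical lens).
#'
#' @param volume numeric length-3, travel volume extents in mm (x, y, z).
#'   Default `c(1150, 840, 718)`.
#' @param width,height camera resolution in pixels. Default 4000 x 3000.
#' @param fov_diagonal diagonal field of view in degrees. Default 98.7.
#' @param head_offset numeric length-3, displacement (mm) from gantry-head
#'   attachment to optical center. Default zero.
#' @param margin_exclusion fraction of image width/height near the border
#'   inside which boxes are rejected; 0 disables. Default 0.03: subimages
#'   whose boxes graze the outer margin are the least reliable (on a
#'   physical lens they also sit where distortion is worst) and are dropped.
#' @return an object of class `gantry_config`.
#' @export
gantry_config <- function(volume = c(1150, 840, 718),
                          width = 4000L, height = 3000L,
                          fov_diagonal = 98.7,
                          head_offset = c(0, 0, 0),
                          margin_exclusion = 0.03) {
  stopifnot(length(volume) == 3, all(is.finite(volume)), all(volume > 0),
            length(head_offset) == 3, all(is.finite(head_offset)),
            margin_exclusion >= 0, margin_exclusion < 0.5)
  structure(list(
    volume = as.numeric(volume),
    model = camera_model(width = width, height = height,
                         fov_diagonal = fov_diagonal),
    head_offset = as.numeric(head_offset),
    margin_exclusion = as.numeric(margin_exclusion)
  ), class = "gantry_config")
}

#' Read / write a rig configuration as JSON
#'
#' @param path file path.
#' @return `read_gantry_config` returns a `gantry_config`.
#' @export
read_gantry_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gantry_config(volume = x$volume,
                width = x$width, height = x$height,
                fov_diagonal = x$fov_diagonal,
                head_offset = if (is.null(x$head_offset)) c(0, 0, 0) else x$head_offset,
                margin_exclusion = if (is.null(x$margin_exclusion)) 0 else x$margin_exclusion)
}

#' @rdname read_gantry_config
#' @param config a `gantry_config`.
#' @export
write_gantry_config <- function(config, path) {
  stopifnot(inherits(config, "gantry_config"))
  jsonlite::write_json(list(
    volume = config$volume,
    width = config$model$width, height = config$model$height,
    fov_diagonal = config$model$fov_diagonal,
    head_offset = config$head_offset,
    margin_exclusion = config$margin_exclusion
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.gantry_config <- function(x, ...) {
  cat(sprintf("gantry_config: volume %g x %g x %g mm, %d x %d px, dFOV %g deg\n",
              x$volume[1], x$volume[2], x$volume[3],
              x$model$width, x$model$height, x$model$fov_diagonal))
  invisible(x)
}
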