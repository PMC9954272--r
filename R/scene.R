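#' Paradigm scene configuration
#'
#' A `scene_config` bundles the geometry and acquisition constants of the
#' two-minute spatial execution paradigm: the screen rectangle, the sphere
#' start position, the four target cubes (top/bottom/left/right), the
#' transverse (horizontal) obstacle, the 120 s evaluation cap and the 60 Hz
#' sampling rate.  Every other module (trajectory logs, biomarker
#' extraction, the trial simulator) consumes a validated scene.
#'
#' Coordinates use a bottom-left origin with x rightward and y upward, so
#' "above the obstacle" always means `y > obstacle_y_px`.  All distances are
#' in screen pixels and all times in seconds, the units in which the
#' biomarkers are reported.
#'
#' @param screen_width_px,screen_height_px Screen size in pixels.  The
#'   default matches a 2560 x 1600 tablet display.
#' @param sphere_start Numeric length-2, sphere centre start position (px).
#' @param sphere_radius_px Sphere radius (px).
#' @param cube_centers Named list with entries `top`, `bottom`, `left`,
#'   `right`, each a numeric length-2 centre position (px).
#' @param cube_half_size_px Half the side length of a target cube (px).
#' @param obstacle_y_px y-coordinate of the obstacle midline (px).
#' @param obstacle_x_min_px,obstacle_x_max_px Horizontal extent of the
#'   obstacle (px).
#' @param obstacle_thickness_px Obstacle thickness (px).
#' @param T_max_s Maximum evaluation time in seconds (120).
#' @param sample_rate_hz Position sampling rate in Hz (60).
#' @return An object of class `scene_config` (a validated named list) with
#'   the derived field `count_max = T_max_s * sample_rate_hz`, the maximum
#'   cumulative number of samples in one trial.
#' @examples
#' sc <- default_scene()
#' sc$count_max   # 7200 samples at 60 Hz over 120 s
#' @export
scene_config <- function(screen_width_px = 2560, screen_height_px = 1600,
                         sphere_start = c(1280, 500), sphere_radius_px = 40,
                         cube_centers = list(top = c(1280, 1250),
                                             bottom = c(1280, 150),
                                             left = c(480, 500),
                                             right = c(2080, 500)),
                         cube_half_size_px = 50,
                         obstacle_y_px = 850,
                         obstacle_x_min_px = 880, obstacle_x_max_px = 1680,
                         obstacle_thickness_px = 20,
                         T_max_s = 120, sample_rate_hz = 60) {
  cfg <- structure(list(
    screen_width_px = screen_width_px, screen_height_px = screen_height_px,
    sphere_start = as.numeric(sphere_start),
    sphere_radius_px = sphere_radius_px,
    cube_centers = lapply(cube_centers, as.numeric),
    cube_half_size_px = cube_half_size_px,
    obstacle_y_px = obstacle_y_px,
    obstacle_x_min_px = obstacle_x_min_px,
    obstacle_x_max_px = obstacle_x_max_px,
    obstacle_thickness_px = obstacle_thickness_px,
    T_max_s = T_max_s, sample_rate_hz = sample_rate_hz,
    count_max = T_max_s * sample_rate_hz
  ), class = "scene_config")
  validate_scene(cfg)
}

#' Default paradigm scene
#'
#' The packaged default geometry: 2560 x 1600 px screen, sphere starting
#' below a transverse obstacle at y = 850 px, cubes in the four cardinal
#' directions with the top cube above the obstacle.  Only the screen
#' resolution, the 120 s cap and the 60 Hz rate are fixed by the paradigm;
#' the remaining coordinates are configurable package defaults.
#'
#' @return A validated `scene_config`.
#' @export
default_scene <- function() scene_config()

#' Validate a scene configuration
#'
#' Checks every structural invariant of the paradigm geometry and fails on
#' the first violation, naming it.  Validation is idempotent and never
#' modifies a valid scene.
#'
#' Invariants: `count_max = T_max_s * sample_rate_hz` is a positive whole
#' number; the four cube centres are pairwise distinct and inside the screen
#' rectangle; the top cube lies strictly above the obstacle midline and the
#' sphere start strictly below it (so finishing the task requires a
#' crossing); radii, sizes and the obstacle extent are positive/ordered.
#'
#' @param cfg A `scene_config` or a plain named list with the same fields.
#' @return `cfg`, classed and unchanged, if all invariants hold.
#' @export
validate_scene <- function(cfg) {
  req <- c("screen_width_px", "screen_height_px", "sphere_start",
           "sphere_radius_px", "cube_centers", "cube_half_size_px",
           "obstacle_y_px", "obstacle_x_min_px", "obstacle_x_max_px",
           "obstacle_thickness_px", "T_max_s", "sample_rate_hz")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("scene invalid (missing-field): ", paste(missing, collapse = ", "))
  cm <- cfg$T_max_s * cfg$sample_rate_hz
  if (!is.finite(cm) || cm <= 0 || abs(cm - round(cm)) > 1e-9)
    stop("scene invalid (count-max): T_max_s * sample_rate_hz must be a positive integer")
  cfg$count_max <- round(cm)
  cubes <- cfg$cube_centers
  need <- c("top", "bottom", "left", "right")
  if (!all(need %in% names(cubes)))
    stop("scene invalid (cube-set): cube_centers needs top, bottom, left, right")
  pos <- do.call(rbind, cubes[need])
  if (anyDuplicated(pos))
    stop("scene invalid (cube-distinct): cube centers must be pairwise distinct")
  inside <- pos[, 1] > 0 & pos[, 1] < cfg$screen_width_px &
            pos[, 2] > 0 & pos[, 2] < cfg$screen_height_px
  if (!all(inside))
    stop("scene invalid (cube-on-screen): cube '", need[which(!inside)[1]],
         "' outside the screen rectangle")
  if (!(cubes$top[2] > cfg$obstacle_y_px))
    stop("scene invalid (crossing-impossible): top cube must lie strictly above the obstacle")
  if (!(cfg$sphere_start[2] < cfg$obstacle_y_px))
    stop("scene invalid (crossing-impossible): sphere start must lie strictly below the obstacle")
  if (!(cfg$sphere_radius_px > 0))
    stop("scene invalid (sphere-radius): sphere_radius_px must be > 0")
  if (!(cfg$cube_half_size_px > 0))
    stop("scene invalid (cube-size): cube_half_size_px must be > 0")
  if (!(cfg$obstacle_x_min_px < cfg$obstacle_x_max_px))
    stop("scene invalid (obstacle-extent): obstacle_x_min_px must be < obstacle_x_max_px")
  if (!(cfg$obstacle_thickness_px > 0))
    stop("scene invalid (obstacle-thickness): obstacle_thickness_px must be > 0")
  class(cfg) <- "scene_config"
  cfg
}

#' Read a scene from a JSON or YAML config file
#'
#' The file holds either the scene fields at top level or under a `scene`
#' key.  Format is chosen by extension (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the config file.
#' @return A validated `scene_config`.
#' @export
read_scene <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML scenes requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$scene)) raw <- raw$scene
  raw$count_max <- NULL
  validate_scene(raw)
}

#' Write a scene to a JSON config file
#'
#' @param cfg A validated `scene_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(cfg, path) {
  cfg <- validate_scene(cfg)
  jsonlite::write_json(list(scene = unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d x %d px, %g s @ %g Hz (count_max = %d)\n",
              x$screen_width_px, x$screen_height_px, x$T_max_s,
              x$sample_rate_hz, x$count_max))
  cat(sprintf("  sphere start (%g, %g) r=%g; obstacle y=%g x=[%g, %g]\n",
              x$sphere_start[1], x$sphere_start[2], x$sphere_radius_px,
              x$obstacle_y_px, x$obstacle_x_min_px, x$obstacle_x_max_px))
  invisible(x)
}
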