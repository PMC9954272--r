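#' Euclidean distance between two adjacent sample positions
#'
#' The elementary distance primitive of the paradigm: the distance the
#' sphere moved between two adjacent sampling points,
#' `d = sqrt((x2-x1)^2 + (y2-y1)^2)` in pixels.  All distance biomarkers
#' are sums of these per-step distances.
#'
#' @param p,q Numeric length-2 positions (px).
#' @return Distance in px.
#' @examples
#' step_distance(c(0, 0), c(3, 4))  # 5
#' @export
step_distance <- function(p, q) {
  sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
}

# per-step distances d_i for steps (i, i+1), i = 0 .. n-2 (vectorised)
step_distances <- function(samples) {
  dx <- diff(samples$x)
  dy <- diff(samples$y)
  sqrt(dx * dx + dy * dy)
}

#' Total mission execution time rate (METRtotal)
#'
#' Ratio of the total execution time Te to the maximum evaluation time of
#' the paradigm: `METRtotal = Te / T_max_s`, dimensionless in (0, 1].  An
#' incomplete trial scores exactly 1.
#'
#' @param log A validated `trajectory_log`.
#' @return METRtotal.
#' @export
metr_total <- function(log) {
  compute_te(log) / log$scene$T_max_s
}

#' Total mission execution distance (MEDtotal)
#'
#' Total distance over which the participant moved the sphere during the
#' paradigm: the sum of adjacent-sample distances over all steps up to the
#' sample at which Te stops (post-completion drift, if logged, is
#' excluded).
#'
#' @param log A validated `trajectory_log`.
#' @return MEDtotal in px.
#' @export
med_total <- function(log) {
  ti <- te_index(log)
  if (ti < 1L) return(0)
  sum(step_distances(log$samples[log$samples$i <= ti, ]))
}

#' Mission execution time of the first task (METfirst)
#'
#' Time taken to eliminate the first target cube: the time of the first
#' elimination event.  Missing (`NA`) when no cube was ever eliminated.
#'
#' @param log A validated `trajectory_log`.
#' @return METfirst in seconds, or `NA_real_`.
#' @export
met_first <- function(log) {
  if (nrow(log$events) < 1L) return(NA_real_)
  log$events$t_s[1]
}

#' Mission execution efficiency of the first task (MEEfirst)
#'
#' Ratio of the distance actually travelled before the first elimination to
#' the shortest possible start-to-cube distance.  The denominator is
#' contact-adjusted: the centre-to-centre distance from the sphere start to
#' the first-eliminated cube minus `sphere_radius_px + cube_half_size_px`,
#' so a perfectly straight approach that stops at contact scores exactly 1.
#'
#' @param log A validated `trajectory_log`.
#' @param scene Scene to take geometry from; defaults to the log's scene.
#' @return MEEfirst (dimensionless, >= ~1 in practice), or `NA_real_` when
#'   no cube was eliminated.
#' @export
mee_first <- function(log, scene = log$scene) {
  if (nrow(log$events) < 1L) return(NA_real_)
  first <- log$events[1, ]
  cube <- scene$cube_centers[[first$cube_id]]
  D <- step_distance(scene$sphere_start, cube) -
    (scene$sphere_radius_px + scene$cube_half_size_px)
  if (D <= 0) stop("degenerate geometry: start-to-cube contact distance is not positive")
  fi <- first$sample_index
  num <- if (fi < 1L) 0 else sum(step_distances(log$samples[log$samples$i <= fi, ]))
  num / D
}

#' Detect the first upward crossing of the transverse obstacle
#'
#' Scans the sphere centre's y-coordinate for the first step (i, i+1), at
#' or before the sample where Te stops, with `y_i <= obstacle_y_px <
#' y_{i+1}`: the step during which the sphere first rises past the obstacle
#' midline.  Only the y-coordinate is tested (the discriminant of crossing
#' is one-dimensional); later dips below the midline do not reset the
#' crossing.
#'
#' @param log A validated `trajectory_log`.
#' @param scene Scene providing `obstacle_y_px`; defaults to the log's.
#' @return A list with `crossing_t_s` (= t of sample i+1, the first sample
#'   above) and `crossing_index` (= i, the last sample at or below), or
#'   `NULL` when the sphere never crossed.
#' @export
detect_crossing <- function(log, scene = log$scene) {
  ti <- te_index(log)
  y <- log$samples$y[log$samples$i <= ti]
  n <- length(y)
  if (n < 2L) return(NULL)
  up <- which(y[-n] <= scene$obstacle_y_px & y[-1] > scene$obstacle_y_px)
  if (!length(up)) return(NULL)
  i <- up[1] - 1L                      # sample index (0-based) of the last at-or-below sample
  list(crossing_t_s = (i + 1L) / scene$sample_rate_hz, crossing_index = i)
}

#' Post-crossing execution time and distance (ETcrossing, EDcrossing)
#'
#' ETcrossing is the time the participant spent completing the remaining
#' tasks after first crossing the obstacle, `Te - Tcrossing`; EDcrossing
#' is the distance covered during that time (the sum of step distances from
#' the first above-midline sample to the Te sample).  Both are missing when
#' the sphere never crossed.
#'
#' @param log A validated `trajectory_log`.
#' @param scene Scene; defaults to the log's.
#' @return A list `(et_crossing_s, ed_crossing_px, crossing_t_s)`; all
#'   `NA_real_` if no crossing exists.
#' @export
crossing_metrics <- function(log, scene = log$scene) {
  cr <- detect_crossing(log, scene)
  if (is.null(cr))
    return(list(et_crossing_s = NA_real_, ed_crossing_px = NA_real_,
                crossing_t_s = NA_real_))
  te <- compute_te(log)
  ti <- te_index(log)
  first_above <- cr$crossing_index + 1L
  ed <- if (first_above >= ti) 0 else {
    s <- log$samples[log$samples$i >= first_above & log$samples$i <= ti, ]
    sum(step_distances(s))
  }
  list(et_crossing_s = te - cr$crossing_t_s, ed_crossing_px = ed,
       crossing_t_s = cr$crossing_t_s)
}

#' Above-obstacle execution time and distance (ETabove, EDabove)
#'
#' ETabove is the total time the sphere spent above the obstacle midline
#' while executing the task; EDabove is the distance it covered while
#' there.  Both count whole inter-sample steps whose two endpoints are both
#' strictly above `obstacle_y_px` (and at or before the Te sample): time as
#' steps / sample_rate, distance as the summed step distances.  No
#' sub-sample interpolation is performed at the boundary; at 60 Hz the
#' convention bounds the discretisation error by one step.  A trial that
#' never rises above the midline scores (0, 0).
#'
#' @param log A validated `trajectory_log`.
#' @param scene Scene; defaults to the log's.
#' @return A list `(et_above_s, ed_above_px)`.
#' @export
above_metrics <- function(log, scene = log$scene) {
  ti <- te_index(log)
  s <- log$samples[log$samples$i <= ti, ]
  n <- nrow(s)
  if (n < 2L) return(list(et_above_s = 0, ed_above_px = 0))
  ab <- s$y > scene$obstacle_y_px
  both <- ab[-n] & ab[-1]
  d <- step_distances(s)
  list(et_above_s = sum(both) / scene$sample_rate_hz,
       ed_above_px = sum(d[both]))
}

#' Extract the eight SEP digital biomarkers from one trial
#'
#' Computes the complete biomarker vector of the two-minute spatial
#' execution paradigm from a single trajectory log: four time-domain
#' markers (METRtotal, METfirst, ETcrossing, ETabove) and four
#' distance-domain markers (MEDtotal, MEEfirst, EDcrossing, EDabove), plus
#' the crossing time and the completion flag.  Markers whose defining event
#' never occurred (no elimination, no crossing) are returned as `NA`, never
#' zero, so batch extraction degrades gracefully.
#'
#' @param log A validated `trajectory_log`.
#' @param scene Scene; defaults to the log's.
#' @return An object of class `biomarker_vector`: a named list with fields
#'   `metr_total`, `met_first_s`, `et_crossing_s`, `et_above_s`,
#'   `med_total_px`, `mee_first`, `ed_crossing_px`, `ed_above_px`,
#'   `crossing_t_s`, `complete`.
#' @export
extract_biomarkers <- function(log, scene = log$scene) {
  cr <- crossing_metrics(log, scene)
  ab <- above_metrics(log, scene)
  structure(list(
    metr_total = metr_total(log),
    met_first_s = met_first(log),
    et_crossing_s = cr$et_crossing_s,
    et_above_s = ab$et_above_s,
    med_total_px = med_total(log),
    mee_first = mee_first(log, scene),
    ed_crossing_px = cr$ed_crossing_px,
    ed_above_px = ab$ed_above_px,
    crossing_t_s = cr$crossing_t_s,
    complete = log$complete
  ), class = "biomarker_vector")
}

#' @export
print.biomarker_vector <- function(x, ...) {
  cat("<biomarker_vector>\n")
  for (f in names(x)) cat(sprintf("  %-14s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Batch biomarker extraction over a set of logs
#'
#' Extracts the biomarker vector of every log and stacks the results into
#' one data frame row per trial, matching the layout consumed by
#' [sep_analyze()].  Extraction failures in individual logs are converted
#' to all-`NA` rows with a warning rather than aborting the batch.
#'
#' @param logs A list of `trajectory_log` objects, or a character vector of
#'   JSONL file paths (read with [read_trajectory_log()]).
#' @param scene Optional scene overriding each log's own.
#' @return A data frame with columns `participant_id`, the eight
#'   biomarkers, `crossing_t_s` and `complete`.
#' @export
extract_cohort <- function(logs, scene = NULL) {
  if (is.character(logs)) logs <- lapply(logs, read_trajectory_log, scene = scene)
  rows <- lapply(logs, function(lg) {
    bm <- tryCatch(extract_biomarkers(lg, if (is.null(scene)) lg$scene else scene),
                   error = function(e) {
                     warning("extraction failed for '", lg$participant_id,
                             "': ", conditionMessage(e))
                     structure(as.list(rep(NA_real_, 9)),
                               names = c("metr_total", "met_first_s",
                                         "et_crossing_s", "et_above_s",
                                         "med_total_px", "mee_first",
                                         "ed_crossing_px", "ed_above_px",
                                         "crossing_t_s"))
                   })
    data.frame(participant_id = lg$participant_id,
               metr_total = bm$metr_total, met_first_s = bm$met_first_s,
               et_crossing_s = bm$et_crossing_s, et_above_s = bm$et_above_s,
               med_total_px = bm$med_total_px, mee_first = bm$mee_first,
               ed_crossing_px = bm$ed_crossing_px, ed_above_px = bm$ed_above_px,
               crossing_t_s = bm$crossing_t_s,
               complete = isTRUE(bm$complete) || isTRUE(lg$complete))
  })
  do.call(rbind, rows)
}
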