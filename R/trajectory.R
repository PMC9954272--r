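#' Construct a per-trial trajectory log
#'
#' A trajectory log is the raw record of one evaluation trial: the sphere
#' centre position sampled at the scene's rate (nominally 60 Hz, at most
#' `count_max` samples) together with the cube-elimination events in the
#' order they occurred.  Sample times are derived, never stored: the i-th
#' sample is at `t = i / sample_rate_hz` seconds, counting from i = 0.
#'
#' @param participant_id Opaque participant/trial identifier string.
#' @param scene A validated [scene_config()].
#' @param samples Data frame (or matrix) with columns `x`, `y`: sphere
#'   centre positions for contiguous sample indices 0, 1, 2, ...
#' @param events Data frame with columns `cube_id` (one of top/bottom/
#'   left/right) and `sample_index`; 0 to 4 rows in elimination order.
#' @return A validated object of class `trajectory_log` with fields
#'   `participant_id`, `scene`, `samples` (data frame `i`, `x`, `y`),
#'   `events` (data frame `cube_id`, `sample_index`, `t_s`) and `complete`
#'   (TRUE iff all four cubes were eliminated).
#' @export
trajectory_log <- function(participant_id, scene, samples,
                           events = data.frame(cube_id = character(),
                                               sample_index = integer())) {
  scene <- validate_scene(scene)
  samples <- as.data.frame(samples)
  if (!all(c("x", "y") %in% names(samples)))
    stop("samples must have columns x and y")
  samples <- data.frame(i = seq_len(nrow(samples)) - 1L,
                        x = as.numeric(samples$x), y = as.numeric(samples$y))
  events <- as.data.frame(events)
  if (nrow(events) && !all(c("cube_id", "sample_index") %in% names(events)))
    stop("events must have columns cube_id and sample_index")
  events <- data.frame(cube_id = as.character(events$cube_id),
                       sample_index = as.integer(events$sample_index))
  events$t_s <- events$sample_index / scene$sample_rate_hz
  log <- structure(list(participant_id = as.character(participant_id),
                        scene = scene, samples = samples, events = events,
                        complete = nrow(events) == 4L),
                   class = "trajectory_log")
  validate_trajectory_log(log)
}

#' Validate a trajectory log
#'
#' Invariants: samples are contiguous from index 0 with the last sample's
#' time at most `T_max_s` (and fewer than `count_max` samples); every
#' event's `sample_index` falls inside the sampled range; no cube is
#' eliminated twice; event times are strictly increasing; `complete` holds
#' exactly when four events are present.
#'
#' @param log A `trajectory_log`.
#' @return `log` unchanged if valid; otherwise an error naming the first
#'   violated invariant.
#' @export
validate_trajectory_log <- function(log) {
  s <- log$samples
  if (nrow(s) < 1L) stop("log invalid (empty): at least one sample required")
  if (!identical(as.integer(s$i), seq_len(nrow(s)) - 1L))
    stop("log invalid (non-contiguous samples): indices must run 0,1,2,...")
  if (nrow(s) > log$scene$count_max)
    stop("log invalid (overrun): more than count_max samples")
  if ((nrow(s) - 1L) / log$scene$sample_rate_hz > log$scene$T_max_s + 1e-9)
    stop("log invalid (overrun): last sample time exceeds T_max_s")
  ev <- log$events
  if (nrow(ev)) {
    if (!all(ev$cube_id %in% c("top", "bottom", "left", "right")))
      stop("log invalid (unknown-cube): event cube_id not one of top/bottom/left/right")
    if (anyDuplicated(ev$cube_id))
      stop("log invalid (duplicate elimination): a cube was eliminated twice")
    if (any(ev$sample_index < 0L | ev$sample_index > max(s$i)))
      stop("log invalid (event-out-of-range): event sample_index beyond the samples")
    if (nrow(ev) > 1L && any(diff(ev$t_s) <= 0))
      stop("log invalid (event-order): event times must be strictly increasing")
  }
  if (!identical(log$complete, nrow(ev) == 4L))
    stop("log invalid (complete-flag): complete must equal (number of events == 4)")
  log
}

fmt_num <- function(x) {
  # shortest decimal text that round-trips a double bit-exactly
  out <- vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
  out
}

#' Write a trajectory log as JSON Lines
#'
#' Serialises a validated log into the package's JSONL dialect: line 1 is a
#' header object `{participant_id, scene, sample_rate_hz}`; each subsequent
#' line is either a sample `{"i":, "x":, "y":}` or an inline elimination
#' event `{"event": cube_id, "i": sample_index}` placed immediately after
#' the sample at which it occurred.  Coordinates are written with enough
#' decimal digits to round-trip bit-exactly, so
#' `read_trajectory_log(write_trajectory_log(log))` is the identity on the
#' data model.
#'
#' @param log A validated `trajectory_log`.
#' @param path Output file path (or a writable connection).
#' @return `path`, invisibly.
#' @export
write_trajectory_log <- function(log, path) {
  log <- validate_trajectory_log(log)
  header <- jsonlite::toJSON(list(participant_id = log$participant_id,
                                  scene = unclass(log$scene),
                                  sample_rate_hz = log$scene$sample_rate_hz),
                             auto_unbox = TRUE, digits = NA)
  s <- log$samples
  lines <- sprintf('{"i":%d,"x":%s,"y":%s}', s$i, fmt_num(s$x), fmt_num(s$y))
  ev <- log$events
  if (nrow(ev)) {
    evl <- sprintf('{"event":"%s","i":%d}', ev$cube_id, ev$sample_index)
    # interleave: event line goes right after its sample line
    ord <- order(c(s$i, ev$sample_index + 0.5))
    lines <- c(lines, evl)[ord]
  }
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' Read a trajectory log from JSON Lines
#'
#' Parses the dialect written by [write_trajectory_log()] and returns a
#' validated `trajectory_log`.  Unknown keys on any line are ignored with a
#' warning; malformed lines, a missing header, duplicate cube events and
#' non-contiguous sample indices are errors reported with their line
#' number.
#'
#' @param path Path to a JSONL log file.
#' @param scene Optional `scene_config` overriding the scene embedded in
#'   the header (used when logs were written against a shared scene file).
#' @return A validated `trajectory_log`.
#' @export
read_trajectory_log <- function(path, scene = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("log read error: empty file, missing header")
  header <- tryCatch(jsonlite::fromJSON(lines[[1]], simplifyVector = TRUE),
                     error = function(e) stop("log read error at line 1: malformed header"))
  if (is.null(header$participant_id))
    stop("log read error: missing header (no participant_id on line 1)")
  if (is.null(scene)) {
    if (is.null(header$scene))
      stop("log read error: header carries no scene and none was supplied")
    sc <- header$scene
    sc$cube_centers <- lapply(sc$cube_centers, as.numeric)
    sc$count_max <- NULL
    scene <- validate_scene(sc)
  }
  known_sample <- c("i", "x", "y")
  known_event <- c("event", "i")
  n <- length(lines) - 1L
  body <- lines[-1]
  xi <- integer(n); xx <- numeric(n); xy <- numeric(n); is_sample <- logical(n)
  ev_cube <- rep(NA_character_, n); ev_i <- rep(NA_integer_, n)
  unknown <- character(0)
  # vectorised fast path for the two canonical line shapes; anything else
  # falls back to a full JSON parse below
  num <- "(-?[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?)"
  s_pat <- paste0('^\\{"i":([0-9]+),"x":', num, ',"y":', num, "\\}$")
  e_pat <- '^\\{"event":"(top|bottom|left|right)","i":([0-9]+)\\}$'
  sm <- grepl(s_pat, body)
  em <- !sm & grepl(e_pat, body)
  if (any(sm)) {
    is_sample[sm] <- TRUE
    xi[sm] <- as.integer(sub(s_pat, "\\1", body[sm]))
    xx[sm] <- as.numeric(sub(s_pat, "\\2", body[sm]))
    xy[sm] <- as.numeric(sub(s_pat, "\\3", body[sm]))
  }
  if (any(em)) {
    ev_cube[em] <- sub(e_pat, "\\1", body[em])
    ev_i[em] <- as.integer(sub(e_pat, "\\2", body[em]))
  }
  for (k in which(!sm & !em)) {
    rec <- tryCatch(jsonlite::fromJSON(body[[k]], simplifyVector = TRUE),
                    error = function(e)
                      stop("log read error at line ", k + 1L, ": malformed JSON"))
    if (!is.null(rec$event)) {
      unknown <- c(unknown, setdiff(names(rec), known_event))
      ev_cube[k] <- rec$event
      ev_i[k] <- as.integer(rec$i)
    } else if (!is.null(rec$i)) {
      unknown <- c(unknown, setdiff(names(rec), known_sample))
      is_sample[k] <- TRUE
      xi[k] <- as.integer(rec$i); xx[k] <- as.numeric(rec$x); xy[k] <- as.numeric(rec$y)
    } else {
      stop("log read error at line ", k + 1L, ": neither sample nor event")
    }
  }
  keep_ev <- !is.na(ev_cube)
  ev_cube <- ev_cube[keep_ev]; ev_i <- ev_i[keep_ev]
  if (length(unknown))
    warning("ignoring unknown log keys: ", paste(unique(unknown), collapse = ", "))
  idx <- xi[is_sample]
  if (!identical(idx, seq_along(idx) - 1L))
    stop("log read error (non-contiguous samples): sample indices must run 0,1,2,...")
  if (anyDuplicated(ev_cube))
    stop("log read error (duplicate elimination): cube '",
         ev_cube[duplicated(ev_cube)][1], "' eliminated twice")
  trajectory_log(header$participant_id, scene,
                 data.frame(x = xx[is_sample], y = xy[is_sample]),
                 data.frame(cube_id = ev_cube, sample_index = ev_i))
}

#' Total task execution time Te
#'
#' Te is the total time a participant spent executing the paradigm: the
#' time of the fourth (final) cube elimination for a completed trial.  A
#' trial that did not finish within the cap is assigned `Te = T_max_s`
#' (the paradigm stops there); biomarkers that require missing events are
#' reported as missing downstream, never zero.
#'
#' @param log A validated `trajectory_log`.
#' @return Te in seconds, in `(0, T_max_s]`.
#' @export
compute_te <- function(log) {
  if (log$complete) log$events$t_s[4] else log$scene$T_max_s
}

# sample index at which the Te clock stops (end of usable trajectory)
te_index <- function(log) {
  if (log$complete) log$events$sample_index[4] else max(log$samples$i)
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat(sprintf("<trajectory_log> %s: %d samples @ %g Hz, %d event(s), %s (Te = %.3f s)\n",
              x$participant_id, nrow(x$samples), x$scene$sample_rate_hz,
              nrow(x$events), if (x$complete) "complete" else "incomplete",
              compute_te(x)))
  invisible(x)
}
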