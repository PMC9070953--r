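#' Describe the assay arena
#'
#' The arena records everything about the plate geometry and imaging setup
#' that downstream metrics need: the imaged field of view, the pixel
#' calibration, the frame rate, the position of the repellent (copper)
#' barrier along the odor axis, the half-width of the marker "dead zone"
#' around the barrier where the tracker loses animals, and which direction
#' along x leads to the odor.
#'
#' Defaults follow a 1024x1024 px camera imaging an approximately
#' 47 mm x 47 mm field at 3 frames per second; `pixel_scale` is therefore
#' 47/1024 mm per pixel, and all of these are user-settable because the
#' calibration is approximate.
#'
#' @param fov_width,fov_height field of view, mm.
#' @param pixel_scale mm per pixel.
#' @param frame_rate frames per second.
#' @param barrier_x barrier midline along the odor axis, mm
#'   (0 < barrier_x < fov_width).
#' @param dead_zone_halfwidth half-width of the untrackable marker zone
#'   around the barrier, mm.
#' @param odor_direction `"increasing_x"` if the odor lies toward larger x,
#'   `"decreasing_x"` otherwise. All downstream metrics work on the odor-axis
#'   coordinate after an internal reflection, so one code path serves both.
#' @param bin_width spatial bin width for residence/velocity profiles, mm.
#' @param termination_margin tracks ending within
#'   `dead_zone_halfwidth + termination_margin` of the barrier are treated as
#'   barrier-terminating, mm.
#' @param direction_window time window for trailing-displacement direction
#'   calls and for instantaneous velocity, seconds.
#' @param exclusion_regions list of numeric length-4 vectors
#'   `c(x0, y0, x1, y1)` in pixel coordinates: regions (shadows, markings)
#'   whose overlap disqualifies a track.
#' @return an object of class `ct_arena`.
#' @export
arena <- function(fov_width = 47, fov_height = 47,
                  pixel_scale = 47 / 1024, frame_rate = 3,
                  barrier_x = 30, dead_zone_halfwidth = 1.5,
                  odor_direction = c("increasing_x", "decreasing_x"),
                  bin_width = 1, termination_margin = 1,
                  direction_window = 2, exclusion_regions = list()) {
  odor_direction <- match.arg(odor_direction)
  stopifnot(is_scalar_number(fov_width), fov_width > 0,
            is_scalar_number(fov_height), fov_height > 0,
            is_scalar_number(pixel_scale), pixel_scale > 0,
            is_scalar_number(frame_rate), frame_rate > 0,
            is_scalar_number(bin_width), bin_width > 0,
            is_scalar_number(dead_zone_halfwidth), dead_zone_halfwidth >= 0,
            is_scalar_number(termination_margin), termination_margin >= 0,
            is_scalar_number(direction_window), direction_window > 0)
  if (!is_scalar_number(barrier_x) || barrier_x <= 0 || barrier_x >= fov_width)
    ct_stop("ct_config_error", "barrier_x must satisfy 0 < barrier_x < fov_width")
  stopifnot(is.list(exclusion_regions))
  for (r in exclusion_regions) {
    if (!is.numeric(r) || length(r) != 4L)
      ct_stop("ct_config_error",
              "each exclusion region must be c(x0, y0, x1, y1) in pixels")
  }
  structure(list(fov_width = fov_width, fov_height = fov_height,
                 pixel_scale = pixel_scale, frame_rate = frame_rate,
                 barrier_x = barrier_x,
                 dead_zone_halfwidth = dead_zone_halfwidth,
                 odor_direction = odor_direction, bin_width = bin_width,
                 termination_margin = termination_margin,
                 direction_window = direction_window,
                 exclusion_regions = exclusion_regions),
            class = "ct_arena")
}

#' @export
print.ct_arena <- function(x, ...) {
  cat(sprintf("<ct_arena> %g x %g mm, %g fps, %.5f mm/px\n",
              x$fov_width, x$fov_height, x$frame_rate, x$pixel_scale))
  cat(sprintf("  barrier at x = %g mm (dead zone +/- %g mm), odor %s\n",
              x$barrier_x, x$dead_zone_halfwidth, x$odor_direction))
  invisible(x)
}

#' Build a track set
#'
#' A track set is the canonical container for one experiment: a tidy table of
#' tracked animal midpoints (one row per track per frame) plus the arena and
#' provenance metadata. Points are stored sorted by track then frame.
#'
#' @param points data.frame with columns `track_id`, `frame`, `time_s`, `x`,
#'   `y`. `time_s` may be NA, in which case it is derived as
#'   `frame / frame_rate` (frame index is authoritative).
#' @param units `"pixel"` or `"mm"` — the unit of `x` and `y`.
#' @param arena a [arena()] object.
#' @param condition free-text condition label (e.g. "well-fed").
#' @param source provenance string.
#' @return an object of class `ct_trackset`.
#' @export
track_set <- function(points, units = c("pixel", "mm"), arena = NULL,
                      condition = "", source = "") {
  units <- match.arg(units)
  arena <- arena %||% coppertracks::arena()
  required <- c("track_id", "frame", "time_s", "x", "y")
  if (!is.data.frame(points))
    ct_stop("ct_parse_error", "points must be a data.frame")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols))
    ct_stop("ct_parse_error",
            paste0("points is missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
  points <- as.data.frame(points)[required]
  points$track_id <- as.character(points$track_id)
  points$frame <- as.integer(points$frame)
  if (nrow(points)) {
    if (anyNA(points$frame) || any(points$frame < 0))
      ct_stop("ct_parse_error", "frame must be a non-negative integer")
    if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
      ct_stop("ct_parse_error", "coordinates must be finite")
    points <- points[order(points$track_id, points$frame), , drop = FALSE]
    dup <- duplicated(points[c("track_id", "frame")])
    if (any(dup))
      ct_stop("ct_integrity_error",
              sprintf("duplicate (track_id, frame) pair: (%s, %d)",
                      points$track_id[dup][1], points$frame[dup][1]))
    na_t <- is.na(points$time_s)
    points$time_s[na_t] <- points$frame[na_t] / arena$frame_rate
    rownames(points) <- NULL
  }
  structure(list(points = points, units = units, arena = arena,
                 condition = condition, source = source),
            class = "ct_trackset")
}

#' @export
print.ct_trackset <- function(x, ...) {
  cat(sprintf("<ct_trackset> %d tracks, %d points, units = %s%s\n",
              n_tracks(x), nrow(x$points), x$units,
              if (nzchar(x$condition)) paste0(", condition = ", x$condition)
              else ""))
  invisible(x)
}

#' Number of tracks in a track set
#' @param track_set a [track_set()].
#' @return integer count of distinct track ids.
#' @export
n_tracks <- function(track_set) {
  length(unique(track_set$points$track_id))
}

#' Keep a subset of tracks by id
#' @param track_set a [track_set()].
#' @param ids character vector of track ids to keep.
#' @return a track set containing only those tracks.
#' @export
subset_tracks <- function(track_set, ids) {
  track_set$points <-
    track_set$points[track_set$points$track_id %in% ids, , drop = FALSE]
  rownames(track_set$points) <- NULL
  track_set
}

#' Read tracks from disk
#'
#' Two dialects are supported. `tidy_csv` is the package's canonical
#' interchange format: a long CSV with columns
#' `track_id, frame, time_s, x, y, units`. `wormlab_wide` is a best-effort
#' reader for wide per-animal exports: a `frame` (and optionally `time`)
#' column followed by paired `x<k>` / `y<k>` (or `x.k`/`y.k`) columns, one
#' pair per animal; empty cells mark frames where that animal was not
#' tracked.
#'
#' @param path file to read.
#' @param dialect `"tidy_csv"` or `"wormlab_wide"`.
#' @param arena arena to attach; default [arena()].
#' @param units unit override for dialects that do not carry one
#'   (`wormlab_wide` defaults to `"pixel"`).
#' @return a [track_set()] with points ordered by frame; no filtering applied.
#' @export
read_tracks <- function(path, dialect = c("tidy_csv", "wormlab_wide"),
                        arena = NULL, units = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ct_stop("ct_io_error", paste0("file not found: ", path))
  if (dialect == "tidy_csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e)
        ct_stop("ct_parse_error", paste0("cannot parse ", path, ": ",
                                         conditionMessage(e))))
    required <- c("track_id", "frame", "time_s", "x", "y")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols))
      ct_stop("ct_parse_error",
              paste0(path, " lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
    bad <- which(!is.finite(df$x) | !is.finite(df$y) | is.na(df$frame))
    if (length(bad))
      ct_stop("ct_parse_error",
              sprintf("%s: malformed row at data line %d", path, bad[1]))
    file_units <- if ("units" %in% names(df) && nrow(df)) df$units[1] else NULL
    units <- units %||% file_units %||% "pixel"
    track_set(df[required], units = units, arena = arena)
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e)
        ct_stop("ct_parse_error", paste0("cannot parse ", path, ": ",
                                         conditionMessage(e))))
    nm <- tolower(names(df))
    frame_col <- which(nm %in% c("frame", "frames"))[1]
    if (is.na(frame_col))
      ct_stop("ct_parse_error", paste0(path, ": no 'frame' column"))
    xs <- grep("^x[._ ]?([0-9]+)$", nm)
    ys <- grep("^y[._ ]?([0-9]+)$", nm)
    idx <- function(cols) sub("^[xy][._ ]?", "", nm[cols])
    xi <- idx(xs); yi <- idx(ys)
    common <- intersect(xi, yi)
    if (!length(common))
      ct_stop("ct_parse_error",
              paste0(path, ": no paired x<k>/y<k> animal columns"))
    time_col <- which(nm %in% c("time", "time_s", "time (s)"))[1]
    pieces <- lapply(common, function(k) {
      x <- as.numeric(df[[xs[match(k, xi)]]])
      y <- as.numeric(df[[ys[match(k, yi)]]])
      keep <- is.finite(x) & is.finite(y)
      if (!any(keep)) return(NULL)
      data.frame(track_id = paste0("worm_", k),
                 frame = as.integer(df[[frame_col]][keep]),
                 time_s = if (!is.na(time_col))
                   as.numeric(df[[time_col]][keep]) else NA_real_,
                 x = x[keep], y = y[keep], stringsAsFactors = FALSE)
    })
    pts <- do.call(rbind, pieces)
    if (is.null(pts))
      pts <- data.frame(track_id = character(), frame = integer(),
                        time_s = numeric(), x = numeric(), y = numeric())
    track_set(pts, units = units %||% "pixel", arena = arena)
  }
}

#' Write tracks to disk (tidy CSV)
#'
#' Writes the canonical tidy long format so that
#' `read_tracks(write_tracks(ts))` reproduces the track set exactly.
#' Coordinates are written with 10 significant digits.
#'
#' @param track_set a [track_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(track_set, path) {
  stopifnot(inherits(track_set, "ct_trackset"))
  df <- track_set$points
  df$units <- rep(track_set$units, nrow(df))
  fmt <- function(v) formatC(v, format = "g", digits = 10)
  out <- data.frame(track_id = df$track_id, frame = df$frame,
                    time_s = fmt(df$time_s), x = fmt(df$x), y = fmt(df$y),
                    units = df$units, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ct_stop("ct_io_error", paste0("cannot write ", path))
  invisible(path)
}

#' Convert pixel coordinates to millimetres
#'
#' Multiplies coordinates by the arena's `pixel_scale`. Frame indices, times
#' and point counts are untouched. A track set already in mm is returned
#' unchanged (idempotent).
#'
#' @param track_set a [track_set()] in pixel units.
#' @return the track set in mm.
#' @export
calibrate <- function(track_set) {
  stopifnot(inherits(track_set, "ct_trackset"))
  if (track_set$units == "mm") return(track_set)
  scale <- track_set$arena$pixel_scale
  if (is.null(scale) || !is_scalar_number(scale) || scale <= 0)
    ct_stop("ct_config_error", "arena$pixel_scale missing; cannot calibrate")
  track_set$points$x <- track_set$points$x * scale
  track_set$points$y <- track_set$points$y * scale
  track_set$units <- "mm"
  track_set
}

#' Estimate the number of animals in an experiment
#'
#' The animal count is estimated as the maximum number of simultaneous
#' tracks present in any single frame, because the imaged field does not
#' cover the whole plate and tracks are lost and re-acquired over time.
#'
#' @param track_set a [track_set()].
#' @return integer estimate (0 for an empty set).
#' @export
estimate_animal_count <- function(track_set) {
  stopifnot(inherits(track_set, "ct_trackset"))
  if (!nrow(track_set$points)) return(0L)
  max(tabulate(track_set$points$frame + 1L))
}

#' Signed odor-axis coordinate of x positions (mm, relative to barrier)
#' @noRd
odor_axis_distance <- function(x, arena) {
  if (arena$odor_direction == "increasing_x") x - arena$barrier_x
  else arena$barrier_x - x
}

#' Read a flat key-value configuration file
#'
#' Parses the package's flat `key: value` config format (one key per line,
#' `#` comments, repeated keys collected into a list — used for
#' `exclusion_region`). Numeric-looking scalars and whitespace-separated
#' numeric vectors are converted to numeric.
#'
#' @param path config file.
#' @return named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    ct_stop("ct_io_error", paste0("config not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L)
      ct_stop("ct_parse_error", paste0("bad config line: '", ln, "'"))
    key <- m[2]; raw <- trimws(m[3])
    parts <- strsplit(raw, "[,[:space:]]+")[[1]]
    nums <- suppressWarnings(as.numeric(parts))
    val <- if (length(parts) && !anyNA(nums)) nums else raw
    if (key %in% names(out)) {
      if (!is.list(out[[key]])) out[[key]] <- list(out[[key]])
      out[[key]] <- c(out[[key]], list(val))
    } else out[[key]] <- val
  }
  out
}

#' Build an arena from a parsed config
#'
#' Recognised keys match [arena()] argument names; `exclusion_region` lines
#' (repeatable, `x0 y0 x1 y1` in pixels) populate `exclusion_regions`.
#' Unrecognised keys are ignored so arena and simulation settings can share
#' one file.
#'
#' @param config named list from [read_config()], or a path to a config file.
#' @return an [arena()].
#' @export
arena_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  args <- config[intersect(names(config),
                           c("fov_width", "fov_height", "pixel_scale",
                             "frame_rate", "barrier_x",
                             "dead_zone_halfwidth", "odor_direction",
                             "bin_width", "termination_margin",
                             "direction_window"))]
  regions <- config[["exclusion_region"]]
  if (!is.null(regions)) {
    if (!is.list(regions)) regions <- list(regions)
    args$exclusion_regions <- regions
  }
  do.call(arena, args)
}
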