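#' Track exclusion criteria
#'
#' Tracks are excluded if they meet any of four criteria, evaluated in this
#' order for the audit label: (1) any midpoint falls inside an exclusion
#' region (shadows/markings; boundary counts as inside); (2) the track lasts
#' less than `min_duration` seconds (last timestamp minus first, so dropped
#' frames do not shorten a track artificially); (3) its bounding-box area is
#' below `min_bbox_area` square pixels (or, with
#' `criterion3 = "path_length"`, its summed step length is below
#' `min_bbox_area` pixels — the printed threshold "30 pixels^2" is ambiguous
#' and both readings are provided); (4) it travels less than `min_span`
#' pixels in every axis direction, i.e. `max(span_x, span_y) < min_span`.
#'
#' @param min_duration seconds; default 10.
#' @param min_bbox_area square pixels; default 30.
#' @param min_span pixels; default 10.
#' @param exclusion_regions list of `c(x0, y0, x1, y1)` rectangles, pixels.
#' @param criterion3 `"area"` (default) or `"path_length"`.
#' @param units unit the thresholds are expressed in; tracks must match.
#' @return an object of class `ct_filter_criteria`.
#' @export
filter_criteria <- function(min_duration = 10, min_bbox_area = 30,
                            min_span = 10, exclusion_regions = list(),
                            criterion3 = c("area", "path_length"),
                            units = "pixel") {
  criterion3 <- match.arg(criterion3)
  stopifnot(min_duration >= 0, min_bbox_area >= 0, min_span >= 0,
            is.list(exclusion_regions))
  structure(list(min_duration = min_duration, min_bbox_area = min_bbox_area,
                 min_span = min_span, exclusion_regions = exclusion_regions,
                 criterion3 = criterion3, units = units),
            class = "ct_filter_criteria")
}

point_in_region <- function(x, y, r) {
  x >= min(r[c(1, 3)]) & x <= max(r[c(1, 3)]) &
    y >= min(r[c(2, 4)]) & y <= max(r[c(2, 4)])
}

# first matching criterion label for one track's points, or NA if kept
classify_track_defect <- function(x, y, time_s, criteria) {
  for (r in criteria$exclusion_regions) {
    if (any(point_in_region(x, y, r))) return("in_exclusion_region")
  }
  if (max(time_s) - min(time_s) < criteria$min_duration) return("too_short")
  extent3 <- if (criteria$criterion3 == "area") {
    (max(x) - min(x)) * (max(y) - min(y))
  } else {
    if (length(x) < 2L) 0 else sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  if (extent3 < criteria$min_bbox_area) return("too_small_area")
  if (max(max(x) - min(x), max(y) - min(y)) < criteria$min_span)
    return("too_small_span")
  NA_character_
}

#' Apply the track exclusion filters
#'
#' Evaluates the four exclusion criteria of [filter_criteria()] on every
#' track and returns the kept tracks together with an audit of rejections
#' (each rejected track labelled with the first criterion it met).
#' Filtering is idempotent: re-filtering the kept set rejects nothing.
#'
#' @param track_set a [track_set()] in the same units as `criteria`
#'   (pixel by default, matching the tracker's native export).
#' @param criteria a [filter_criteria()]; defaults taken from the arena's
#'   exclusion regions and the standard thresholds.
#' @return an object of class `ct_filter_report`: a list with `kept` (a
#'   track set) and `rejected` (data.frame `track_id`, `rejected_by`).
#' @export
filter_tracks <- function(track_set, criteria = NULL) {
  stopifnot(inherits(track_set, "ct_trackset"))
  criteria <- criteria %||%
    filter_criteria(exclusion_regions = track_set$arena$exclusion_regions)
  if (track_set$units != criteria$units)
    ct_stop("ct_unit_error",
            sprintf("track units (%s) differ from criteria units (%s); %s",
                    track_set$units, criteria$units,
                    "convert thresholds or calibrate after filtering"))
  pts <- track_set$points
  ids <- unique(pts$track_id)
  labels <- vapply(split(seq_len(nrow(pts)), factor(pts$track_id, ids)),
                   function(i) classify_track_defect(pts$x[i], pts$y[i],
                                                     pts$time_s[i], criteria),
                   character(1))
  rejected <- data.frame(track_id = ids[!is.na(labels)],
                         rejected_by = labels[!is.na(labels)],
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(kept = subset_tracks(track_set, ids[is.na(labels)]),
                 rejected = rejected, criteria = criteria),
            class = "ct_filter_report")
}

#' @export
print.ct_filter_report <- function(x, ...) {
  cat(sprintf("<ct_filter_report> kept %d tracks, rejected %d\n",
              n_tracks(x$kept), nrow(x$rejected)))
  if (nrow(x$rejected))
    print(table(x$rejected$rejected_by))
  invisible(x)
}

#' Export a filter report's audit as CSV
#' @param report a `ct_filter_report`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$rejected, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
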