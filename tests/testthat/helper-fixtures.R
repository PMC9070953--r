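# shared fixture builders: everything is generated in code at test time

# a track point table from coordinate vectors (frames 0, 1, ...)
pts_df <- function(id, x, y, frame_rate = 3, frames = seq_along(x) - 1L) {
  data.frame(track_id = id, frame = as.integer(frames),
             time_s = frames / frame_rate, x = x, y = y,
             stringsAsFactors = FALSE)
}

# a straight-line track between two points with n points
line_track <- function(id, from, to, n, frame_rate = 3, start_frame = 0L,
                       frames = start_frame + seq_len(n) - 1L) {
  pts_df(id, seq(from[1], to[1], length.out = n),
         seq(from[2], to[2], length.out = n), frame_rate, frames = frames)
}

mm_set <- function(..., arena = coppertracks::arena(), condition = "") {
  track_set(do.call(rbind, list(...)), units = "mm", arena = arena,
            condition = condition)
}

px_set <- function(..., arena = coppertracks::arena()) {
  track_set(do.call(rbind, list(...)), units = "pixel", arena = arena)
}

# quick simulation at reduced scale for Monte-Carlo-flavoured tests
quick_config <- function(duration = 600, n_animals = 15, ...) {
  simulation_config(duration = duration, n_animals = n_animals, ...)
}

# independent straight-line reimplementation of the four exclusion
# predicates (the brute-force oracle for filter_tracks)
oracle_filter_label <- function(df, criteria) {
  in_rect <- function(x, y, r)
    x >= min(r[c(1, 3)]) & x <= max(r[c(1, 3)]) &
      y >= min(r[c(2, 4)]) & y <= max(r[c(2, 4)])
  hit_region <- FALSE
  for (r in criteria$exclusion_regions)
    hit_region <- hit_region || any(in_rect(df$x, df$y, r))
  if (hit_region) return("in_exclusion_region")
  if ((max(df$time_s) - min(df$time_s)) < criteria$min_duration)
    return("too_short")
  ext <- if (criteria$criterion3 == "area")
    diff(range(df$x)) * diff(range(df$y))
  else sum(sqrt(diff(df$x)^2 + diff(df$y)^2))
  if (ext < criteria$min_bbox_area) return("too_small_area")
  if (max(diff(range(df$x)), diff(range(df$y))) < criteria$min_span)
    return("too_small_span")
  NA_character_
}
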