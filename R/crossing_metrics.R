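#' Classify barrier-terminating tracks
#'
#' Animals that cross the copper barrier pass under an untrackable marker
#' zone, so their tracks terminate there. A track "terminates at the
#' barrier" when its final point lies within
#' `dead_zone_halfwidth + termination_margin` of the barrier midline along
#' the odor axis. Such tracks are categorised as:
#' \describe{
#'   \item{reversal}{the first point also lies within that band — the animal
#'     emerged from the marker zone and returned to it; discounted from
#'     crossing counts.}
#'   \item{forward}{a crossing toward the odor.}
#'   \item{reverse}{a crossing away from the odor.}
#' }
#' All other tracks are labelled `none`.
#'
#' Two direction rules are available. `"side"` (default) uses the side of
#' the barrier on which the track terminates: ending on the origin side
#' means the animal was entering the marker zone toward the odor (forward),
#' ending on the odor side means it was heading back (reverse).
#' `"trailing"` instead uses the sign of the net odor-axis displacement over
#' the trailing `direction_window` seconds; a zero displacement (no approach
#' direction) is labelled `reversal`.
#'
#' @param track_set a [track_set()] in mm.
#' @param arena arena override; defaults to the track set's arena.
#' @param direction `"side"` or `"trailing"` (see Details).
#' @param censor_at optional recording length in seconds: tracks whose last
#'   frame reaches `censor_at` (within one frame) are labelled `none`, since
#'   they ended with the recording rather than at the marker zone. Default
#'   `NULL` (no censoring).
#' @return data.frame with columns `track_id`, `label`
#'   (forward/reverse/reversal/none) and `termination_time` (seconds; NA for
#'   `none`).
#' @export
classify_terminations <- function(track_set, arena = NULL,
                                  direction = c("side", "trailing"),
                                  censor_at = NULL) {
  stopifnot(inherits(track_set, "ct_trackset"))
  direction <- match.arg(direction)
  arena <- arena %||% track_set$arena
  if (track_set$units != "mm")
    ct_stop("ct_unit_error", "classify_terminations needs mm units; calibrate() first")
  if (is.null(arena$barrier_x))
    ct_stop("ct_config_error", "arena has no barrier_x")
  band <- arena$dead_zone_halfwidth + arena$termination_margin
  pts <- track_set$points
  ids <- unique(pts$track_id)
  res <- lapply(split(seq_len(nrow(pts)), factor(pts$track_id, ids)), function(i) {
    u <- odor_axis_distance(pts$x[i], arena)
    t <- pts$time_s[i]
    n <- length(i)
    t_end <- t[n]
    censored <- !is.null(censor_at) &&
      t_end >= censor_at - 1 / arena$frame_rate - 1e-9
    if (censored || abs(u[n]) > band)
      return(list(label = "none", time = NA_real_))
    if (abs(u[1]) <= band)
      return(list(label = "reversal", time = t_end))
    if (direction == "side") {
      lab <- if (u[n] < 0) "forward" else if (u[n] > 0) "reverse"
             else "reversal"
    } else {
      j <- max(which(t <= t_end - arena$direction_window), 1L)
      disp <- u[n] - u[j]
      lab <- if (disp > 0) "forward" else if (disp < 0) "reverse"
             else "reversal"
    }
    list(label = lab, time = t_end)
  })
  data.frame(track_id = ids,
             label = vapply(res, `[[`, character(1), "label"),
             termination_time = vapply(res, `[[`, numeric(1), "time"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cumulative net barrier crossings
#'
#' At each checkpoint time T, counts the forward- and reverse-labelled
#' tracks that terminated at or before T, takes net = forward − reverse, and
#' normalizes by the estimated animal count to give the barrier-crossings
#' score. Reversal and `none` labels contribute nothing.
#'
#' @param labels data.frame from [classify_terminations()].
#' @param animal_count estimated animals on the plate (≥ 1), typically from
#'   [estimate_animal_count()].
#' @param checkpoints seconds, ascending; default 15/30/45 minutes.
#' @return an object of class `ct_crossing_summary`: data.frame with
#'   `checkpoint_s`, `forward`, `reverse`, `net`, `fraction`, and the animal
#'   count as attribute `animal_count`.
#' @export
cumulative_crossings <- function(labels, animal_count,
                                 checkpoints = c(900, 1800, 2700)) {
  if (!is_scalar_number(animal_count) || animal_count < 1)
    ct_stop("ct_config_error",
            "animal_count must be >= 1 for a defined crossing fraction")
  stopifnot(is.numeric(checkpoints), !is.unsorted(checkpoints))
  fwd_t <- labels$termination_time[labels$label == "forward"]
  rev_t <- labels$termination_time[labels$label == "reverse"]
  forward <- vapply(checkpoints, function(T) sum(fwd_t <= T), numeric(1))
  reverse <- vapply(checkpoints, function(T) sum(rev_t <= T), numeric(1))
  out <- data.frame(checkpoint_s = checkpoints, forward = forward,
                    reverse = reverse, net = forward - reverse,
                    fraction = (forward - reverse) / animal_count)
  attr(out, "animal_count") <- animal_count
  class(out) <- c("ct_crossing_summary", "data.frame")
  out
}

#' Chemotactic index
#'
#' The fraction of animals on the odor half of the plate: animals on the
#' odor side divided by the total number of animals on the plate.
#'
#' @param n_odor_side animals counted on the odor side (≥ 0).
#' @param n_origin_side animals on the origin side (≥ 0).
#' @return index in \[0, 1\].
#' @export
chemotactic_index <- function(n_odor_side, n_origin_side) {
  stopifnot(n_odor_side >= 0, n_origin_side >= 0)
  total <- n_odor_side + n_origin_side
  if (total <= 0)
    ct_stop("ct_config_error", "chemotactic index undefined for zero animals")
  n_odor_side / total
}
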