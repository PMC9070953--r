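#' Signed distance from the barrier
#'
#' The odor-axis coordinate of every tracked midpoint relative to the
#' barrier midline: negative on the origin (start) side, positive on the
#' odor side, irrespective of whether the odor lies toward increasing or
#' decreasing x in the camera frame.
#'
#' @param track_set a [track_set()] in mm.
#' @param arena arena override; defaults to the track set's arena.
#' @return numeric vector of signed distances (mm), one per point row.
#' @export
signed_distance <- function(track_set, arena = NULL) {
  stopifnot(inherits(track_set, "ct_trackset"))
  arena <- arena %||% track_set$arena
  if (track_set$units != "mm")
    ct_stop("ct_unit_error", "signed_distance needs mm units; calibrate() first")
  odor_axis_distance(track_set$points$x, arena)
}

# default integer-mm bin edges spanning the field of view around the barrier
default_bin_edges <- function(arena) {
  lo <- -arena$barrier_x
  hi <- arena$fov_width - arena$barrier_x
  if (arena$odor_direction == "decreasing_x") {
    tmp <- lo; lo <- -hi; hi <- -tmp
  }
  seq(floor(lo), ceiling(hi), by = arena$bin_width)
}

new_profile <- function(bin_edges, value, n, sem = NULL, kind) {
  out <- data.frame(bin_left = bin_edges[-length(bin_edges)],
                    bin_right = bin_edges[-1],
                    value = value, n = n)
  if (!is.null(sem)) out$sem <- sem
  attr(out, "kind") <- kind
  class(out) <- c("ct_profile", "data.frame")
  out
}

#' Residence probability profile
#'
#' The probability of a tracked animal midpoint being located in each 1 mm
#' bin of signed distance from the barrier: midpoints in the bin, summed
#' over all frames of all tracks, divided by the total number of tracked
#' midpoints across all bins. Every midpoint of every track at every frame
#' contributes exactly once; normalization is per experiment.
#'
#' @param track_set a [track_set()] in mm (typically the kept tracks).
#' @param arena arena override.
#' @param bin_edges bin edges in mm of signed distance (half-open
#'   `[left, right)` bins); default integer-mm edges covering the field of
#'   view on both sides of the barrier.
#' @return a `ct_profile` data.frame: `bin_left`, `bin_right`, `value`
#'   (probability), `n` (midpoint count).
#' @export
residence_probability <- function(track_set, arena = NULL, bin_edges = NULL) {
  arena <- arena %||% track_set$arena
  d <- signed_distance(track_set, arena)
  bin_edges <- bin_edges %||% default_bin_edges(arena)
  idx <- findInterval(d, bin_edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= length(bin_edges) - 1L]
  if (!length(idx))
    ct_stop("ct_empty_error", "no tracked midpoints within the binned range")
  counts <- tabulate(idx, nbins = length(bin_edges) - 1L)
  new_profile(bin_edges, counts / sum(counts), counts, kind = "residence")
}

#' Instantaneous velocity over a sliding window
#'
#' For each point at time t, the Euclidean (chord) distance between the
#' track's positions at t − window/2 and t + window/2, divided by the
#' window, in μm/s. Videos of this kind lack the resolution for absolute
#' path length, so the chord is used. The velocity is undefined (NA) within
#' window/2 of either end of a track, and at points where the exact frames
#' at ±window/2 are missing (gapped tracks are not silently shortened).
#'
#' @param track_set a [track_set()] in mm.
#' @param window window length in seconds (default 2: t − 1 s to t + 1 s).
#' @return the track set's point table with a `velocity_um_s` column.
#' @export
instantaneous_velocity <- function(track_set, window = 2) {
  stopifnot(inherits(track_set, "ct_trackset"))
  if (track_set$units != "mm")
    ct_stop("ct_unit_error", "instantaneous_velocity needs mm units")
  stopifnot(window > 0)
  fr <- track_set$arena$frame_rate
  half <- window / 2 * fr
  if (abs(half - round(half)) > 1e-9)
    ct_stop("ct_config_error",
            "window/2 must be a whole number of frames at this frame rate")
  half <- as.integer(round(half))
  pts <- track_set$points
  pts$velocity_um_s <- NA_real_
  for (i in split(seq_len(nrow(pts)), pts$track_id)) {
    f <- pts$frame[i]
    before <- match(f - half, f)
    after <- match(f + half, f)
    ok <- !is.na(before) & !is.na(after)
    dx <- pts$x[i][after[ok]] - pts$x[i][before[ok]]
    dy <- pts$y[i][after[ok]] - pts$y[i][before[ok]]
    pts$velocity_um_s[i[ok]] <- sqrt(dx^2 + dy^2) * 1000 / window
  }
  pts
}

#' Velocity-versus-distance profile
#'
#' Each defined instantaneous-velocity sample is assigned to the 1 mm bin of
#' its central point's signed distance from the barrier; the per-bin mean
#' and standard error of the mean are computed over samples. Empty bins have
#' `n = 0` and NA mean.
#'
#' @inheritParams residence_probability
#' @param window velocity window, seconds.
#' @param exclude_dead_zone drop samples whose central point lies within the
#'   termination band around the barrier (default FALSE: included).
#' @return a `ct_profile` data.frame: `bin_left`, `bin_right`, `value`
#'   (mean velocity, μm/s), `n`, `sem`.
#' @export
velocity_profile <- function(track_set, arena = NULL, bin_edges = NULL,
                             window = 2, exclude_dead_zone = FALSE) {
  arena <- arena %||% track_set$arena
  bin_edges <- bin_edges %||% default_bin_edges(arena)
  pts <- instantaneous_velocity(track_set, window = window)
  d <- odor_axis_distance(pts$x, arena)
  keep <- !is.na(pts$velocity_um_s)
  if (exclude_dead_zone) {
    band <- arena$dead_zone_halfwidth + arena$termination_margin
    keep <- keep & abs(d) > band
  }
  v <- pts$velocity_um_s[keep]
  idx <- findInterval(d[keep], bin_edges, rightmost.closed = FALSE)
  inb <- idx >= 1L & idx <= length(bin_edges) - 1L
  v <- v[inb]; idx <- idx[inb]
  nb <- length(bin_edges) - 1L
  n <- tabulate(idx, nbins = nb)
  mean_v <- rep(NA_real_, nb)
  sem <- rep(NA_real_, nb)
  if (length(v)) {
    sums <- vapply(split(v, factor(idx, seq_len(nb))), sum, numeric(1))
    mean_v[n > 0] <- sums[n > 0] / n[n > 0]
    vars <- vapply(split(v, factor(idx, seq_len(nb))),
                   function(z) if (length(z) > 1) stats::var(z) else NA_real_,
                   numeric(1))
    sem[n > 1] <- sqrt(vars[n > 1] / n[n > 1])
  }
  new_profile(bin_edges, mean_v, n, sem, kind = "velocity")
}

#' Write a profile as CSV
#' @param profile a `ct_profile`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot a profile (mean with shaded SEM band)
#'
#' Draws one or more profiles on a common signed-distance axis, residence
#' probability or mean velocity against distance from the barrier, with a
#' shaded ±SEM band where SEM is available.
#'
#' @param x a `ct_profile`.
#' @param ... further `ct_profile` objects to overlay.
#' @param col line colors, recycled.
#' @param labels legend labels.
#' @export
plot.ct_profile <- function(x, ..., col = c("black", "blue"), labels = NULL) {
  profiles <- c(list(x), Filter(function(p) inherits(p, "ct_profile"),
                                list(...)))
  col <- rep_len(col, length(profiles))
  kind <- attr(x, "kind") %||% "value"
  ylab <- if (identical(kind, "residence")) "p(location)"
          else "mean velocity (μm/s)"
  mid <- (x$bin_left + x$bin_right) / 2
  ylim <- range(unlist(lapply(profiles, function(p)
    c(p$value - if (is.null(p$sem)) 0 else p$sem,
      p$value + if (is.null(p$sem)) 0 else p$sem))), 0, na.rm = TRUE)
  graphics::plot(mid, profiles[[1]]$value, type = "n", ylim = ylim,
                 xlab = "signed distance from barrier (mm)", ylab = ylab)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    m <- (p$bin_left + p$bin_right) / 2
    if (!is.null(p$sem)) {
      ok <- !is.na(p$value) & !is.na(p$sem)
      graphics::polygon(c(m[ok], rev(m[ok])),
                        c(p$value[ok] - p$sem[ok],
                          rev(p$value[ok] + p$sem[ok])),
                        border = NA,
                        col = grDevices::adjustcolor(col[k], alpha.f = 0.25))
    }
    graphics::lines(m, p$value, col = col[k], lwd = 2)
  }
  if (!is.null(labels))
    graphics::legend("topright", legend = labels, col = col, lwd = 2,
                     bty = "n")
  invisible(x)
}
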