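#' Simulation configuration for synthetic worm tracks
#'
#' Parameters of the generative model used to produce track sets with known
#' ground truth. Animals follow a persistent random walk: each step the
#' heading carries over with angular (wrapped-normal) noise and a weak
#' deterministic pull toward the odor; the step length is the local mean
#' speed (a piecewise-linear function of signed distance from the barrier)
#' divided by the frame rate, with multiplicative lognormal noise. On
#' touching the dead-zone boundary an animal crosses with probability
#' `crossing_propensity` (the track is truncated there and the event
#' recorded) or turns away; a crossing decision is made once per encounter
#' (the animal must retreat 1 mm before a new decision is armed). A crossed
#' animal re-emerges on the far side with probability `reversal_propensity`
#' after a short delay, starting a new track near the barrier that may
#' re-cross. Tracks are clipped to the field of view and no emitted point
#' lies inside the dead zone.
#'
#' Defaults emulate the assay the analysis was built for: ~30 tracked
#' animals, 45-minute recordings at 3 frames per second in a 47 mm field,
#' crawling at ~200 μm/s, placed in a start zone ~2 cm on the origin side
#' of the barrier.
#'
#' @param arena an [arena()].
#' @param n_animals animals placed at frame 0.
#' @param duration recording length, seconds.
#' @param base_speed mean crawling speed, μm/s.
#' @param speed_vs_distance piecewise-linear speed law: data.frame with
#'   columns `distance_mm` (signed distance from barrier) and `speed_um_s`;
#'   NULL for a flat law at `base_speed`.
#' @param heading_persistence per-step heading correlation in \[0, 1);
#'   angular noise SD is `(1 - heading_persistence) * pi` radians.
#' @param odor_drift strength of the deterministic heading pull toward the
#'   odor (radians per step at right angles to the odor axis).
#' @param crossing_propensity probability of crossing per barrier encounter.
#' @param reversal_propensity probability that a crossed animal re-emerges.
#' @param start_zone mm interval of signed distance from the barrier in
#'   which animals start (uniform).
#' @param noise_tracks named counts of degenerate tracks to append, classes
#'   `too_short`, `too_small_area`, `too_small_span`, `in_exclusion_region`.
#' @param step_noise_sd lognormal sigma of the multiplicative step noise.
#' @param seed integer RNG seed (NULL: use the current RNG stream).
#' @param condition condition label carried into the emitted track set.
#' @return an object of class `ct_sim_config`.
#' @export
simulation_config <- function(arena = coppertracks::arena(), n_animals = 30,
                              duration = 2700, base_speed = 200,
                              speed_vs_distance = NULL,
                              heading_persistence = 0.9, odor_drift = 0.05,
                              crossing_propensity = 0.3,
                              reversal_propensity = 0.1,
                              start_zone = c(-22, -19),
                              noise_tracks = c(too_short = 0,
                                               too_small_area = 0,
                                               too_small_span = 0,
                                               in_exclusion_region = 0),
                              step_noise_sd = 0.15, seed = NULL,
                              condition = "") {
  fail <- function(field, why)
    ct_stop("ct_validation_error", sprintf("invalid %s: %s", field, why))
  if (!inherits(arena, "ct_arena")) fail("arena", "not a ct_arena")
  if (!is_scalar_number(n_animals) || n_animals < 1 ||
      n_animals != round(n_animals)) fail("n_animals", "positive integer required")
  if (!is_scalar_number(duration) || duration <= 0) fail("duration", "must be > 0")
  if (!is_scalar_number(base_speed) || base_speed < 0) fail("base_speed", "must be >= 0")
  if (!is.null(speed_vs_distance)) {
    if (!is.data.frame(speed_vs_distance) ||
        !all(c("distance_mm", "speed_um_s") %in% names(speed_vs_distance)))
      fail("speed_vs_distance", "needs columns distance_mm, speed_um_s")
    if (any(speed_vs_distance$speed_um_s < 0))
      fail("speed_vs_distance", "speeds must be >= 0")
  }
  if (!is_scalar_number(heading_persistence) || heading_persistence < 0 ||
      heading_persistence >= 1) fail("heading_persistence", "must be in [0, 1)")
  if (!is_scalar_number(odor_drift) || odor_drift < 0) fail("odor_drift", "must be >= 0")
  for (f in c("crossing_propensity", "reversal_propensity")) {
    v <- get(f)
    if (!is_scalar_number(v) || v < 0 || v > 1) fail(f, "must be in [0, 1]")
  }
  if (!is.numeric(start_zone) || length(start_zone) != 2 ||
      start_zone[1] > start_zone[2]) fail("start_zone", "must be c(lo, hi), lo <= hi")
  defect_classes <- c("too_short", "too_small_area", "too_small_span",
                      "in_exclusion_region")
  nt <- noise_tracks
  if (is.null(names(nt)) || !all(names(nt) %in% defect_classes) ||
      any(nt < 0)) fail("noise_tracks", paste0("named non-negative counts among: ",
                                               paste(defect_classes, collapse = ", ")))
  full <- stats::setNames(rep(0, 4), defect_classes)
  full[names(nt)] <- nt
  if (!is_scalar_number(step_noise_sd) || step_noise_sd < 0)
    fail("step_noise_sd", "must be >= 0")
  structure(list(arena = arena, n_animals = as.integer(n_animals),
                 duration = duration, base_speed = base_speed,
                 speed_vs_distance = speed_vs_distance,
                 heading_persistence = heading_persistence,
                 odor_drift = odor_drift,
                 crossing_propensity = crossing_propensity,
                 reversal_propensity = reversal_propensity,
                 start_zone = start_zone, noise_tracks = full,
                 step_noise_sd = step_noise_sd, seed = seed,
                 condition = condition),
            class = "ct_sim_config")
}

# effective speed law as a data.frame (flat law materialized)
effective_speed_law <- function(config) {
  config$speed_vs_distance %||%
    data.frame(distance_mm = c(-config$arena$fov_width,
                               config$arena$fov_width),
               speed_um_s = rep(config$base_speed, 2))
}

# walk one agent from start frame to the end of the recording or until it
# crosses; internal frame: odor toward +x, barrier at bx. Returns emitted
# positions and the truncation event, if any.
walk_agent <- function(x0, y0, theta0, f_start, n_frames, config) {
  arena <- config$arena
  bx <- if (arena$odor_direction == "increasing_x") arena$barrier_x
        else arena$fov_width - arena$barrier_x
  hw <- arena$dead_zone_halfwidth
  rearm <- hw + 1
  law <- effective_speed_law(config)
  speed_at <- stats::approxfun(law$distance_mm, law$speed_um_s, rule = 2)
  fr <- arena$frame_rate
  sn <- config$step_noise_sd
  sig_theta <- (1 - config$heading_persistence) * pi
  n_steps <- n_frames - f_start - 1L
  if (n_steps < 0L) return(NULL)
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  xs[1] <- x0; ys[1] <- y0
  if (n_steps > 0L) {
    ang_noise <- stats::rnorm(n_steps, 0, sig_theta)
    step_noise <- if (sn > 0) exp(stats::rnorm(n_steps, -sn^2 / 2, sn))
                  else rep(1, n_steps)
    cross_u <- stats::runif(n_steps)
  }
  x <- x0; y <- y0; theta <- theta0
  eligible <- TRUE
  event <- NULL
  k <- 1L
  for (s in seq_len(max(n_steps, 0L))) {
    theta <- theta + ang_noise[s] - config$odor_drift * sin(theta)
    L <- speed_at(x - bx) / 1000 / fr * step_noise[s]
    nx <- x + L * cos(theta)
    ny <- y + L * sin(theta)
    # billiard reflection at the field-of-view walls (position and heading)
    if (ny < 0) { ny <- -ny; theta <- -theta }
    if (ny > arena$fov_height) { ny <- 2 * arena$fov_height - ny; theta <- -theta }
    if (nx < 0) { nx <- -nx; theta <- pi - theta }
    if (nx > arena$fov_width) { nx <- 2 * arena$fov_width - nx; theta <- pi - theta }
    ny <- min(max(ny, 0), arena$fov_height)
    nx <- min(max(nx, 0), arena$fov_width)
    sd_old <- x - bx
    sd_new <- nx - bx
    if (abs(sd_new) < hw) {
      if (eligible && cross_u[s] < config$crossing_propensity) {
        event <- list(frame = f_start + k - 1L,
                      direction = if (sd_old < 0) "forward" else "reverse")
        break
      }
      # refused (or refractory): reflect off the dead-zone boundary
      eligible <- FALSE
      edge <- bx + sign(sd_old) * hw
      nx <- 2 * edge - nx
      if (abs(nx - bx) < hw) nx <- edge + sign(sd_old) * 1e-6
      theta <- pi - theta
      sd_new <- nx - bx
    }
    if (abs(sd_new) > rearm) eligible <- TRUE
    x <- nx; y <- ny
    k <- k + 1L
    xs[k] <- x; ys[k] <- y
  }
  list(x = xs[seq_len(k)], y = ys[seq_len(k)],
       frames = seq.int(f_start, f_start + k - 1L), event = event)
}

#' Simulate one tracking experiment
#'
#' Runs the persistent-random-walk model of [simulation_config()] for every
#' animal, truncating tracks at the dead zone on crossings and spawning
#' re-emergent tracks, then appends any requested degenerate noise tracks.
#' Identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return an object of class `ct_simulation`: list with `tracks` (a
#'   [track_set()] in pixel units, as a tracker would export) and `truth`,
#'   a ground-truth list holding `crossings` (data.frame `track_id`,
#'   `time_s`, `direction` — truncation events of tracks that started
#'   outside the termination band), `reversals` (barrier terminations of
#'   tracks that started inside the band), `emergences`, `defects` (planted
#'   noise-track labels), `speed_law` and `animal_count`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ct_sim_config"))
  with_seed(seed, {
    arena <- config$arena
    fr <- arena$frame_rate
    n_frames <- as.integer(round(config$duration * fr))
    bx <- if (arena$odor_direction == "increasing_x") arena$barrier_x
          else arena$fov_width - arena$barrier_x
    band <- arena$dead_zone_halfwidth + arena$termination_margin
    # seed agents in the start zone on the origin side
    queue <- lapply(seq_len(config$n_animals), function(i) {
      list(x0 = bx + stats::runif(1, config$start_zone[1],
                                  config$start_zone[2]),
           y0 = stats::runif(1, 0.15, 0.85) * arena$fov_height,
           theta0 = stats::runif(1, -pi, pi), f_start = 0L)
    })
    pieces <- list()
    crossings <- list(); reversals <- list(); emergences <- list()
    next_id <- 1L
    while (length(queue)) {
      ag <- queue[[1]]; queue <- queue[-1]
      tr <- walk_agent(ag$x0, ag$y0, ag$theta0, ag$f_start, n_frames, config)
      if (is.null(tr) || !length(tr$frames)) next
      id <- sprintf("t%03d", next_id); next_id <- next_id + 1L
      if (!is.null(ag$parent))
        emergences[[length(emergences) + 1L]] <-
          data.frame(track_id = id, parent_id = ag$parent,
                     time_s = tr$frames[1] / fr, stringsAsFactors = FALSE)
      pieces[[id]] <- data.frame(track_id = id, frame = tr$frames,
                                 time_s = tr$frames / fr,
                                 x = tr$x, y = tr$y,
                                 stringsAsFactors = FALSE)
      if (!is.null(tr$event)) {
        t_end <- tr$event$frame / fr
        started_in_band <- abs(tr$x[1] - bx) <= band
        rec <- data.frame(track_id = id, time_s = t_end,
                          direction = tr$event$direction,
                          stringsAsFactors = FALSE)
        if (started_in_band) reversals[[length(reversals) + 1L]] <- rec
        else crossings[[length(crossings) + 1L]] <- rec
        # re-emergence on the far side after a dwell under the marker
        if (stats::runif(1) < config$reversal_propensity) {
          side <- if (tr$event$direction == "forward") 1 else -1
          dist <- stats::runif(1, arena$dead_zone_halfwidth + 0.1,
                               arena$dead_zone_halfwidth + 1.5)
          delay <- as.integer(round(stats::runif(1, 5, 15) * fr))
          f_new <- tr$event$frame + delay
          if (f_new < n_frames - 1L)
            queue[[length(queue) + 1L]] <-
              list(x0 = bx + side * dist,
                   y0 = min(max(tr$y[length(tr$y)], 0), arena$fov_height),
                   theta0 = stats::runif(1, -pi, pi), f_start = f_new,
                   parent = id)
        }
      }
    }
    pts <- if (length(pieces)) do.call(rbind, pieces)
           else data.frame(track_id = character(), frame = integer(),
                           time_s = numeric(), x = numeric(), y = numeric())
    # internal frame has odor toward +x; reflect for decreasing_x arenas
    if (arena$odor_direction == "decreasing_x")
      pts$x <- arena$fov_width - pts$x
    pts$x <- pts$x / arena$pixel_scale
    pts$y <- pts$y / arena$pixel_scale
    ts <- track_set(pts, units = "pixel", arena = arena,
                    condition = config$condition, source = "ct_simulation")
    empty_events <- data.frame(track_id = character(), time_s = numeric(),
                               direction = character(),
                               stringsAsFactors = FALSE)
    bind_or_empty <- function(lst, cols) {
      if (length(lst)) do.call(rbind, lst) else empty_events
    }
    truth <- list(
      crossings = bind_or_empty(crossings, c("track_id", "time_s", "direction")),
      reversals = bind_or_empty(reversals, c("track_id", "time_s", "direction")),
      emergences = if (length(emergences)) do.call(rbind, emergences)
                   else data.frame(track_id = character(),
                                   parent_id = character(),
                                   time_s = numeric(),
                                   stringsAsFactors = FALSE),
      defects = data.frame(track_id = character(), defect = character(),
                           stringsAsFactors = FALSE),
      speed_law = effective_speed_law(config),
      animal_count = config$n_animals)
    sim <- list(tracks = ts, truth = truth, config = config)
    if (sum(config$noise_tracks) > 0) {
      inj <- inject_noise_tracks(ts, config)
      sim$tracks <- inj$tracks
      sim$truth$defects <- inj$defects
    }
    structure(sim, class = "ct_simulation")
  })
}

#' @export
print.ct_simulation <- function(x, ...) {
  cat(sprintf("<ct_simulation> %d tracks (%d crossings, %d reversals, %d noise)\n",
              n_tracks(x$tracks), nrow(x$truth$crossings),
              nrow(x$truth$reversals), nrow(x$truth$defects)))
  invisible(x)
}

#' Paired well-fed / food-deprived configurations
#'
#' Encodes the qualitative behavioral contrast between well-fed and
#' food-deprived animals in the assay: food-deprived animals cross the
#' barrier more readily (higher crossing propensity, stronger pull toward
#' the odor, hence elevated residence near the barrier) and crawl more
#' slowly far from the barrier (a depressed far-field speed law). All other
#' fields are shared with the base configuration.
#'
#' @param base a [simulation_config()] providing the shared fields.
#' @return list with elements `wf` and `fd` (both `ct_sim_config`).
#' @export
make_wf_fd_pair <- function(base = simulation_config()) {
  stopifnot(inherits(base, "ct_sim_config"))
  bs <- base$base_speed
  w <- base$arena$fov_width
  # per-encounter propensities are compounded over many barrier encounters
  # in a 45-min recording; these values give plate-level 45-min net crossing
  # fractions of roughly 0.3-0.4 (WF) and 0.7-0.9 (FD)
  wf <- base
  wf$crossing_propensity <- 0.015
  wf$odor_drift <- 0.02
  wf$speed_vs_distance <- NULL
  wf$condition <- "well-fed"
  fd <- base
  fd$crossing_propensity <- 0.035
  fd$odor_drift <- 0.06
  fd$speed_vs_distance <- data.frame(
    distance_mm = c(-w, -10, -5, w),
    speed_um_s = c(0.6, 0.6, 0.95, 0.95) * bs)
  fd$condition <- "food-deprived"
  list(wf = wf, fd = fd)
}

#' Append degenerate noise tracks exercising the exclusion filters
#'
#' Each appended track violates exactly one exclusion criterion of
#' [filter_criteria()] at the default thresholds (10 s, 30 px², 10 px) and
#' no other: a 9 s track with ample motion; a 60 s track confined to a
#' 12 x 2 px box (area 24 px² but span 12 px); a 60 s track confined to a
#' 9 x 9 px box (area 81 px² but max span 9 px); and a long, large track
#' routed through the first configured exclusion region.
#'
#' @param track_set a pixel-unit [track_set()] to append to.
#' @param config a [simulation_config()] whose `noise_tracks` counts say how
#'   many of each class to plant (its arena supplies exclusion regions).
#' @return list with `tracks` (augmented track set) and `defects`
#'   (data.frame `track_id`, `defect`).
#' @export
inject_noise_tracks <- function(track_set, config) {
  stopifnot(inherits(track_set, "ct_trackset"),
            inherits(config, "ct_sim_config"))
  arena <- config$arena
  fr <- arena$frame_rate
  counts <- config$noise_tracks
  regions <- arena$exclusion_regions
  if (counts["in_exclusion_region"] > 0 && !length(regions))
    ct_stop("ct_validation_error",
            paste0("in_exclusion_region noise tracks need an exclusion ",
                   "region in the arena config"))
  fov_px <- c(arena$fov_width, arena$fov_height) / arena$pixel_scale
  in_any_region <- function(x, y) {
    for (r in regions) if (any(point_in_region(x, y, r))) return(TRUE)
    FALSE
  }
  # find a corner anchor whose footprint avoids all exclusion regions
  find_anchor <- function(w, h) {
    for (y0 in seq(20, fov_px[2] - h - 20, by = 60)) {
      for (x0 in c(20, fov_px[1] - w - 20)) {
        cx <- c(x0, x0 + w, x0 + w, x0); cy <- c(y0, y0, y0 + h, y0 + h)
        if (!in_any_region(cx, cy)) return(c(x0, y0))
      }
    }
    ct_stop("ct_validation_error",
            "no placement for a noise track outside the exclusion regions")
  }
  make_defect <- function(class, k) {
    id <- sprintf("noise_%s_%d", class, k)
    if (class == "too_short") {
      nf <- as.integer(round(9 * fr)) + 1L   # exactly 9 s span
      a <- find_anchor(60, 20)
      f <- seq_len(nf) - 1L
      df <- data.frame(track_id = id, frame = f, time_s = f / fr,
                       x = a[1] + seq(0, 60, length.out = nf),
                       y = a[2] + seq(0, 20, length.out = nf))
    } else if (class == "too_small_area") {
      nf <- as.integer(round(60 * fr)) + 1L
      a <- find_anchor(12, 2)
      f <- seq_len(nf) - 1L
      df <- data.frame(track_id = id, frame = f, time_s = f / fr,
                       x = a[1] + 6 + 6 * sin(2 * pi * f / 30),
                       y = a[2] + 1 + cos(2 * pi * f / 20))
    } else if (class == "too_small_span") {
      nf <- as.integer(round(60 * fr)) + 1L
      a <- find_anchor(9, 9)
      f <- seq_len(nf) - 1L
      df <- data.frame(track_id = id, frame = f, time_s = f / fr,
                       x = a[1] + 4.5 + 4.5 * sin(2 * pi * f / 30),
                       y = a[2] + 4.5 + 4.5 * cos(2 * pi * f / 30))
    } else {  # in_exclusion_region
      nf <- as.integer(round(60 * fr)) + 1L
      r <- regions[[1]]
      cx <- mean(r[c(1, 3)]); cy <- mean(r[c(2, 4)])
      f <- seq_len(nf) - 1L
      df <- data.frame(track_id = id, frame = f, time_s = f / fr,
                       x = cx - 40 + seq(0, 80, length.out = nf),
                       y = cy + seq(-15, 15, length.out = nf))
    }
    df
  }
  defect_rows <- list(); new_pts <- list()
  for (class in names(counts)) {
    n <- counts[[class]]
    if (n < 1) next
    for (k in seq_len(n)) {
      df <- make_defect(class, k)
      new_pts[[length(new_pts) + 1L]] <- df
      defect_rows[[length(defect_rows) + 1L]] <-
        data.frame(track_id = df$track_id[1], defect = class,
                   stringsAsFactors = FALSE)
    }
  }
  defects <- if (length(defect_rows)) do.call(rbind, defect_rows)
             else data.frame(track_id = character(), defect = character(),
                             stringsAsFactors = FALSE)
  if (length(new_pts)) {
    pts <- rbind(track_set$points,
                 do.call(rbind, new_pts)[names(track_set$points)])
    track_set <- track_set(pts, units = track_set$units,
                           arena = track_set$arena,
                           condition = track_set$condition,
                           source = track_set$source)
  }
  list(tracks = track_set, defects = defects)
}
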