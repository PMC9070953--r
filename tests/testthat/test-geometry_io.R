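test_that("tidy CSV round-trips a track set exactly", {
  ts <- px_set(line_track("a", c(0, 0), c(100, 50), 3),
               line_track("b", c(10, 10), c(10, 10), 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, path)
  back <- read_tracks(path)
  expect_equal(back$points$track_id, ts$points$track_id)
  expect_equal(back$points$frame, ts$points$frame)
  expect_equal(back$points$x, ts$points$x, tolerance = 1e-9)
  expect_equal(back$points$y, ts$points$y, tolerance = 1e-9)
  expect_equal(back$units, "pixel")

  # single 3-point track survives as-is
  one <- px_set(line_track("only", c(1, 2), c(3, 4), 3))
  write_tracks(one, path)
  got <- read_tracks(path)
  expect_equal(n_tracks(got), 1L)
  expect_equal(nrow(got$points), 3L)
})

test_that("empty track set writes a header-only file", {
  ts <- track_set(data.frame(track_id = character(), frame = integer(),
                             time_s = numeric(), x = numeric(),
                             y = numeric()), units = "pixel")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, path)
  expect_length(readLines(path), 1L)
  expect_equal(n_tracks(read_tracks(path)), 0L)
})

test_that("writes are byte-stable across repeats", {
  sim <- simulate_experiment(quick_config(duration = 120, n_animals = 3),
                             seed = 11)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, p1)
  write_tracks(sim$tracks, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_gt(nrow(sim$tracks$points), 1000)
})

test_that("duplicate (track_id, frame) pairs are an integrity error", {
  df <- rbind(line_track("a", c(0, 0), c(10, 0), 4),
              pts_df("a", 5, 5, frames = 2L))
  expect_error(track_set(df, units = "pixel"), class = "ct_integrity_error")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cbind(df, units = "pixel"), path, row.names = FALSE)
  expect_error(read_tracks(path), class = "ct_integrity_error")
})

test_that("malformed rows raise a parse error naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,time_s,x,y", "a,0,0,1,2", "a,1,0.33,NaN,4"),
             path)
  expect_error(read_tracks(path), "line 2", class = "ct_parse_error")
})

test_that("wormlab wide dialect reads per-animal column pairs", {
  # wide fixture written by code: 2 animals x 10 frames, animal 2 drops out
  n <- 10
  wide <- data.frame(frame = 0:(n - 1), time = (0:(n - 1)) / 3,
                     x1 = seq(100, 190, by = 10), y1 = rep(50, n),
                     x2 = c(seq(400, 460, by = 10), NA, NA, NA),
                     y2 = c(seq(300, 360, by = 10), NA, NA, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, path, row.names = FALSE)
  ts <- read_tracks(path, dialect = "wormlab_wide")
  expect_equal(n_tracks(ts), 2L)
  expect_equal(sum(ts$points$track_id == "worm_1"), 10L)
  expect_equal(sum(ts$points$track_id == "worm_2"), 7L)
  # round-trip through the tidy writer preserves the points
  tidy <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts, tidy)
  back <- read_tracks(tidy)
  expect_equal(back$points$x, ts$points$x, tolerance = 1e-9)
})

test_that("calibrate scales by pixel_scale and is idempotent", {
  a <- arena(pixel_scale = 47 / 1024)
  ts <- px_set(pts_df("a", c(0, 1024), c(0, 1024)), arena = a)
  mm <- calibrate(ts)
  expect_equal(mm$units, "mm")
  expect_equal(mm$points$x, c(0, 47))
  expect_equal(mm$points$y, c(0, 47))
  expect_identical(calibrate(mm), mm)               # no-op on mm input
  expect_equal(mm$points$frame, ts$points$frame)    # frames/times untouched
  expect_equal(mm$points$time_s, ts$points$time_s)
  expect_equal(nrow(mm$points), nrow(ts$points))
})

test_that("calibrate scales all pairwise distances by exactly pixel_scale", {
  set.seed(42)
  xy <- matrix(runif(40, 0, 1024), ncol = 2)
  a <- arena(pixel_scale = 47 / 1024)
  ts <- px_set(pts_df("a", xy[, 1], xy[, 2]), arena = a)
  mm <- calibrate(ts)
  d_px <- as.matrix(dist(xy))                        # brute-force oracle
  d_mm <- as.matrix(dist(cbind(mm$points$x, mm$points$y)))
  expect_equal(d_mm, d_px * (47 / 1024), tolerance = 1e-12)
})

test_that("animal count is the max number of simultaneous tracks", {
  expect_equal(estimate_animal_count(px_set(line_track("a", c(0, 0), c(9, 9), 5))), 1L)
  ts <- px_set(line_track("a", c(0, 0), c(10, 0), 11, frames = 0:10),
               line_track("b", c(0, 5), c(10, 5), 11, frames = 5:15),
               line_track("c", c(0, 9), c(10, 9), 11, frames = 20:30))
  # brute-force per-frame recount
  per_frame <- table(ts$points$frame)
  expect_equal(estimate_animal_count(ts), max(per_frame))
  expect_equal(estimate_animal_count(ts), 2L)
  # invariant to ordering and relabeling; bounded by the track count
  shuffled <- ts
  set.seed(7)
  shuffled$points <- ts$points[sample(nrow(ts$points)), ]
  shuffled <- track_set(shuffled$points, units = "pixel")
  relabeled <- ts
  relabeled$points$track_id <-
    c(a = "zz", b = "qq", c = "aa")[relabeled$points$track_id]
  expect_equal(estimate_animal_count(shuffled), 2L)
  expect_equal(estimate_animal_count(track_set(relabeled$points,
                                               units = "pixel")), 2L)
  expect_lte(estimate_animal_count(ts), n_tracks(ts))
  empty <- track_set(data.frame(track_id = character(), frame = integer(),
                                time_s = numeric(), x = numeric(),
                                y = numeric()), units = "pixel")
  expect_equal(estimate_animal_count(empty), 0L)
})

test_that("flat key-value configs build arenas, including exclusion regions", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# arena", "fov_width: 47", "fov_height: 47",
               "pixel_scale: 0.0459", "frame_rate: 3", "barrier_x: 30",
               "dead_zone_halfwidth: 1.5", "odor_direction: increasing_x",
               "exclusion_region: 100 200 150 260",
               "exclusion_region: 700 700 800 820",
               "n_animals: 12   # simulator key, ignored by the arena"),
             path)
  a <- arena_from_config(path)
  expect_s3_class(a, "ct_arena")
  expect_equal(a$barrier_x, 30)
  expect_length(a$exclusion_regions, 2L)
  expect_equal(a$exclusion_regions[[2]], c(700, 700, 800, 820))
  expect_error(arena_from_config(list(barrier_x = 99)),
               class = "ct_config_error")
})
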