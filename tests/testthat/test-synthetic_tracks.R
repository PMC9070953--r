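test_that("identical seeds give identical output, different seeds differ", {
  cfg <- quick_config(duration = 200, n_animals = 6)
  s1 <- simulate_experiment(cfg, seed = 5)
  s2 <- simulate_experiment(cfg, seed = 5)
  expect_identical(s1$tracks$points, s2$tracks$points)
  expect_identical(s1$truth$crossings, s2$truth$crossings)
  s3 <- simulate_experiment(cfg, seed = 6)
  expect_false(identical(s1$tracks$points, s3$tracks$points))
})

test_that("a closed barrier yields no crossings anywhere in the pipeline", {
  cfg <- quick_config(duration = 400, n_animals = 10,
                      crossing_propensity = 0, odor_drift = 0.1)
  sim <- simulate_experiment(cfg, seed = 9)
  expect_equal(nrow(sim$truth$crossings), 0L)
  labs <- classify_terminations(calibrate(sim$tracks),
                                censor_at = cfg$duration)
  expect_equal(sum(labs$label %in% c("forward", "reverse")), 0L)
})

test_that("emitted points stay inside the field of view and outside the dead zone", {
  for (seed in c(2, 12)) {
    sim <- simulate_experiment(quick_config(duration = 300, n_animals = 10,
                                            crossing_propensity = 0.2,
                                            reversal_propensity = 0.5),
                               seed = seed)
    mm <- calibrate(sim$tracks)
    a <- mm$arena
    expect_true(all(mm$points$x >= -1e-9 & mm$points$x <= a$fov_width + 1e-9))
    expect_true(all(mm$points$y >= -1e-9 & mm$points$y <= a$fov_height + 1e-9))
    expect_true(all(abs(mm$points$x - a$barrier_x) >=
                      a$dead_zone_halfwidth - 1e-9))
  }
})

test_that("classification recovers the simulator's ground truth exactly", {
  for (seed in c(7, 77, 777)) {
    cfg <- quick_config(duration = 500, n_animals = 12,
                        crossing_propensity = 0.25,
                        reversal_propensity = 0.5, odor_drift = 0.08)
    sim <- simulate_experiment(cfg, seed = seed)
    labs <- classify_terminations(calibrate(sim$tracks),
                                  censor_at = cfg$duration)
    tab <- table(factor(labs$label,
                        c("forward", "reverse", "reversal", "none")))
    expect_equal(unname(tab[["forward"]]),
                 sum(sim$truth$crossings$direction == "forward"))
    expect_equal(unname(tab[["reverse"]]),
                 sum(sim$truth$crossings$direction == "reverse"))
    expect_equal(unname(tab[["reversal"]]), nrow(sim$truth$reversals))
    # per-track agreement, not just totals
    expect_setequal(labs$track_id[labs$label %in% c("forward", "reverse")],
                    sim$truth$crossings$track_id)
    ct <- merge(labs, sim$truth$crossings, by = "track_id")
    expect_equal(ct$label, ct$direction)
    expect_equal(ct$termination_time, ct$time_s)
  }
})

test_that("net crossings rise with crossing propensity (fixed seeds)", {
  mean_frac <- function(p, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- quick_config(duration = 600, n_animals = 12,
                          crossing_propensity = p, odor_drift = 0.08)
      sim <- simulate_experiment(cfg, seed = s)
      labs <- classify_terminations(calibrate(sim$tracks),
                                    censor_at = cfg$duration)
      cumulative_crossings(labs, cfg$n_animals,
                           checkpoints = cfg$duration)$fraction
    }, numeric(1)))
  }
  seeds <- 1:8
  expect_gt(mean_frac(0.8, seeds), mean_frac(0.2, seeds))
})

test_that("velocity profile recovers a planted speed law", {
  law <- data.frame(distance_mm = c(-47, -15, -5, 47),
                    speed_um_s = c(120, 120, 220, 220))
  # near-ballistic motion so the 2-s chord is close to the true path
  cfg <- simulation_config(duration = 900, n_animals = 25,
                           speed_vs_distance = law,
                           heading_persistence = 0.98, odor_drift = 0.01,
                           crossing_propensity = 0, step_noise_sd = 0.05)
  sim <- simulate_experiment(cfg, seed = 41)
  vp <- velocity_profile(calibrate(sim$tracks))
  truth <- approx(law$distance_mm, law$speed_um_s,
                  xout = (vp$bin_left + vp$bin_right) / 2, rule = 2)$y
  # only bins fully inside a flat stretch of the law (no binning bias) and
  # clear of the dead-zone bounce point at -1.5 mm, where the 2-s chord of
  # a turning animal necessarily undershoots its path
  occ <- which(vp$n > 100 & !is.na(vp$sem) &
                 (vp$bin_right <= -15 |
                    (vp$bin_left >= -5 & vp$bin_right <= -2)))
  expect_gt(length(occ), 10)
  # within 3 SEM plus a small allowance for residual chord-vs-arc bias
  tol <- pmax(3 * vp$sem[occ], 0.03 * truth[occ])
  expect_true(all(abs(vp$value[occ] - truth[occ]) < tol))
})

test_that("well-fed / food-deprived pair encodes the stated contrasts", {
  pair <- make_wf_fd_pair(simulation_config())
  expect_gt(pair$fd$crossing_propensity, pair$wf$crossing_propensity)
  expect_s3_class(pair$wf, "ct_sim_config")
  expect_equal(pair$wf$n_animals, pair$fd$n_animals)
  # far-field FD speed is depressed relative to WF
  far_fd <- approx(pair$fd$speed_vs_distance$distance_mm,
                   pair$fd$speed_vs_distance$speed_um_s, xout = -20,
                   rule = 2)$y
  expect_lt(far_fd, pair$wf$base_speed)
})

test_that("planted defect tracks are recovered exactly by the filter", {
  # region on the odor side, unreachable with a closed barrier, so genuine
  # tracks cannot stray into it; closed barrier also rules out truncation
  a <- arena(exclusion_regions = list(c(750, 750, 820, 830)))
  cfg <- simulation_config(arena = a, duration = 300, n_animals = 10,
                           crossing_propensity = 0,
                           noise_tracks = c(too_short = 2,
                                            too_small_area = 1,
                                            too_small_span = 2,
                                            in_exclusion_region = 1))
  sim <- simulate_experiment(cfg, seed = 23)
  expect_equal(nrow(sim$truth$defects), 6L)
  rep <- filter_tracks(sim$tracks,
                       filter_criteria(exclusion_regions = a$exclusion_regions))
  planted <- setNames(sim$truth$defects$defect, sim$truth$defects$track_id)
  got <- setNames(rep$rejected$rejected_by, rep$rejected$track_id)
  expect_setequal(names(got), names(planted))       # exactly the planted ids
  expect_equal(got[names(planted)], planted)        # each with its criterion
})

test_that("noise-track edge cases follow the contract", {
  sim <- simulate_experiment(quick_config(duration = 120, n_animals = 4),
                             seed = 2)
  out <- inject_noise_tracks(sim$tracks, quick_config(duration = 120,
                                                      n_animals = 4))
  expect_identical(out$tracks$points, sim$tracks$points)  # zero requested
  cfg_bad <- quick_config(noise_tracks = c(in_exclusion_region = 1))
  expect_error(inject_noise_tracks(sim$tracks, cfg_bad),
               class = "ct_validation_error")
  # a single too_short track is rejected by criterion 2 alone
  cfg1 <- quick_config(noise_tracks = c(too_short = 1))
  one <- inject_noise_tracks(sim$tracks, cfg1)
  rep <- filter_tracks(subset_tracks(one$tracks, one$defects$track_id))
  expect_equal(rep$rejected$rejected_by, "too_short")
})

test_that("simulator count matches the requested animals with no dropout", {
  sim <- simulate_experiment(quick_config(duration = 200, n_animals = 14,
                                          crossing_propensity = 0),
                             seed = 4)
  expect_equal(estimate_animal_count(sim$tracks), 14L)
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(crossing_propensity = 1.4),
               "crossing_propensity", class = "ct_validation_error")
  expect_error(simulation_config(heading_persistence = 1),
               "heading_persistence", class = "ct_validation_error")
  expect_error(simulation_config(n_animals = 0), "n_animals",
               class = "ct_validation_error")
  expect_error(simulation_config(noise_tracks = c(bogus = 1)),
               "noise_tracks", class = "ct_validation_error")
})
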