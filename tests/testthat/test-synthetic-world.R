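test_that("configuration invariants are enforced", {
  expect_error(sim_config(hz = 0), "hz")
  expect_error(sim_config(speed_mps = -1), "speed")
  expect_error(sim_config(noise_sds = list(rater_sd = -0.1)), "non-negative")
})

test_that("the agent walk respects kinematics and room geometry", {
  room <- generate_room(seed = 2, occlusion_fraction = 0.3)
  tr <- simulate_trajectory(room, drive = 6, scan_rate = 5, duration_s = 10,
                            seed = 8)
  expect_equal(nrow(tr), 600)  # 10 s at 60 Hz
  # confined to accessible cells
  h <- bin_path(tr, room)
  expect_equal(h$n_samples_dropped, 0)
  # speed limit per sample
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_lte(max(d), 3.4 / 60 + 1e-9)
  expect_true(all(tr$yaw >= -180 & tr$yaw < 180))
  expect_true(all(tr$pitch >= -90 & tr$pitch <= 90))
  # determinism
  tr2 <- simulate_trajectory(room, drive = 6, scan_rate = 5, duration_s = 10,
                             seed = 8)
  expect_identical(tr, tr2)
  expect_error(simulate_trajectory(room, 5, 5, duration_s = 0), "duration")
  expect_error(simulate_trajectory(room, Inf, 5, duration_s = 5), "finite")
})

test_that("entropy-matched synthesis realises its targets", {
  room <- generate_room(seed = 4, occlusion_fraction = 0.25)
  set.seed(5)
  for (target in c(0.15, 0.35, 0.55)) {
    tr <- synth_trajectory(room, target, 0.6, duration_s = 30)
    expect_lt(abs(tr$path_re - target), 0.01)
    expect_lt(abs(tr$head_re - 0.6), 0.01)
    re <- compute_trial_re(tr$samples, room)
    # binning the emitted samples reproduces the constructed histogram
    expect_equal(re$path_re, tr$path_re, tolerance = 1e-12)
    expect_equal(re$head_re, tr$head_re, tolerance = 1e-12)
    expect_equal(re$n_dropped, 0)
    d <- sqrt(diff(tr$samples$x)^2 + diff(tr$samples$y)^2)
    expect_lte(max(d), 3.4 / 60 + 1e-9)
  }
})

test_that("cohorts are deterministic and respect all scale invariants", {
  coh <- small_cohort()
  cfg <- small_config()
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$trajectories, coh2$trajectories)
  expect_identical(coh$ratings, coh2$ratings)
  expect_identical(coh$sketch_scores, coh2$sketch_scores)

  r <- coh$ratings
  expect_equal(nrow(r), 8 * 6)
  expect_true(all(r$curiosity == round(r$curiosity) &
                    r$curiosity >= 1 & r$curiosity <= 10))
  expect_true(all(r$interest == round(r$interest) &
                    r$interest >= 1 & r$interest <= 10))
  tr <- coh$traits
  expect_true(all(as.matrix(tr[-1]) >= 1 & as.matrix(tr[-1]) <= 7))
  sk <- as.matrix(coh$sketch_scores[c("OP", "SD", "RP", "SP")])
  expect_true(all(sk >= 1 & sk <= 5))
  expect_true(all(abs(sk * 2 - round(sk * 2)) < 1e-9))
  # two raters per map
  expect_true(all(table(coh$sketch_scores$participant_id,
                        coh$sketch_scores$room_id) == 2))
  # durations consistent with sample counts
  ns <- dplyr::count(coh$trajectories, participant_id, room_id)
  j <- dplyr::inner_join(ns, r, by = c("participant_id", "room_id"))
  expect_equal(j$n / 60, j$duration_s, tolerance = 1e-9)
})

test_that("a zero coupling yields no curiosity-coverage correlation", {
  cfg <- small_config(n_participants = 15L, n_rooms = 12L,
                      beta_drive_coverage = 0, beta_interest_coverage = 0,
                      trait_moderation = 0)
  coh <- generate_cohort(cfg)
  re <- compute_re(coh$trajectories, coh$rooms)
  d <- dplyr::inner_join(re, coh$ratings, by = c("participant_id", "room_id"))
  d <- d |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(cw = curiosity - mean(curiosity),
                  rw = path_re - mean(path_re)) |>
    dplyr::ungroup()
  expect_lt(abs(stats::cor(d$cw, d$rw)), 0.15)
})

test_that("within-person OLS recovers a positive generative slope", {
  cfg <- small_config(n_participants = 15L, n_rooms = 12L,
                      beta_drive_coverage = 0.02, trait_moderation = 0)
  coh <- generate_cohort(cfg)
  re <- compute_re(coh$trajectories, coh$rooms)
  d <- dplyr::inner_join(re, coh$ratings, by = c("participant_id", "room_id"))
  d <- d |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(cw = curiosity - mean(curiosity),
                  iw = interest - mean(interest),
                  dw = duration_s - mean(duration_s)) |>
    dplyr::ungroup()
  fit <- stats::lm(path_re ~ 0 + factor(participant_id) + cw + iw + dw,
                   data = d)
  slope <- stats::coef(fit)[["cw"]]
  expect_gt(slope, 0.01)
  expect_lt(abs(slope - 0.02), 2.5 * summary(fit)$coefficients["cw", 2])
})

test_that("raising the drive-coverage coupling never lowers the slope", {
  slopes <- vapply(c(0, 0.01, 0.02), function(beta) {
    cfg <- small_config(beta_drive_coverage = beta, trait_moderation = 0)
    coh <- generate_cohort(cfg)
    re <- compute_re(coh$trajectories, coh$rooms)
    d <- dplyr::inner_join(re, coh$ratings,
                           by = c("participant_id", "room_id")) |>
      dplyr::group_by(participant_id) |>
      dplyr::mutate(cw = curiosity - mean(curiosity)) |>
      dplyr::ungroup()
    stats::coef(stats::lm(path_re ~ 0 + factor(participant_id) + cw,
                          data = d))[["cw"]]
  }, numeric(1))
  expect_true(all(diff(slopes) > -1e-6))
})

test_that("cohorts write to disk in the formats the readers accept", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_trajectories(file.path(dir, "trajectories.csv"))
  expect_equal(nrow(back), nrow(coh$trajectories))
  expect_equal(read_ratings(file.path(dir, "ratings.csv")),
               coh$ratings, ignore_attr = TRUE)
  expect_equal(nrow(read_traits(file.path(dir, "traits.csv"))), 8)
  expect_equal(nrow(read_sketch_scores(file.path(dir, "sketch_scores.csv"))),
               nrow(coh$sketch_scores))
  room <- read_mask(file.path(dir, "masks", "room01.txt"))
  expect_identical(room$accessible, coh$rooms$room01$accessible)
  gt <- yaml::read_yaml(file.path(dir, "ground_truth.yml"))
  expect_equal(gt$beta_curiosity_path, coh$ground_truth$beta_curiosity_path)
})
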