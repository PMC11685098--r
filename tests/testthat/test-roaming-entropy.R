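test_that("roaming entropy matches hand-computed and boundary values", {
  h <- function(counts, k) list(counts = counts, k = k)
  # -(3/4 log2 3/4 + 1/4 log2 1/4) / log2 4, evaluated independently
  expect_equal(roaming_entropy(h(c(3, 1), 4)), 0.4056390622, tolerance = 1e-9)
  expect_identical(roaming_entropy(h(rep(5, 8), 8)), 1)
  expect_identical(roaming_entropy(h(c(12, 0, 0, 0), 4)), 0)
  expect_identical(roaming_entropy(h(7, 1)), 0)  # k = 1 convention
  expect_error(roaming_entropy(h(c(-1, 2), 4)), "negative")
  expect_error(roaming_entropy(h(c(0, 0), 4)), "empty")
})

test_that("entropy depends only on the histogram (permutation invariance)", {
  set.seed(101)
  for (i in 1:20) {
    k <- sample(3:12, 1)
    counts <- rpois(k, 4)
    counts[1] <- counts[1] + 1   # non-empty
    h1 <- roaming_entropy(list(counts = counts, k = k))
    h2 <- roaming_entropy(list(counts = sample(counts), k = k))
    expect_equal(h1, h2, tolerance = 1e-14)
    expect_gte(h1, 0); expect_lte(h1, 1)
  }
})

test_that("merging two occupied bins never increases raw entropy", {
  set.seed(202)
  for (i in 1:25) {
    counts <- rpois(8, 5) + 1
    occ <- which(counts > 0)
    pick <- sample(occ, 2)
    merged <- counts
    merged[pick[1]] <- merged[pick[1]] + merged[pick[2]]
    merged[pick[2]] <- 0
    raw <- function(cc) roaming_entropy(list(counts = cc, k = 2)) * log2(2)
    expect_lte(raw(merged), raw(counts) + 1e-12)
  }
})

test_that("path binning follows the half-open grid with boundary clamping", {
  room <- open_room(4)   # 4 x 4 cells of 0.5 m, all accessible
  # three samples in one cell, one in another
  s <- samples_at(x = c(0.1, 0.12, 0.2, 0.6), y = c(0.1, 0.15, 0.1, 0.1))
  hist <- bin_path(s, room)
  expect_equal(sort(hist$counts[hist$counts > 0]), c(1, 3))
  expect_equal(hist$n_samples_dropped, 0)
  expect_equal(hist$k, 16)
  # x exactly at the wall clamps into the last cell
  edge <- bin_path(samples_at(2.0, 1.0), room)
  expect_equal(edge$n_samples_dropped, 0)
  expect_equal(sum(edge$counts), 1)
  expect_error(bin_path(samples_at(2.3, 0.2), room), "outside")
})

test_that("samples in occluded cells are dropped, not snapped", {
  m <- matrix(TRUE, 4, 4); m[2, 2] <- FALSE
  room <- room_grid(m, room_id = "blocked")
  s <- samples_at(x = c(0.6, 0.1), y = c(0.6, 0.1))  # first lands in (2,2)
  hist <- bin_path(s, room)
  expect_equal(hist$n_samples_dropped, 1)
  expect_equal(hist$n_samples_used, 1)
  expect_equal(hist$k, 15)
  all_blocked <- samples_at(0.6, 0.6)
  expect_error(bin_path(all_blocked, room), "inaccessible")
})

test_that("head-direction binning uses the fixed 18 x 36 10-degree grid", {
  h <- bin_head(samples_at(0, 0, yaw = -180, pitch = -90))
  expect_equal(h$k, 648L)
  expect_equal(length(h$counts), 18 * 36)
  expect_equal(which(h$counts == 1), 1L)            # south-west corner bin
  h2 <- bin_head(samples_at(0, 0, yaw = 0, pitch = 0))
  # floor((0+90)/10) = 9, floor((0+180)/10) = 18 (0-based) -> linear 18*18+10
  expect_equal(which(h2$counts == 1), 334L)
  h3 <- bin_head(samples_at(0, 0, yaw = 175, pitch = 90))  # top bin clamp
  expect_equal(which(h3$counts == 1), 18L + 35L * 18L)
  expect_error(bin_head(samples_at(0, 0, yaw = 180, pitch = 0)), "yaw")
  expect_error(bin_head(samples_at(0, 0, yaw = 0, pitch = 91)), "pitch")
})

test_that("trial-level RE hits its exact extremes on constructed input", {
  room <- room_grid(matrix(TRUE, 2, 2), room_id = "tiny")
  still <- samples_at(0.2, 0.2, yaw = 10, pitch = 5)
  still <- still[rep(1, 50), ]
  re0 <- compute_trial_re(still, room)
  expect_identical(re0$path_re, 0)
  expect_identical(re0$head_re, 0)

  # uniform sweep: every cell and every head bin visited equally often
  yawc <- rep(seq(-175, 175, by = 10), each = 18)
  pitc <- rep(seq(-85, 85, by = 10), times = 36)
  n <- 648 * 2
  # order x/y so each of the 4 cells appears exactly n/4 times
  sweep <- tibble::tibble(t = (seq_len(n) - 1) / 60,
                          x = rep(c(0.2, 0.7, 0.2, 0.7), n / 4),
                          y = rep(c(0.2, 0.2, 0.7, 0.7), n / 4),
                          yaw = rep(yawc, 2), pitch = rep(pitc, 2))
  re1 <- compute_trial_re(sweep, room)
  expect_equal(re1$path_re, 1, tolerance = 1e-12)
  expect_equal(re1$head_re, 1, tolerance = 1e-12)

  pct <- compute_trial_re(sweep, room, as_percent = TRUE)
  expect_equal(pct$path_re, 100 * re1$path_re)
  expect_equal(pct$scale, "percent")
})

test_that("path RE is invariant under a 90-degree rotation of room and path", {
  set.seed(33)
  m <- matrix(TRUE, 8, 8); m[3:4, 5:6] <- FALSE
  room <- room_grid(m, room_id = "r")
  side <- room$side_m
  # rotate the mask: cell (r, c) -> (c, n + 1 - r)
  n <- nrow(m)
  m2 <- matrix(FALSE, n, n)
  for (r in 1:n) for (c in 1:n) m2[c, n + 1 - r] <- m[r, c]
  room2 <- room_grid(m2, room_id = "r90")
  ok <- FALSE
  for (i in 1:200) {
    x <- runif(40, 0, side); y <- runif(40, 0, side)
    keep <- room$accessible[cbind(pmin(floor(y / 0.5) + 1, n),
                                  pmin(floor(x / 0.5) + 1, n))]
    if (sum(keep) < 10) next
    s1 <- samples_at(x[keep], y[keep])
    s2 <- samples_at(side - y[keep], x[keep])  # same rotation applied to path
    expect_equal(roaming_entropy(bin_path(s1, room)),
                 roaming_entropy(bin_path(s2, room2)), tolerance = 1e-12)
    ok <- TRUE
    break
  }
  expect_true(ok)
})

test_that("the simulated agent earns higher path RE when drive is high", {
  room <- generate_room(seed = 5, occlusion_fraction = 0.25)
  hi <- simulate_trajectory(room, drive = 9, scan_rate = 8, duration_s = 20,
                            seed = 17)
  lo <- simulate_trajectory(room, drive = 2, scan_rate = 2, duration_s = 20,
                            seed = 17)
  expect_gt(compute_trial_re(hi, room)$path_re,
            compute_trial_re(lo, room)$path_re)
  expect_gt(compute_trial_re(hi, room)$head_re,
            compute_trial_re(lo, room)$head_re)
})

test_that("cumulative RE ends at the full-trial value", {
  room <- open_room(4)
  set.seed(4)
  s <- samples_at(runif(120, 0, 2), runif(120, 0, 2))
  curve <- re_over_time(s, room)
  expect_true(all(curve$path_re >= 0 & curve$path_re <= 1))
  expect_equal(curve$path_re[nrow(curve)],
               roaming_entropy(bin_path(s, room)))
})

test_that("compute_re maps trials to their rooms and flags missing masks", {
  coh <- small_cohort()
  if (is.null(the$small_re)) {
    the$small_re <- compute_re(coh$trajectories, coh$rooms)
  }
  re <- the$small_re
  expect_equal(nrow(re), 8 * 6)
  expect_true(all(re$path_re > 0 & re$path_re < 1))
  expect_true(all(re$head_re > 0 & re$head_re < 1))
  expect_error(compute_re(coh$trajectories, coh$rooms["room01"]),
               "no room mask")
})
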