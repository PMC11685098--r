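#' Simulation configuration
#'
#' Collects every parameter of the synthetic cohort generator: cohort
#' dimensions, kinematics, the ground-truth coefficients of the
#' generative model, and all noise levels. Defaults describe a
#' free-exploration study of 60 participants visiting 16 rooms of
#' 16 m x 16 m at a fixed 3.4 m/s walking speed, logged at 60 Hz, with
#' per-room dwell times log-normal around 33 s (SD 23 s), effect sizes
#' on the scale of unit-interval roaming entropy per 1-10 rating point,
#' and rater noise tuned to give inter-rater reliabilities in the low
#' 0.7s.
#'
#' @param n_participants,n_rooms cohort dimensions.
#' @param hz sampling rate (samples/second).
#' @param speed_mps walking speed in metres/second.
#' @param duration_mean_s,duration_sd_s,duration_range_s log-normal
#'   dwell-time distribution (mean, SD, clipping range), seconds.
#' @param occlusion_fraction fraction of room cells occluded by
#'   furniture blobs.
#' @param rating_mean centre of the 1-10 rating scale used by the
#'   generative model.
#' @param person_rating_sd,person_rating_cor SD and correlation of
#'   participant-level mean curiosity/interest.
#' @param latent_sd,latent_cor SD and correlation of the trial-level
#'   (curiosity drive, interest level) latents.
#' @param beta_drive_coverage effect of the curiosity rating on path
#'   roaming entropy (RE units per rating point), within person.
#' @param beta_interest_coverage cross effect of interest on path RE.
#' @param beta_interest_scan effect of the interest rating on
#'   head-direction RE.
#' @param beta_curiosity_scan cross effect of curiosity on head RE.
#' @param beta_duration_path,beta_duration_head duration effects
#'   (RE units per second).
#' @param intercept_path,intercept_head expected RE at the rating-scale
#'   centre and mean duration.
#' @param trait_moderation interaction of Stress Tolerance with the
#'   curiosity -> path-RE slope (RE units per rating point per trait
#'   point).
#' @param trait_means,trait_sd,trait_cor distribution of the four
#'   curiosity-trait subscales (JE, DS, ST, TS) on their 1-7 scale.
#' @param map_intercept expected composite sketch score at the scale
#'   centres.
#' @param map_beta_curiosity,map_beta_coverage effects of the curiosity
#'   rating and of realised path RE on the latent map score.
#' @param resid_cor residual correlation between path and head RE after
#'   the predictors.
#' @param noise_sds named list of noise SDs: `path_resid`, `head_resid`
#'   (trial residuals), `person_path`, `person_head`, `person_map`
#'   (participant intercepts), `slope_c_path`, `slope_i_head`
#'   (participant slope deviations), `map_resid` (trial-level map
#'   noise), `dim_sd` (rubric-dimension specificity) and `rater_sd`
#'   (per-rater noise before rounding to the 0.5 grid).
#' @param seed master seed; the full dataset is a deterministic
#'   function of the configuration.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 60L, n_rooms = 16L, hz = 60,
                       speed_mps = 3.4,
                       duration_mean_s = 33.1, duration_sd_s = 22.8,
                       duration_range_s = c(8, 120),
                       occlusion_fraction = 0.25,
                       rating_mean = 5.5,
                       person_rating_sd = 1.2, person_rating_cor = 0.5,
                       latent_sd = 1.8, latent_cor = 0.4,
                       beta_drive_coverage = 0.006,
                       beta_interest_coverage = -0.002,
                       beta_interest_scan = 0.005,
                       beta_curiosity_scan = 0,
                       beta_duration_path = 0.0015,
                       beta_duration_head = 0.001,
                       intercept_path = 0.42, intercept_head = 0.58,
                       trait_moderation = 0.004,
                       trait_means = c(JE = 4.8, DS = 4.2, ST = 4.1, TS = 4.3),
                       trait_sd = 0.8, trait_cor = 0.3,
                       map_intercept = 3.0,
                       map_beta_curiosity = 0.066,
                       map_beta_coverage = 0.8,
                       resid_cor = 0.3,
                       noise_sds = list(),
                       seed = 1L) {
  sds <- utils::modifyList(
    list(path_resid = 0.08, head_resid = 0.05,
         person_path = 0.05, person_head = 0.04,
         slope_c_path = 0.002, slope_i_head = 0.0015,
         person_map = 0.35, map_resid = 0.4,
         dim_sd = 0.2, rater_sd = 0.32),
    noise_sds
  )
  if (hz <= 0) stop("hz must be positive")
  if (speed_mps <= 0) stop("speed_mps must be positive")
  if (any(unlist(sds) < 0)) stop("noise SDs must be non-negative")
  if (duration_mean_s <= 0 || duration_sd_s < 0) stop("invalid duration spec")
  cfg <- as.list(environment())
  cfg$noise_sds <- sds
  cfg$n_participants <- as.integer(n_participants)
  cfg$n_rooms <- as.integer(n_rooms)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d participants x %d rooms, %g Hz, seed %d\n",
              x$n_participants, x$n_rooms, x$hz, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mechanistic agent: correlated random walk with drive-scaled revisit
# avoidance and home-base attraction, plus scan-rate-scaled head motion.
# ---------------------------------------------------------------------------

#' Simulate an exploring agent in a room
#'
#' A correlated random walk at fixed speed, confined to the accessible
#' cells of `room`. The agent re-chooses its heading every 0.1 s among
#' candidate directions weighted by (i) persistence, (ii) avoidance of
#' already-visited cells, whose weight grows with `drive`, and (iii) for
#' low drive, attraction back towards the entry. Head direction is a
#' bounded random walk whose angular diffusion grows with `scan_rate`.
#' Higher drive therefore yields broader spatial coverage (higher path
#' roaming entropy); higher scan rate yields broader angular coverage.
#'
#' @param room a [room_grid()].
#' @param drive curiosity drive on the 1-10 rating scale.
#' @param scan_rate scanning intensity on the 1-10 rating scale.
#' @param duration_s trial length in seconds.
#' @param hz,speed_mps kinematics (defaults match [sim_config()]).
#' @param seed integer seed; the walk is deterministic given it.
#' @return Tibble with columns `t`, `x`, `y`, `yaw`, `pitch`.
#' @export
simulate_trajectory <- function(room, drive, scan_rate, duration_s,
                                hz = 60, speed_mps = 3.4, seed = 1L) {
  stopifnot(inherits(room, "room_grid"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (!is.finite(drive) || !is.finite(scan_rate)) {
    stop("drive and scan_rate must be finite")
  }
  n <- max(2L, as.integer(round(duration_s * hz)))
  old <- local_rng(seed)
  on.exit(restore_rng(old))

  nc <- room$n_cells_side
  cell_m <- room$cell_m
  acc <- room$accessible
  start <- nearest_accessible(room, entry_cell(nc))
  pos <- c((start[2] - 0.5) * cell_m, (start[1] - 0.5) * cell_m)
  entry_xy <- pos
  heading <- 90  # facing into the room (north)

  sub <- 6L                     # samples per heading decision (0.1 s)
  step <- speed_mps / hz
  n_dec <- ceiling(n / sub)
  visits <- matrix(0, nc, nc)   # seconds of occupancy per cell
  w_avoid <- 0.25 * drive            # per second of prior occupancy
  w_home <- 0.8 * max(0, 5.5 - drive)  # per metre from the entry
  p_pause <- 0.02 + 0.04 * max(0, 6 - drive)
  cand_turn <- c(0, -30, 30, -70, 70, -120, 120, 180)

  xs <- numeric(n_dec * sub); ys <- numeric(n_dec * sub)
  i <- 0L
  for (d in seq_len(n_dec)) {
    move <- stats::runif(1) > p_pause
    chosen <- NULL
    if (move) {
      turns <- cand_turn + stats::rnorm(length(cand_turn), 0, 8)
      w <- numeric(length(turns))
      ends <- vector("list", length(turns))
      for (j in seq_along(turns)) {
        ang <- (heading + turns[j]) * pi / 180
        dxy <- c(cos(ang), sin(ang)) * step
        pts_x <- pos[1] + dxy[1] * seq_len(sub)
        pts_y <- pos[2] + dxy[2] * seq_len(sub)
        cc <- coord_ok(pts_x, pts_y, acc, cell_m, nc, room$side_m)
        if (!cc$ok) { w[j] <- 0; next }
        end_cell <- cc$end_cell
        d_new <- sqrt((pts_x[sub] - entry_xy[1])^2 +
                        (pts_y[sub] - entry_xy[2])^2)
        w[j] <- exp(1.2 * cos(turns[j] * pi / 180)) *
          exp(-w_avoid * visits[end_cell[1], end_cell[2]]) *
          exp(-w_home * d_new)
        ends[[j]] <- list(x = pts_x, y = pts_y, cell = end_cell)
      }
      if (sum(w) > 0) {
        ci <- sample.int(length(w), 1, prob = w)
        chosen <- ends[[ci]]
        heading <- wrap180(heading + turns[ci])
      }
    }
    if (is.null(chosen)) {   # pause (or fully blocked)
      xs[i + seq_len(sub)] <- pos[1]
      ys[i + seq_len(sub)] <- pos[2]
    } else {
      xs[i + seq_len(sub)] <- chosen$x
      ys[i + seq_len(sub)] <- chosen$y
      pos <- c(chosen$x[sub], chosen$y[sub])
    }
    cell <- c(coord_to_cell(pos[2], cell_m, nc), coord_to_cell(pos[1], cell_m, nc))
    visits[cell[1], cell[2]] <- visits[cell[1], cell[2]] + sub / hz
    i <- i + sub
  }
  xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]

  sd_yaw <- 0.5 + 0.35 * scan_rate
  yaw <- wrap180(cumsum(c(0, stats::rnorm(n - 1, 0, sd_yaw))))
  sd_pitch <- 0.1 + 0.06 * scan_rate
  pitch <- numeric(n)
  for (tt in 2:n) {
    pitch[tt] <- max(-90, min(90, 0.98 * pitch[tt - 1] +
                                stats::rnorm(1, 0, sd_pitch)))
  }
  tibble::tibble(t = (seq_len(n) - 1) / hz, x = xs, y = ys,
                 yaw = yaw, pitch = pitch)
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

nearest_accessible <- function(room, cell) {
  if (room$accessible[cell[1], cell[2]]) return(cell)
  idx <- which(room$accessible, arr.ind = TRUE)
  d <- (idx[, 1] - cell[1])^2 + (idx[, 2] - cell[2])^2
  as.integer(idx[which.min(d), ])
}

coord_ok <- function(xs, ys, acc, cell_m, nc, side_m) {
  if (any(xs < 0 | xs > side_m | ys < 0 | ys > side_m)) {
    return(list(ok = FALSE))
  }
  rows <- coord_to_cell(ys, cell_m, nc)
  cols <- coord_to_cell(xs, cell_m, nc)
  if (!all(acc[cbind(rows, cols)])) return(list(ok = FALSE))
  list(ok = TRUE, end_cell = c(rows[length(rows)], cols[length(cols)]))
}

# ---------------------------------------------------------------------------
# Constructive trajectory synthesis: build a kinematically valid walk whose
# occupancy histogram realises a requested roaming entropy near-exactly.
# Used by generate_cohort() so that downstream model coefficients have an
# exactly known ground truth.
# ---------------------------------------------------------------------------

entropy_bits <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

round_preserve_sum <- function(x, total) {
  base <- floor(x)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    ord <- order(x - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(x - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

# Integer counts c >= floors with sum(floors) + extra samples, entropy close
# to H_target bits. Interpolates between the max-entropy (water-filled) and
# min-entropy (concentrated) allocations, then refines by single-sample moves.
solve_counts <- function(floors, extra, H_target, tol = 5e-4) {
  m <- length(floors)
  n <- sum(floors) + extra
  if (m == 1) return(as.integer(n))
  # water-fill
  lo <- min(floors); hi <- max(floors) + extra
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(pmax(mid - floors, 0)) > extra) hi <- mid else lo <- mid
  }
  c_wf <- floors + round_preserve_sum(pmax(lo - floors, 0), extra)
  c_con <- floors
  c_con[which.max(floors)] <- c_con[which.max(floors)] + extra
  H_wf <- entropy_bits(c_wf); H_con <- entropy_bits(c_con)
  if (H_target >= H_wf) {
    counts <- c_wf
  } else if (H_target <= H_con) {
    counts <- c_con
  } else {
    lambdas <- seq(0, 1, length.out = 41)
    best <- NULL; best_gap <- Inf
    for (l in lambdas) {
      d <- round_preserve_sum(l * (c_wf - floors) + (1 - l) * (c_con - floors),
                              extra)
      cc <- floors + pmax(d, 0)
      gap <- abs(entropy_bits(cc) - H_target)
      if (gap < best_gap) { best_gap <- gap; best <- cc }
    }
    counts <- best
  }
  # single-sample refinement (respecting the transit floors)
  for (it in 1:400) {
    H <- entropy_bits(counts)
    if (abs(H - H_target) < tol) break
    movable <- counts > floors
    if (H < H_target) {
      from <- which(movable)[which.max(counts[movable])]
      to <- which.min(counts)
    } else {
      cand <- which(movable & counts < max(counts))
      if (length(cand) == 0) break
      from <- cand[which.min(counts[cand])]
      to <- which.max(counts)
    }
    if (from == to) break
    new_counts <- counts
    new_counts[from] <- new_counts[from] - 1L
    new_counts[to] <- new_counts[to] + 1L
    if (abs(entropy_bits(new_counts) - H_target) >= abs(H - H_target)) break
    counts <- new_counts
  }
  as.integer(counts)
}

grid_neighbours <- function(lin, nr, nc, allowed = NULL) {
  r <- (lin - 1L) %% nr + 1L
  cl <- (lin - 1L) %/% nr + 1L
  out <- integer(0)
  if (r > 1) out <- c(out, lin - 1L)
  if (r < nr) out <- c(out, lin + 1L)
  if (cl > 1) out <- c(out, lin - nr)
  if (cl < nc) out <- c(out, lin + nr)
  if (!is.null(allowed)) out <- out[allowed[out]]
  out
}

# Random compact connected region of m cells grown from `start`
grow_region <- function(start, m, nr, nc, allowed = NULL) {
  region <- logical(nr * nc)
  region[start] <- TRUE
  frontier <- grid_neighbours(start, nr, nc, allowed)
  size <- 1L
  while (size < m && length(frontier) > 0) {
    pick <- frontier[sample.int(length(frontier), 1)]
    frontier <- frontier[frontier != pick]
    if (region[pick]) next
    region[pick] <- TRUE
    size <- size + 1L
    nb <- grid_neighbours(pick, nr, nc, allowed)
    frontier <- unique(c(frontier, nb[!region[nb]]))
  }
  which(region)
}

# Randomised DFS over the region's grid graph; returns the cell sequence
# walked, including backtracking steps (consecutive cells are 4-adjacent).
dfs_walk <- function(region, start, nr, nc) {
  inr <- logical(nr * nc); inr[region] <- TRUE
  seen <- logical(nr * nc); seen[start] <- TRUE
  path <- integer(2 * length(region)); path[1] <- start; np <- 1L
  stack <- start
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    nb <- grid_neighbours(cur, nr, nc, inr)
    nb <- nb[!seen[nb]]
    if (length(nb) > 0) {
      nxt <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
      seen[nxt] <- TRUE
      stack <- c(stack, nxt)
      np <- np + 1L; path[np] <- nxt
    } else {
      stack <- stack[-length(stack)]
      if (length(stack) > 0) { np <- np + 1L; path[np] <- stack[length(stack)] }
    }
  }
  path[seq_len(np)]
}

# Build one trial whose path and head-direction roaming entropies match the
# requested targets as closely as the trial length permits.
synth_trajectory <- function(room, path_re, head_re, duration_s,
                             hz = 60, speed_mps = 3.4) {
  n <- max(30L, as.integer(round(duration_s * hz)))
  nc <- room$n_cells_side
  k <- room$k_accessible
  acc_vec <- as.vector(room$accessible)
  start <- nearest_accessible(room, entry_cell(nc))
  start_lin <- start[1] + (start[2] - 1L) * nc

  # ---- path: transit costs 9 samples per 0.5 m move (4 depart, 5 arrive)
  Hp <- min(max(path_re, 0), 1) * log2(k)
  m <- min(max(2L, as.integer(ceiling(2^Hp * 1.3))), k,
           max(2L, floor(n / 14)))
  for (attempt in 1:6) {
    region <- grow_region(start_lin, m, nc, nc, acc_vec)
    walk <- dfs_walk(region, start_lin, nc, nc)
    transit <- 9L * (length(walk) - 1L)
    if (n - 1L - transit >= max(1, round(0.06 * n)) || m <= 2L) break
    m <- max(2L, as.integer(ceiling(m * 0.75)))
  }
  floors <- integer(length(region))
  idx <- match(walk, region)
  floors[idx[1]] <- 1L
  if (length(walk) > 1) {
    dep <- tabulate(idx[-length(idx)], nbins = length(region))
    arr <- tabulate(idx[-1], nbins = length(region))
    floors <- floors + 4L * dep + 5L * arr
  }
  extra <- n - sum(floors)
  counts <- solve_counts(floors, extra, Hp)
  dwell <- counts - floors
  cx <- ((region - 1L) %/% nc + 1L - 0.5) * room$cell_m   # column -> x
  cy <- ((region - 1L) %% nc + 1L - 0.5) * room$cell_m    # row -> y
  xs <- vector("list", 2L * length(walk)); ys <- xs
  seen <- logical(length(region)); nb <- 0L
  emit <- function(vx, vy) {
    nb <<- nb + 1L
    xs[[nb]] <<- vx; ys[[nb]] <<- vy
  }
  j1 <- idx[1]
  emit(rep(cx[j1], 1L + dwell[j1]), rep(cy[j1], 1L + dwell[j1]))
  seen[j1] <- TRUE
  if (length(walk) > 1) {
    for (s in 2:length(walk)) {
      a <- idx[s - 1]; b <- idx[s]
      f <- (1:9) / 9
      emit(cx[a] + f * (cx[b] - cx[a]), cy[a] + f * (cy[b] - cy[a]))
      if (!seen[b]) {
        seen[b] <- TRUE
        if (dwell[b] > 0) emit(rep(cx[b], dwell[b]), rep(cy[b], dwell[b]))
      }
    }
  }
  x <- unlist(xs[seq_len(nb)]); y <- unlist(ys[seq_len(nb)])
  path_counts <- counts
  realized_path <- entropy_bits(counts) / log2(k)

  # ---- head: 18 x 36 bin grid, transit costs 1 sample per 10-degree move
  kh <- 648L
  Hh <- min(max(head_re, 0), 1) * log2(kh)
  start_h <- 10L + (19L - 1L) * 18L   # pitch ~ 0, yaw ~ 0
  mh <- min(max(2L, as.integer(ceiling(2^Hh * 1.3))), kh,
            max(2L, floor(n / 3)))
  region_h <- grow_region(start_h, mh, 18L, 36L)
  walk_h <- dfs_walk(region_h, start_h, 18L, 36L)
  idx_h <- match(walk_h, region_h)
  floors_h <- tabulate(idx_h, nbins = length(region_h))
  extra_h <- n - sum(floors_h)
  if (extra_h < 0) {  # extremely short trial: truncate the walk
    walk_h <- walk_h[seq_len(n)]
    idx_h <- match(walk_h, region_h)
    floors_h <- tabulate(idx_h, nbins = length(region_h))
    extra_h <- n - sum(floors_h)
  }
  counts_h <- solve_counts(floors_h, extra_h, Hh)
  dwell_h <- counts_h - floors_h
  yawc <- ((region_h - 1L) %/% 18L + 1L - 0.5) * 10 - 180
  pitc <- ((region_h - 1L) %% 18L + 1L - 0.5) * 10 - 90
  yaws <- vector("list", 2L * length(walk_h)); pits <- yaws
  seen_h <- logical(length(region_h)); nbh <- 0L
  emit_h <- function(vy, vp) {
    nbh <<- nbh + 1L
    yaws[[nbh]] <<- vy; pits[[nbh]] <<- vp
  }
  h1 <- idx_h[1]
  emit_h(rep(yawc[h1], 1L + dwell_h[h1]), rep(pitc[h1], 1L + dwell_h[h1]))
  seen_h[h1] <- TRUE
  if (length(walk_h) > 1) {
    for (s in 2:length(walk_h)) {
      b <- idx_h[s]
      extra_rep <- if (!seen_h[b]) dwell_h[b] else 0L
      seen_h[b] <- TRUE
      emit_h(rep(yawc[b], 1L + extra_rep), rep(pitc[b], 1L + extra_rep))
    }
  }
  yaw <- unlist(yaws[seq_len(nbh)]); pitch <- unlist(pits[seq_len(nbh)])
  realized_head <- entropy_bits(counts_h) / log2(kh)

  stopifnot(length(x) == n, length(yaw) == n)
  list(
    samples = tibble::tibble(t = (seq_len(n) - 1) / hz, x = x, y = y,
                             yaw = yaw, pitch = pitch),
    path_re = realized_path, head_re = realized_head,
    path_counts = path_counts, head_counts = counts_h
  )
}

# ---------------------------------------------------------------------------
# Cohort generator
# ---------------------------------------------------------------------------

#' Generate a full synthetic cohort with a known ground truth
#'
#' Simulates rooms, participants, trial latents, ratings, durations,
#' trajectories, trait scores and two-rater sketch scores. Trial-level
#' path and head-direction roaming entropies are drawn from a linear
#' bivariate model (participant intercepts, participant slope
#' deviations, correlated trial residuals) whose coefficients are the
#' configuration's `beta_*` values; each trial's trajectory is then
#' synthesised so that its occupancy histograms realise those entropies
#' (see the methods vignette). Sketch scores depend linearly on the
#' curiosity rating and the realised path RE. Every coefficient used is
#' returned in `ground_truth`.
#'
#' All noise is drawn before any coefficient is applied, so two
#' configurations differing only in a `beta_*` value share identical
#' noise realisations.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `rooms` (named list of [room_grid()]),
#'   `trajectories`, `ratings`, `traits`, `sketch_scores`, `latents`
#'   (per-trial table incl. target and realised RE) and `ground_truth`.
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- local_rng(cfg$seed)
  on.exit(restore_rng(old))
  P <- cfg$n_participants; R <- cfg$n_rooms; N <- P * R
  sds <- cfg$noise_sds
  pid <- sprintf("p%02d", seq_len(P))
  rid <- sprintf("room%02d", seq_len(R))

  rooms <- lapply(seq_len(R), function(r) {
    generate_room(seed = (cfg$seed * 131L + r) %% .Machine$integer.max,
                  occlusion_fraction = cfg$occlusion_fraction,
                  room_id = rid[r])
  })
  names(rooms) <- rid

  # --- stage A: all random draws, none depending on any beta ---------------
  traits <- draw_traits(P, cfg)
  zp <- mvn2(P, cfg$person_rating_sd, cfg$person_rating_sd,
             cfg$person_rating_cor)
  mu_c <- zp[, 1]; mu_i <- zp[, 2]
  u_path <- stats::rnorm(P, 0, sds$person_path)
  u_head <- stats::rnorm(P, 0, sds$person_head)
  u_map <- stats::rnorm(P, 0, sds$person_map)
  s_c_path <- stats::rnorm(P, 0, sds$slope_c_path)
  s_i_head <- stats::rnorm(P, 0, sds$slope_i_head)

  zt <- mvn2(N, cfg$latent_sd, cfg$latent_sd, cfg$latent_cor)
  et <- mvn2(N, sds$path_resid, sds$head_resid, cfg$resid_cor)
  e_map <- stats::rnorm(N, 0, sds$map_resid)
  e_dim <- matrix(stats::rnorm(N * 4, 0, sds$dim_sd), N, 4)
  e_rater <- array(stats::rnorm(N * 4 * 2, 0, sds$rater_sd), c(N, 4, 2))
  sdl <- sqrt(log(1 + (cfg$duration_sd_s / cfg$duration_mean_s)^2))
  mnl <- log(cfg$duration_mean_s) - sdl^2 / 2
  durations <- pmin(pmax(stats::rlnorm(N, mnl, sdl),
                         cfg$duration_range_s[1]), cfg$duration_range_s[2])
  trial_seeds <- sample.int(.Machine$integer.max - 1L, N)

  p_of <- rep(seq_len(P), each = R)
  r_of <- rep(seq_len(R), times = P)

  # --- stage B: apply the generative model ---------------------------------
  c_lat <- cfg$rating_mean + mu_c[p_of] + zt[, 1]
  i_lat <- cfg$rating_mean + mu_i[p_of] + zt[, 2]
  curiosity <- pmin(pmax(round(c_lat), 1), 10)
  interest <- pmin(pmax(round(i_lat), 1), 10)

  slope_c <- cfg$beta_drive_coverage +
    cfg$trait_moderation * (traits$trait_ST - cfg$trait_means[["ST"]]) +
    s_c_path
  slope_i <- cfg$beta_interest_scan + s_i_head
  cw0 <- curiosity - cfg$rating_mean
  iw0 <- interest - cfg$rating_mean
  dw0 <- durations - cfg$duration_mean_s
  path_target <- cfg$intercept_path + slope_c[p_of] * cw0 +
    cfg$beta_interest_coverage * iw0 + cfg$beta_duration_path * dw0 +
    u_path[p_of] + et[, 1]
  head_target <- cfg$intercept_head + slope_i[p_of] * iw0 +
    cfg$beta_curiosity_scan * cw0 + cfg$beta_duration_head * dw0 +
    u_head[p_of] + et[, 2]
  path_target <- pmin(pmax(path_target, 0.03), 0.97)
  head_target <- pmin(pmax(head_target, 0.03), 0.97)

  traj_list <- vector("list", N)
  path_real <- numeric(N); head_real <- numeric(N)
  for (ti in seq_len(N)) {
    olds <- local_rng(trial_seeds[ti])
    tr <- synth_trajectory(rooms[[r_of[ti]]], path_target[ti], head_target[ti],
                           durations[ti], hz = cfg$hz,
                           speed_mps = cfg$speed_mps)
    restore_rng(olds)
    path_real[ti] <- tr$path_re; head_real[ti] <- tr$head_re
    traj_list[[ti]] <- tibble::tibble(
      participant_id = pid[p_of[ti]], room_id = rid[r_of[ti]], tr$samples
    )
  }
  trajectories <- dplyr::bind_rows(traj_list)

  map_raw <- cfg$map_intercept +
    cfg$map_beta_curiosity * (curiosity - cfg$rating_mean) +
    cfg$map_beta_coverage * (path_real - cfg$intercept_path) +
    u_map[p_of] + e_map
  dim_lat <- map_raw + e_dim                        # N x 4
  sketch <- lapply(1:2, function(rt) {
    obs <- pmin(pmax(round((dim_lat + e_rater[, , rt]) * 2) / 2, 1), 5)
    tibble::tibble(participant_id = pid[p_of], room_id = rid[r_of],
                   rater_id = paste0("rater", rt),
                   OP = obs[, 1], SD = obs[, 2], RP = obs[, 3], SP = obs[, 4])
  })
  sketch_scores <- dplyr::bind_rows(sketch) |>
    dplyr::arrange(.data$participant_id, .data$room_id, .data$rater_id)

  n_samp <- as.integer(round(durations * cfg$hz))
  n_samp <- pmax(n_samp, 30L)
  ratings <- tibble::tibble(participant_id = pid[p_of], room_id = rid[r_of],
                            curiosity = as.integer(curiosity),
                            interest = as.integer(interest),
                            duration_s = n_samp / cfg$hz)
  latents <- tibble::tibble(
    participant_id = pid[p_of], room_id = rid[r_of],
    curiosity_drive = c_lat, interest_level = i_lat,
    path_re_target = path_target, head_re_target = head_target,
    path_re = path_real, head_re = head_real,
    map_score_latent = map_raw
  )

  ground_truth <- list(
    beta_curiosity_path = cfg$beta_drive_coverage,
    beta_interest_path = cfg$beta_interest_coverage,
    beta_curiosity_head = cfg$beta_curiosity_scan,
    beta_interest_head = cfg$beta_interest_scan,
    beta_duration_path = cfg$beta_duration_path,
    beta_duration_head = cfg$beta_duration_head,
    contrast_curiosity = cfg$beta_drive_coverage - cfg$beta_curiosity_scan,
    contrast_interest = cfg$beta_interest_coverage - cfg$beta_interest_scan,
    resid_cor = cfg$resid_cor,
    trait_moderation_ST = cfg$trait_moderation,
    map_beta_curiosity = cfg$map_beta_curiosity,
    map_beta_path_re = cfg$map_beta_coverage,
    map_beta_interest = 0,
    map_beta_head_re = 0,
    mediation_a = cfg$beta_drive_coverage,
    mediation_b = cfg$map_beta_coverage,
    indirect_effect = cfg$beta_drive_coverage * cfg$map_beta_coverage,
    noise_sds = sds,
    seed = cfg$seed,
    n_participants = P, n_rooms = R
  )

  list(rooms = rooms, trajectories = trajectories, ratings = ratings,
       traits = traits, sketch_scores = sketch_scores, latents = latents,
       ground_truth = ground_truth)
}

draw_traits <- function(P, cfg) {
  mu <- cfg$trait_means
  S <- matrix(cfg$trait_cor, 4, 4); diag(S) <- 1
  S <- S * cfg$trait_sd^2
  L <- chol(S)
  z <- matrix(stats::rnorm(P * 4), P, 4) %*% L
  vals <- sweep(z, 2, mu, "+")
  vals <- pmin(pmax(round(vals, 2), 1), 7)
  tibble::tibble(participant_id = sprintf("p%02d", seq_len(P)),
                 trait_JE = vals[, 1], trait_DS = vals[, 2],
                 trait_ST = vals[, 3], trait_TS = vals[, 4])
}

mvn2 <- function(n, sd1, sd2, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(sd1 * z1, sd2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Write a synthetic cohort to disk
#'
#' Emits the CSV and mask files consumed by the I/O layer, plus the
#' ground-truth record as YAML (`ground_truth.yml`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  write_trajectories(cohort$trajectories, file.path(dir, "trajectories.csv"))
  readr::write_csv(cohort$ratings, file.path(dir, "ratings.csv"))
  readr::write_csv(cohort$traits, file.path(dir, "traits.csv"))
  readr::write_csv(cohort$sketch_scores, file.path(dir, "sketch_scores.csv"))
  for (room in cohort$rooms) {
    write_mask(room, file.path(dir, "masks", paste0(room$room_id, ".txt")))
  }
  gt <- cohort$ground_truth
  gt$noise_sds <- lapply(gt$noise_sds, as.numeric)
  yaml::write_yaml(gt, file.path(dir, "ground_truth.yml"))
  invisible(dir)
}
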