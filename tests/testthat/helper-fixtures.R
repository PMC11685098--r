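# Shared fixtures. Expensive objects (the study-scale cohort and its model
# fits) are built once per test run and cached.

the <- new.env(parent = emptyenv())

# study-scale synthetic cohort at generator defaults (60 participants x 16
# rooms); the seed is fixed once for the whole suite
study_cohort <- function() {
  if (is.null(the$cohort)) the$cohort <- generate_cohort(sim_config(seed = 1L))
  the$cohort
}

study_design <- function() {
  if (is.null(the$design)) {
    coh <- study_cohort()
    re <- compute_re(coh$trajectories, coh$rooms)
    comp <- sketch_composite(coh$sketch_scores)
    the$re <- re
    the$design <- build_design(
      join_trials(re, coh$ratings, traits = coh$traits, composites = comp))
  }
  the$design
}

study_exploration_fit <- function() {
  if (is.null(the$fit)) {
    the$fit <- fit_exploration_model(study_design(),
                                     preset = sampler_preset("reduced"),
                                     seed = 1L)
  }
  the$fit
}

# small, quick cohort for operation-level tests (short trials for speed)
small_cohort <- function() {
  if (is.null(the$small)) {
    the$small <- generate_cohort(small_config())
  }
  the$small
}

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 8L, n_rooms = 6L, duration_mean_s = 15,
         duration_sd_s = 5, duration_range_s = c(8, 40), seed = 11L),
    list(...))
  do.call(sim_config, args)
}

small_design <- function() {
  if (is.null(the$small_design)) {
    coh <- small_cohort()
    re <- compute_re(coh$trajectories, coh$rooms)
    comp <- sketch_composite(coh$sketch_scores)
    the$small_design <- build_design(
      join_trials(re, coh$ratings, traits = coh$traits, composites = comp))
  }
  the$small_design
}

open_room <- function(n = 4, cell_m = 0.5, room_id = "toy") {
  room_grid(matrix(TRUE, n, n), room_id = room_id, cell_m = cell_m)
}

# minimal sample table builder
samples_at <- function(x, y, yaw = 0, pitch = 0, hz = 60) {
  n <- max(length(x), length(y), length(yaw), length(pitch))
  tibble::tibble(t = (seq_len(n) - 1) / hz,
                 x = rep_len(x, n), y = rep_len(y, n),
                 yaw = rep_len(yaw, n), pitch = rep_len(pitch, n))
}

# independent brute-force normalized entropy (naive summation)
naive_re <- function(counts, k) {
  n <- sum(counts)
  acc <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / n
      acc <- acc - p * log2(p)
    }
  }
  acc / log2(k)
}
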