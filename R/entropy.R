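#' Roaming entropy
#'
#' Roaming entropy (RE) quantifies how evenly an agent's time is spread
#' over a discrete bin space: the Shannon entropy (base 2) of the
#' empirical occupancy distribution, divided by `log2(k)` where `k` is
#' the number of available bins. RE is 0 when all samples fall in one
#' bin and 1 when occupancy is uniform over all `k` bins.
#'
#' Two bin spaces are used: *path* RE over the accessible 0.5 m cells of
#' a room (`k` = number of accessible cells), and *head-direction* RE
#' over an 18 x 36 grid of 10-degree pitch x yaw bins (`k` = 648,
#' independent of which bins are visited).
#'
#' @param hist an `occupancy_histogram` as returned by [bin_path()] or
#'   [bin_head()], or any list with integer `counts` and scalar `k`.
#' @return A number in `[0, 1]`.
#' @export
roaming_entropy <- function(hist) {
  counts <- hist$counts
  k <- hist$k
  if (any(counts < 0)) stop("negative occupancy counts")
  n <- sum(counts)
  if (n < 1) stop("empty occupancy histogram")
  if (k < 1) stop("k must be >= 1")
  if (k == 1) return(0)          # degenerate bin space: no roaming freedom
  p <- counts[counts > 0] / n
  -sum(p * log2(p)) / log2(k)
}

new_occupancy_histogram <- function(counts, k, n_used, n_dropped, space) {
  structure(
    list(counts = counts, k = k, n_samples_used = n_used,
         n_samples_dropped = n_dropped, space = space),
    class = "occupancy_histogram"
  )
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("<occupancy_histogram: %s> k = %d bins, %d samples used, %d dropped, %d bins occupied\n",
              x$space, x$k, x$n_samples_used, x$n_samples_dropped,
              sum(x$counts > 0)))
  invisible(x)
}

# metric coordinate -> 1-based cell index; coord == side_m clamps into the
# last cell so boundary samples are kept (half-open cells elsewhere)
coord_to_cell <- function(coord, cell_m, n_cells) {
  pmin(as.integer(floor(coord / cell_m)) + 1L, n_cells)
}

#' Bin trajectory samples onto a room's accessible cells
#'
#' Each sample is mapped to the 0.5 m grid cell containing it; samples
#' landing in inaccessible cells are dropped and counted. The histogram
#' is indexed over the `k_accessible` accessible cells only.
#'
#' @param samples data frame with columns `x`, `y` in metres.
#' @param room a [room_grid()].
#' @return An `occupancy_histogram` with `k = room$k_accessible`.
#' @export
bin_path <- function(samples, room) {
  stopifnot(inherits(room, "room_grid"))
  x <- samples$x; y <- samples$y
  if (length(x) == 0) stop("no samples to bin")
  if (any(x < 0 | x > room$side_m | y < 0 | y > room$side_m)) {
    stop("samples outside room bounds [0, ", room$side_m, "]")
  }
  col <- coord_to_cell(x, room$cell_m, room$n_cells_side)
  row <- coord_to_cell(y, room$cell_m, room$n_cells_side)
  lin <- (col - 1L) * room$n_cells_side + row
  acc_lin <- which(as.vector(room$accessible))  # column-major: row + (col-1)*n
  idx <- match(lin, acc_lin)
  dropped <- sum(is.na(idx))
  if (dropped == length(lin)) stop("all samples fell in inaccessible cells")
  counts <- tabulate(idx[!is.na(idx)], nbins = room$k_accessible)
  new_occupancy_histogram(counts, room$k_accessible,
                          length(lin) - dropped, dropped, "path")
}

#' Bin head-direction samples onto the 18 x 36 angular grid
#'
#' Yaw spans -180 to 180 degrees (36 bins, half-open at +180) and pitch
#' -90 to +90 degrees (18 bins; the closed upper bound +90 is clamped
#' into the top bin). `k` is always 648 regardless of which bins are
#' visited.
#'
#' @param samples data frame with columns `yaw`, `pitch` in degrees.
#' @return An `occupancy_histogram` with `k = 648`.
#' @export
bin_head <- function(samples) {
  yaw <- samples$yaw; pitch <- samples$pitch
  if (length(yaw) == 0) stop("no samples to bin")
  if (any(yaw < -180 | yaw >= 180)) stop("yaw out of range [-180, 180)")
  if (any(pitch < -90 | pitch > 90)) stop("pitch out of range [-90, 90]")
  col <- as.integer(floor((yaw + 180) / 10)) + 1L         # 1..36
  row <- pmin(as.integer(floor((pitch + 90) / 10)) + 1L, 18L)  # 1..18
  counts <- tabulate((col - 1L) * 18L + row, nbins = 648L)
  new_occupancy_histogram(counts, 648L, length(yaw), 0L, "head")
}

#' Path and head-direction roaming entropy of one trial
#'
#' @param samples data frame of trajectory samples (`t`, `x`, `y`,
#'   `yaw`, `pitch`) for one participant x room visit.
#' @param room the [room_grid()] the trial took place in.
#' @param as_percent if `TRUE`, entropies are multiplied by 100.
#' @return A list of class `re_result`: `path_re`, `head_re`,
#'   `path_hist`, `head_hist`, `n_dropped`, `scale`.
#' @export
compute_trial_re <- function(samples, room, as_percent = FALSE) {
  ph <- bin_path(samples, room)
  hh <- bin_head(samples)
  s <- if (as_percent) 100 else 1
  structure(
    list(path_re = s * roaming_entropy(ph),
         head_re = s * roaming_entropy(hh),
         path_hist = ph, head_hist = hh,
         n_dropped = ph$n_samples_dropped,
         scale = if (as_percent) "percent" else "unit"),
    class = "re_result"
  )
}

#' @export
print.re_result <- function(x, ...) {
  cat(sprintf("<re_result> path RE = %.4f, head RE = %.4f (%s scale), %d samples dropped\n",
              x$path_re, x$head_re, x$scale, x$n_dropped))
  invisible(x)
}

#' Per-trial roaming entropy table for a whole dataset
#'
#' @param trajectories tibble of samples with `participant_id`,
#'   `room_id`, `t`, `x`, `y`, `yaw`, `pitch` (as returned by
#'   [read_trajectories()] or [generate_cohort()]).
#' @param rooms named list of [room_grid()] objects keyed by `room_id`.
#' @param as_percent scale switch, see [compute_trial_re()].
#' @return Tibble with one row per participant x room:
#'   `participant_id`, `room_id`, `path_re`, `head_re`, `n_samples`,
#'   `n_dropped`.
#' @export
compute_re <- function(trajectories, rooms, as_percent = FALSE) {
  stopifnot(all(c("participant_id", "room_id", "x", "y", "yaw", "pitch")
                %in% names(trajectories)))
  if (inherits(rooms, "room_grid")) rooms <- stats::setNames(list(rooms), rooms$room_id)
  trajectories |>
    dplyr::group_by(.data$participant_id, .data$room_id) |>
    dplyr::group_modify(function(df, key) {
      room <- rooms[[as.character(key$room_id)]]
      if (is.null(room)) stop("no room mask for room_id '", key$room_id, "'")
      re <- compute_trial_re(df, room, as_percent = as_percent)
      tibble::tibble(path_re = re$path_re, head_re = re$head_re,
                     n_samples = nrow(df), n_dropped = re$n_dropped)
    }) |>
    dplyr::ungroup()
}

#' Cumulative roaming entropy over time
#'
#' Evaluates path RE on the samples up to each requested time, giving an
#' RE-versus-time curve. The per-trial analyses use only the full-trial
#' value; this variant is provided for exploratory plots.
#'
#' @inheritParams compute_trial_re
#' @param at numeric vector of times (seconds); defaults to deciles of
#'   the trial duration.
#' @return Tibble with columns `t` and `path_re`.
#' @export
re_over_time <- function(samples, room, at = NULL) {
  if (is.null(at)) at <- stats::quantile(samples$t, probs = seq(0.1, 1, 0.1))
  at <- unname(as.numeric(at))
  tibble::tibble(
    t = at,
    path_re = vapply(at, function(tt) {
      roaming_entropy(bin_path(samples[samples$t <= tt, , drop = FALSE], room))
    }, numeric(1))
  )
}
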