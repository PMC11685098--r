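#' Read and write trajectory logs
#'
#' Trajectory logs are CSV tables with one row per 60 Hz sample and
#' columns `participant_id`, `room_id`, `t` (seconds from room entry),
#' `x`, `y` (metres, origin at the south-west corner), `yaw` (degrees in
#' `[-180, 180)`, relative to the room's entry direction) and `pitch`
#' (degrees in `[-90, 90]`, 0 = forward). Validation failures name the
#' offending rows.
#'
#' @param path CSV file path.
#' @return A tibble of samples, time-sorted within each
#'   participant x room trial.
#' @export
read_trajectories <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("participant_id", "room_id", "t", "x", "y", "yaw", "pitch")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("trajectory file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  validate_trajectories(df, where = path)
  df |>
    dplyr::arrange(.data$participant_id, .data$room_id, .data$t) |>
    tibble::as_tibble()
}

validate_trajectories <- function(df, where = "trajectories") {
  bad_rows <- function(flag) paste(utils::head(which(flag), 5), collapse = ", ")
  if (any(flag <- df$yaw < -180 | df$yaw >= 180)) {
    stop(where, ": yaw outside [-180, 180) at rows ", bad_rows(flag))
  }
  if (any(flag <- df$pitch < -90 | df$pitch > 90)) {
    stop(where, ": pitch outside [-90, 90] at rows ", bad_rows(flag))
  }
  if (any(flag <- df$x < 0 | df$y < 0)) {
    stop(where, ": negative coordinates at rows ", bad_rows(flag))
  }
  mono <- df |>
    dplyr::group_by(.data$participant_id, .data$room_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$t), .groups = "drop")
  if (any(!mono$ok)) {
    bad <- mono[!mono$ok, ]
    stop(where, ": non-monotone time within trials: ",
         paste(paste(bad$participant_id, bad$room_id, sep = " x "),
               collapse = "; "))
  }
  invisible(df)
}

#' @rdname read_trajectories
#' @param trajectories tibble of samples.
#' @export
write_trajectories <- function(trajectories, path) {
  validate_trajectories(trajectories)
  readr::write_csv(trajectories, path, progress = FALSE)
  invisible(path)
}

#' Read per-trial ratings, trait and sketch-score tables
#'
#' Ratings tables have one row per participant x room with integer
#' `curiosity` and `interest` (1-10) and `duration_s`. Trait tables have
#' one row per participant with the four curiosity subscales
#' (`trait_JE`, `trait_DS`, `trait_ST`, `trait_TS`, each in `[1, 7]`).
#' Sketch-score tables have one row per participant x room x rater with
#' the four rubric dimensions `OP`, `SD`, `RP`, `SP` on the half-point
#' 1-5 scale. Duplicate keys are an error.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_ratings <- function(path) {
  df <- read_keyed(path, c("participant_id", "room_id"),
                   c("curiosity", "interest", "duration_s"))
  check_rating_range(df$curiosity, "curiosity", path)
  check_rating_range(df$interest, "interest", path)
  if (any(df$duration_s <= 0)) stop(path, ": non-positive duration_s")
  df
}

#' @rdname read_ratings
#' @export
read_traits <- function(path) {
  df <- read_keyed(path, "participant_id",
                   c("trait_JE", "trait_DS", "trait_ST", "trait_TS"))
  for (v in c("trait_JE", "trait_DS", "trait_ST", "trait_TS")) {
    if (any(df[[v]] < 1 | df[[v]] > 7 | !is.finite(df[[v]]))) {
      stop(path, ": ", v, " outside [1, 7]")
    }
  }
  df
}

#' @rdname read_ratings
#' @export
read_sketch_scores <- function(path) {
  df <- read_keyed(path, c("participant_id", "room_id", "rater_id"),
                   c("OP", "SD", "RP", "SP"))
  for (v in c("OP", "SD", "RP", "SP")) {
    x <- df[[v]]
    if (any(x < 1 | x > 5 | abs(x * 2 - round(x * 2)) > 1e-9)) {
      stop(path, ": ", v, " must lie on the half-point grid in [1, 5]")
    }
  }
  df
}

read_keyed <- function(path, keys, cols) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(keys, cols), names(df))
  if (length(missing) > 0) {
    stop(path, " is missing columns: ", paste(missing, collapse = ", "))
  }
  dup <- df |> dplyr::count(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(path, ": duplicate keys: ",
         paste(apply(dup[keys], 1, paste, collapse = " x "), collapse = "; "))
  }
  tibble::as_tibble(df)
}

check_rating_range <- function(x, name, where) {
  if (any(x != round(x) | x < 1 | x > 10)) {
    stop(where, ": ", name, " ratings must be integers in [1, 10]")
  }
  invisible(x)
}

#' Assemble trials from trajectory, rating, trait and score tables
#'
#' Inner-joins the per-trial roaming-entropy table (or raw trajectories)
#' with ratings, and optionally traits and sketch composites, on
#' (`participant_id`, `room_id`). Trials missing a rating row are
#' dropped with a warning naming them.
#'
#' @param re_table per-trial table with `participant_id`, `room_id`
#'   (e.g. from [compute_re()]).
#' @param ratings tibble from [read_ratings()].
#' @param traits optional tibble from [read_traits()].
#' @param composites optional tibble from [sketch_composite()].
#' @return One row per retained trial.
#' @export
join_trials <- function(re_table, ratings, traits = NULL, composites = NULL) {
  out <- dplyr::inner_join(re_table, ratings,
                           by = c("participant_id", "room_id"))
  lost <- dplyr::anti_join(re_table, ratings,
                           by = c("participant_id", "room_id"))
  if (nrow(lost) > 0) {
    warning(nrow(lost), " trial(s) without ratings excluded: ",
            paste(utils::head(paste(lost$participant_id, lost$room_id,
                                    sep = " x "), 5), collapse = "; "))
  }
  if (!is.null(traits)) {
    out <- dplyr::inner_join(out, traits, by = "participant_id")
  }
  if (!is.null(composites)) {
    out <- dplyr::inner_join(out, composites,
                             by = c("participant_id", "room_id"))
  }
  out
}
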