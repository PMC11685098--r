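#' Build the centred analysis design
#'
#' Implements the two-level centring used throughout the model stage:
#' each trial-level predictor is split into a within-person deviation
#' (`*_w`, the trial value minus that participant's own mean) carrying
#' intra-individual effects, and a person mean centred at the grand
#' mean (`*_m`) carrying inter-individual effects. Duration is
#' grand-mean centred (`duration_c`); trait scores, when supplied, are
#' grand-mean centred across participants (`*_c`).
#'
#' Trials with missing ratings, RE or (when supplied) composites are
#' dropped listwise with a message; participants contributing a single
#' trial are flagged in the `single_trial` attribute since their
#' within-person deviations are degenerate (identically zero).
#'
#' @param trials joined per-trial table with `participant_id`,
#'   `room_id`, `curiosity`, `interest`, `duration_s`, `path_re`,
#'   `head_re`, optionally trait columns and `composite` (see
#'   [join_trials()]).
#' @return Tibble of class `centred_design` with the original columns
#'   plus `curiosity_w/m`, `interest_w/m`, `path_re_w/m`,
#'   `head_re_w/m`, `duration_c`, `composite_w/m` and `trait_*_c` when
#'   available.
#' @export
build_design <- function(trials) {
  core <- c("curiosity", "interest", "duration_s", "path_re", "head_re")
  missing_cols <- setdiff(c("participant_id", "room_id", core), names(trials))
  if (length(missing_cols) > 0) {
    stop("design input is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  opt <- intersect("composite", names(trials))
  vars <- c(core[core != "duration_s"], opt)
  complete <- stats::complete.cases(trials[c(core, opt)])
  if (any(!complete)) {
    message(sum(!complete), " incomplete trial(s) excluded from the design")
    trials <- trials[complete, , drop = FALSE]
  }
  out <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(vars),
                                list(w = ~ .x - mean(.x), m = ~ mean(.x)))) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      dplyr::across(dplyr::ends_with("_m"), ~ .x - mean(.x)),
      duration_c = .data$duration_s - mean(.data$duration_s)
    )
  traits <- grep("^trait_", names(trials), value = TRUE)
  if (length(traits) > 0) {
    ptab <- out |>
      dplyr::distinct(.data$participant_id,
                      dplyr::pick(dplyr::all_of(traits)))
    for (tr in traits) {
      out[[paste0(tr, "_c")]] <- out[[tr]] - mean(ptab[[tr]])
    }
  }
  single <- out |>
    dplyr::count(.data$participant_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(single) > 0) {
    warning("participant(s) with a single trial have degenerate ",
            "within-person deviations: ",
            paste(single$participant_id, collapse = ", "))
  }
  attr(out, "single_trial") <- single$participant_id
  class(out) <- c("centred_design", class(out))
  out
}

#' Highest posterior density interval
#'
#' The shortest interval containing `ceiling(level * n)` of the sorted
#' draws, found by exhaustive scan over contiguous windows, plus the
#' posterior mean. With 93% as the default level, matching the summary
#' convention of the model stage.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param level interval mass (default 0.93).
#' @return List with `mean`, `lower`, `upper`, `level`.
#' @export
hpdi <- function(draws, level = 0.93) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HPDI, got ", n)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  s <- sort(draws)
  m <- ceiling(level * n)
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  out <- list(mean = mean(draws), lower = s[i], upper = s[i + m - 1],
              level = level)
  if (out$mean < out$lower || out$mean > out$upper) {
    attr(out, "flag") <- "posterior mean outside HPDI (multimodal posterior?)"
  }
  out
}
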