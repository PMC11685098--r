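#' Composite sketch-map precision scores
#'
#' Each sketch map is scored by two raters on four rubric dimensions --
#' Object Presence (OP), Spatial Distortion and Rotation of features
#' (SD), Relative Positioning (RP) and Spatial Proportion (SP) -- on a
#' 1-5 scale in 0.5 steps. The composite precision score of a map is
#' the mean of the four dimension scores after averaging the two
#' raters; it is invariant to rater and dimension order.
#'
#' @param scores tibble with `participant_id`, `room_id`, `rater_id`,
#'   `OP`, `SD`, `RP`, `SP` (one row per map per rater; exactly two
#'   raters per map).
#' @return Tibble with `participant_id`, `room_id`, `composite`.
#' @export
sketch_composite <- function(scores) {
  dims <- c("OP", "SD", "RP", "SP")
  missing <- setdiff(dims, names(scores))
  if (length(missing) > 0) {
    stop("missing rubric dimensions: ", paste(missing, collapse = ", "))
  }
  if (anyNA(scores[dims])) stop("missing dimension scores")
  nr <- scores |>
    dplyr::count(.data$participant_id, .data$room_id) |>
    dplyr::filter(.data$n != 2)
  if (nrow(nr) > 0) {
    stop("each map needs exactly two raters; offending maps: ",
         paste(utils::head(paste(nr$participant_id, nr$room_id, sep = " x "),
                           5), collapse = "; "))
  }
  scores |>
    dplyr::group_by(.data$participant_id, .data$room_id) |>
    dplyr::summarise(
      composite = mean(c(mean(.data$OP), mean(.data$SD),
                         mean(.data$RP), mean(.data$SP))),
      .groups = "drop"
    )
}

#' Inter-rater reliability for one rubric dimension
#'
#' Computes both the Pearson correlation between the two raters' scores
#' across participant x room units and a two-way consistency intraclass
#' correlation, ICC(C,1) (mean squares from the units x raters two-way
#' layout: `(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)` with
#' k = 2 raters). The intraclass form is the headline value.
#'
#' @param scores as in [sketch_composite()].
#' @param dimension one of `"OP"`, `"SD"`, `"RP"`, `"SP"`.
#' @return A list with `icc`, `pearson`, `n_units`, `dimension`.
#' @export
inter_rater_reliability <- function(scores, dimension = c("OP", "SD", "RP", "SP")) {
  dimension <- match.arg(dimension)
  wide <- scores |>
    dplyr::select(dplyr::all_of(c("participant_id", "room_id", "rater_id",
                                  dimension))) |>
    tidyr::pivot_wider(names_from = "rater_id",
                       values_from = dplyr::all_of(dimension))
  raters <- setdiff(names(wide), c("participant_id", "room_id"))
  if (length(raters) != 2) stop("expected exactly two raters, got ",
                                length(raters))
  x <- as.matrix(wide[raters])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 doubly-scored maps")
  if (stats::sd(x[, 1]) == 0 || stats::sd(x[, 2]) == 0) {
    stop("zero variance in a rater's scores: reliability undefined")
  }
  k <- 2
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  ms_rows <- k * sum((row_means - grand)^2) / (n - 1)
  ms_cols <- n * sum((col_means - grand)^2) / (k - 1)
  ss_err <- sum((x - outer(row_means, rep(1, k)) -
                   outer(rep(1, n), col_means) + grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  list(
    icc = (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err),
    pearson = stats::cor(x[, 1], x[, 2]),
    n_units = n,
    dimension = dimension
  )
}

#' Cronbach's alpha with a bootstrap interval
#'
#' Internal consistency of the four rubric dimensions over
#' participant x room units (rater-averaged scores):
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))` with
#' k = 4 items. Uncertainty is a nonparametric bootstrap over units,
#' reported as a percentile interval at the 93% level to parallel the
#' HPDI summaries of the model stage.
#'
#' @param items numeric matrix or data frame, units x items.
#' @param level interval level (default 0.93).
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return List with `alpha`, `lower`, `upper`, `level`, `n_units`.
#' @export
cronbach_alpha <- function(items, level = 0.93, n_boot = 2000, seed = 1L) {
  x <- as.matrix(items)
  if (ncol(x) < 2 || nrow(x) < 3) stop("need >= 3 units and >= 2 items")
  if (anyNA(x)) stop("missing values in item matrix")
  point <- alpha_formula(x)
  if (!is.finite(point)) stop("zero total variance: alpha undefined")
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  boots <- vapply(seq_len(n_boot), function(b) {
    alpha_formula(x[sample.int(nrow(x), replace = TRUE), , drop = FALSE])
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(alpha = point, lower = qs[1], upper = qs[2], level = level,
       n_units = nrow(x))
}

alpha_formula <- function(x) {
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) return(NA_real_)
  item_var <- sum(apply(x, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Rater-averaged dimension matrix
#'
#' Helper producing the units x 4 matrix consumed by
#' [cronbach_alpha()]: one row per participant x room, each dimension
#' averaged over the two raters.
#'
#' @inheritParams sketch_composite
#' @return Tibble with `participant_id`, `room_id`, `OP`, `SD`, `RP`,
#'   `SP`.
#' @export
dimension_matrix <- function(scores) {
  scores |>
    dplyr::group_by(.data$participant_id, .data$room_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("OP", "SD", "RP", "SP")),
                                   mean),
                     .groups = "drop")
}
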