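two_rater_scores <- function(a, b, id = "p01", room = "roomA") {
  tibble::tibble(participant_id = id, room_id = room,
                 rater_id = c("r1", "r2"),
                 OP = c(a[1], b[1]), SD = c(a[2], b[2]),
                 RP = c(a[3], b[3]), SP = c(a[4], b[4]))
}

test_that("composites average raters then dimensions", {
  expect_equal(sketch_composite(two_rater_scores(rep(5, 4),
                                                 rep(5, 4)))$composite, 5)
  expect_equal(sketch_composite(two_rater_scores(rep(3, 4),
                                                 rep(4, 4)))$composite, 3.5)
  # hand-computed: rater means (4.25, 3, 3.25, 3.25), mean = 3.4375
  s <- two_rater_scores(c(4, 3, 3.5, 3), c(4.5, 3, 3, 3.5))
  expect_equal(sketch_composite(s)$composite, 3.4375)
  # invariant to rater order and dimension relabelling
  s_flipped <- s[2:1, ]
  expect_equal(sketch_composite(s_flipped)$composite, 3.4375)
  s_perm <- s
  names(s_perm)[4:7] <- c("RP", "SP", "OP", "SD")
  expect_equal(sketch_composite(s_perm)$composite, 3.4375)
  expect_error(sketch_composite(s[1, ]), "two raters")
  expect_error(sketch_composite(s[-4]), "missing rubric")
})

test_that("reliability is 1 for duplicated raters and ~0 for independence", {
  set.seed(7)
  base <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:20), each = 10),
    room_id = rep(sprintf("room%02d", 1:10), times = 20),
    OP = sample(seq(1, 5, 0.5), 200, TRUE), SD = sample(seq(1, 5, 0.5), 200, TRUE),
    RP = sample(seq(1, 5, 0.5), 200, TRUE), SP = sample(seq(1, 5, 0.5), 200, TRUE))
  dup <- dplyr::bind_rows(
    dplyr::mutate(base, rater_id = "r1"),
    dplyr::mutate(base, rater_id = "r2"))
  r <- inter_rater_reliability(dup, "OP")
  expect_equal(r$icc, 1)
  expect_equal(r$pearson, 1)

  indep <- dplyr::bind_rows(
    dplyr::mutate(base, rater_id = "r1"),
    dplyr::mutate(base, rater_id = "r2",
                  OP = sample(OP), SD = sample(SD),
                  RP = sample(RP), SP = sample(SP)))
  r2 <- inter_rater_reliability(indep, "OP")
  expect_lt(abs(r2$icc), 0.2)
  expect_lt(abs(r2$pearson), 0.2)

  flat <- dplyr::bind_rows(
    dplyr::mutate(base, rater_id = "r1"),
    dplyr::mutate(base, rater_id = "r2", OP = 3))
  expect_error(inter_rater_reliability(flat, "OP"), "zero variance")
})

test_that("adding symmetric rater noise lowers reliability", {
  set.seed(21)
  truth <- rnorm(150, 3, 0.6)
  noisy_scores <- function(sd) {
    tibble::tibble(
      participant_id = rep(sprintf("p%03d", 1:150), 2),
      room_id = "roomA",
      rater_id = rep(c("r1", "r2"), each = 150),
      OP = pmin(pmax(round((truth + rnorm(300, 0, sd)) * 2) / 2, 1), 5),
      SD = 3, RP = 3, SP = 3)
  }
  low <- inter_rater_reliability(noisy_scores(0.1), "OP")$icc
  high <- inter_rater_reliability(noisy_scores(0.8), "OP")$icc
  expect_gt(low, high)
})

test_that("Cronbach's alpha matches an independent covariance formula", {
  # 5-unit toy matrix, alpha from the covariance representation
  m <- matrix(c(3, 3.5, 3, 2.5,
                4, 4.5, 4.5, 4,
                2, 2.5, 2, 2,
                5, 4.5, 5, 4.5,
                3.5, 3, 3.5, 3), nrow = 5, byrow = TRUE)
  C <- stats::cov(m)
  k <- ncol(m)
  alpha_cov <- k / (k - 1) * (1 - sum(diag(C)) / sum(C))
  a <- cronbach_alpha(m, seed = 2)
  expect_equal(a$alpha, alpha_cov, tolerance = 1e-12)
  expect_lte(a$lower, a$alpha)
  expect_gte(a$upper, a$alpha)

  identical_items <- matrix(rep(rnorm(30), 4), ncol = 4)
  expect_equal(cronbach_alpha(identical_items, seed = 1)$alpha, 1)

  set.seed(9)
  indep <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(cronbach_alpha(indep, seed = 1)$alpha), 0.15)

  expect_error(cronbach_alpha(matrix(3, 10, 4)), "zero total variance")
  expect_error(cronbach_alpha(matrix(1, 2, 4)), ">= 3 units")
})

test_that("the rater-averaged dimension matrix feeds alpha correctly", {
  coh <- small_cohort()
  dm <- dimension_matrix(coh$sketch_scores)
  expect_equal(nrow(dm), 8 * 6)
  a <- cronbach_alpha(dm[c("OP", "SD", "RP", "SP")], seed = 5)
  expect_gt(a$alpha, 0.5)
  expect_lt(a$alpha, 1)
})
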