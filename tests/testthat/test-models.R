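trial_stub <- function(curiosity, participant = "p01") {
  n <- length(curiosity)
  tibble::tibble(participant_id = participant,
                 room_id = sprintf("room%02d", seq_len(n)),
                 curiosity = curiosity,
                 interest = rep(5L, n), duration_s = rep(30, n),
                 path_re = seq(0.3, 0.5, length.out = n),
                 head_re = seq(0.5, 0.6, length.out = n))
}

test_that("centring splits predictors into within and between parts", {
  d <- dplyr::bind_rows(trial_stub(c(2, 4, 6), "p01"),
                        trial_stub(c(5, 5, 5), "p02"))
  out <- build_design(d)
  expect_equal(out$curiosity_w[out$participant_id == "p01"], c(-2, 0, 2))
  expect_equal(out$curiosity_w[out$participant_id == "p02"], c(0, 0, 0))
  # grand mean of the person-mean column is zero after centring
  expect_lt(abs(mean(out$curiosity_m)), 1e-12)
  expect_lt(abs(mean(out$duration_c)), 1e-12)
  # adding a constant to a predictor changes nothing in the design
  d2 <- dplyr::mutate(d, curiosity = curiosity + 3)
  out2 <- build_design(d2)
  expect_equal(out2$curiosity_w, out$curiosity_w, tolerance = 1e-12)
  expect_equal(out2$curiosity_m, out$curiosity_m, tolerance = 1e-12)
})

test_that("degenerate design inputs are flagged or dropped", {
  d <- dplyr::bind_rows(trial_stub(c(2, 4, 6), "p01"),
                        trial_stub(5L, "p02"))
  expect_warning(out <- build_design(d), "single trial")
  expect_equal(attr(out, "single_trial"), "p02")
  d$path_re[2] <- NA
  expect_message(expect_warning(out2 <- build_design(d)), "1 incomplete")
  expect_equal(nrow(out2), 3)
  expect_error(build_design(d[-3]), "missing columns")
})

test_that("the HPDI is the shortest window over sorted draws", {
  # exhaustive-window oracle
  oracle <- function(draws, level) {
    s <- sort(draws)
    m <- ceiling(level * length(s))
    best <- c(Inf, NA, NA)
    for (i in 1:(length(s) - m + 1)) {
      w <- s[i + m - 1] - s[i]
      if (w < best[1]) best <- c(w, s[i], s[i + m - 1])
    }
    best[2:3]
  }
  h <- hpdi(1:100, 0.93)
  expect_equal(c(h$lower, h$upper), oracle(1:100, 0.93))
  expect_equal(h$upper - h$lower, 92)
  set.seed(12)
  skewed <- rexp(5000)
  h2 <- hpdi(skewed, 0.93)
  expect_equal(c(h2$lower, h2$upper), oracle(skewed, 0.93))
  # shorter than (and nested in) the equal-tailed interval for skewed draws
  et <- unname(stats::quantile(skewed, c(0.035, 0.965)))
  expect_lt(h2$upper - h2$lower, et[2] - et[1])
  # near-symmetric draws: HPDI approximates the equal-tailed interval
  z <- rnorm(1e5)
  h3 <- hpdi(z, 0.93)
  et3 <- unname(stats::quantile(z, c(0.035, 0.965)))
  expect_lt(max(abs(c(h3$lower, h3$upper) - et3)), 0.05)
  # agreement with the independent coda implementation
  # coda rounds rather than ceilings the window size: agreement to ~draw spacing
  cd <- coda::HPDinterval(coda::mcmc(z), prob = 0.93)
  expect_lt(abs(h3$lower - cd[1, "lower"]), 1e-3)
  expect_lt(abs(h3$upper - cd[1, "upper"]), 1e-3)

  expect_identical(hpdi(rep(2, 500))$upper - hpdi(rep(2, 500))$lower, 0)
  expect_error(hpdi(1:50), "at least 100")
  # nesting across levels
  h50 <- hpdi(skewed, 0.5)
  expect_gte(h50$lower, h2$lower - 1e-12)
  expect_lte(h50$upper, h2$upper + 1e-12)
})

test_that("the exploration model fits, with sane posteriors and diagnostics", {
  fit <- suppressWarnings(
    fit_exploration_model(small_design(), preset = sampler_preset("test"),
                          seed = 3))
  expect_s3_class(fit, "model_fit")
  expect_true(all(is.finite(fit$draws)))
  rc <- fit$summary[fit$summary$parameter == "resid_cor", ]
  expect_gt(rc$mean, -1); expect_lt(rc$mean, 1)
  expect_true(all(!is.na(fit$summary$rhat)))
  expect_true(all(fit$summary$ess > 0))
  expect_true(all(c("b_curiosity_path", "b_interest_head",
                    "sd_intercept_path") %in% fit$summary$parameter))
  the$small_fit <- fit

  # intercept-only fallback drops the slope SD parameters
  fit0 <- suppressWarnings(
    fit_exploration_model(small_design(), preset = sampler_preset("test"),
                          random = "intercepts", seed = 3))
  expect_false("sd_slope_curiosity_path" %in% fit0$summary$parameter)
})

test_that("cross-outcome contrasts are draw-wise linear", {
  fit <- the$small_fit
  if (is.null(fit)) {
    fit <- suppressWarnings(
      fit_exploration_model(small_design(), preset = sampler_preset("test"),
                            seed = 3))
  }
  con <- coefficient_contrast(fit, "b_curiosity")
  expect_equal(con$mean,
               mean(fit$draws[, "b_curiosity_path"]) -
                 mean(fit$draws[, "b_curiosity_head"]), tolerance = 1e-12)
  self <- coefficient_contrast(fit, "b_curiosity", "path", "path")
  expect_identical(self$mean, 0)
  expect_identical(self$upper - self$lower, 0)
  expect_error(coefficient_contrast(fit, "b_nonexistent"), "unknown")
})

test_that("moderation and map models reject unidentifiable inputs", {
  des <- small_design()
  flat <- des
  flat$trait_ST_c <- 0
  expect_error(fit_moderation_model(flat, preset = sampler_preset("test")),
               "constant across participants")
  flat2 <- des
  flat2$composite <- 3
  expect_error(fit_map_model(flat2, preset = sampler_preset("test")),
               "constant")
  expect_error(fit_exploration_model(des[1:5, ]), "at least 2")
  expect_error(fit_exploration_model(tibble::tibble(a = 1)), "build_design")
})

test_that("the mediation indirect effect is the product of draws", {
  med <- suppressWarnings(
    mediation(small_design(), preset = sampler_preset("test"), seed = 6))
  d <- med$fit$draws
  expect_equal(unname(d[, "indirect_effect"]),
               unname(d[, "a_curiosity_to_path_re"] *
                        d[, "b_path_re_to_composite"]), tolerance = 1e-12)
  expect_equal(med$indirect$mean, mean(d[, "indirect_effect"]))
  # the product-of-draws mean differs from the product of means by cov(a, b)
  gap <- mean(d[, "indirect_effect"]) -
    mean(d[, "a_curiosity_to_path_re"]) * mean(d[, "b_path_re_to_composite"])
  co <- stats::cov(d[, "a_curiosity_to_path_re"],
                   d[, "b_path_re_to_composite"])
  expect_equal(gap, co * (nrow(d) - 1) / nrow(d), tolerance = 1e-12)
})

test_that("a severed mediator-outcome link yields a null indirect effect", {
  cfg <- small_config(map_beta_coverage = 0)
  coh <- generate_cohort(cfg)
  re <- compute_re(coh$trajectories, coh$rooms)
  des <- build_design(join_trials(re, coh$ratings,
                                  composites = sketch_composite(coh$sketch_scores)))
  med <- suppressWarnings(
    mediation(des, preset = sampler_preset("test"), seed = 7))
  expect_lte(med$indirect$lower, 0)
  expect_gte(med$indirect$upper, 0)
})
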