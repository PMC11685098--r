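#' Sampler presets
#'
#' `"full"` is the headline setting: 4 chains of 4800 iterations each,
#' half treated as warm-up. `"reduced"` and
#' `"test"` are shorter presets for desk-scale recovery runs and unit
#' tests; diagnostics (split R-hat, effective sample size) are reported
#' for every preset so under-sampled fits are visibly flagged.
#'
#' @param name one of `"full"`, `"reduced"`, `"test"`.
#' @return List with `chains`, `adapt`, `burn`, `sample`.
#' @export
sampler_preset <- function(name = c("reduced", "full", "test")) {
  name <- match.arg(name)
  switch(name,
    full = list(chains = 4L, adapt = 1000L, burn = 1400L, sample = 2400L),
    reduced = list(chains = 2L, adapt = 500L, burn = 500L, sample = 1250L),
    test = list(chains = 2L, adapt = 250L, burn = 250L, sample = 600L)
  )
}

#' Prior settings
#'
#' Normal priors centred at zero for all regression coefficients
#' (`coef_scale` is their SD; intercepts get the wider `intercept_scale`),
#' uniform priors on residual and random-effect SDs, and a uniform
#' prior on the residual correlation of the bivariate model.
#'
#' @param coef_scale SD of the normal prior on slopes.
#' @param intercept_scale SD of the normal prior on intercepts.
#' @param sd_upper upper bound of the uniform priors on SDs.
#' @return List of prior settings.
#' @export
prior_settings <- function(coef_scale = 1, intercept_scale = 5,
                           sd_upper = 2) {
  stopifnot(coef_scale > 0, intercept_scale > 0, sd_upper > 0)
  list(coef_scale = coef_scale, intercept_scale = intercept_scale,
       sd_upper = sd_upper)
}

# --------------------------------------------------------------------------

jags_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = as.integer((seed + 1000L * ch) %% 2147483629L) + 1L)
  })
}

run_jags <- function(model_string, data, params, preset, seed) {
  con <- textConnection(model_string)
  on.exit(close(con))
  jm <- rjags::jags.model(con, data = data, n.chains = preset$chains,
                          n.adapt = preset$adapt, quiet = TRUE,
                          inits = jags_inits(preset$chains, seed))
  stats::update(jm, n.iter = preset$burn, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = params, n.iter = preset$sample,
                      progress.bar = "none")
}

# Rename raw JAGS columns (e.g. "bcw[1]") to semantic names via `map`
# (named character vector: semantic_name = jags_name), summarise and wrap.
new_model_fit <- function(mcmc, map, model, preset, level = 0.93,
                          structural = names(map)) {
  renamed <- lapply(mcmc, function(ch) {
    m <- as.matrix(ch)
    keep <- map[map %in% colnames(m)]
    m <- m[, keep, drop = FALSE]
    colnames(m) <- names(keep)
    coda::mcmc(m, start = stats::start(ch), thin = coda::thin(ch))
  })
  renamed <- coda::mcmc.list(renamed)
  draws <- as.matrix(renamed)
  ess <- coda::effectiveSize(renamed)
  rhat <- if (length(renamed) >= 2) {
    coda::gelman.diag(renamed, multivariate = FALSE,
                      autoburnin = FALSE)$psrf[, 1]
  } else {
    stats::setNames(rep(NA_real_, ncol(draws)), colnames(draws))
  }
  summ <- dplyr::bind_rows(lapply(colnames(draws), function(pn) {
    h <- hpdi(draws[, pn], level = level)
    tibble::tibble(parameter = pn, mean = h$mean,
                   sd = stats::sd(draws[, pn]),
                   hpdi_low = h$lower, hpdi_high = h$upper,
                   rhat = unname(rhat[pn]), ess = unname(ess[pn]))
  }))
  structural <- intersect(structural, colnames(draws))
  bad_rhat <- summ$parameter[!is.na(summ$rhat) & summ$rhat > 1.01 &
                               summ$parameter %in% structural]
  low_ess <- summ$parameter[summ$ess < 400 & summ$parameter %in% structural]
  flagged <- length(bad_rhat) > 0 || length(low_ess) > 0
  if (flagged) {
    warning("convergence flags for ", model, ": ",
            if (length(bad_rhat) > 0)
              paste0("R-hat > 1.01: ", paste(bad_rhat, collapse = ", "), "; "),
            if (length(low_ess) > 0)
              paste0("ESS < 400: ", paste(low_ess, collapse = ", ")),
            call. = FALSE)
  }
  structure(
    list(model = model, summary = summ, draws = draws, mcmc = renamed,
         level = level, preset = preset, structural = structural,
         flagged = flagged),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<model_fit: %s> %d chains x %d draws%s\n", x$model,
              length(x$mcmc), nrow(x$draws) / length(x$mcmc),
              if (x$flagged) " [convergence flags - see warnings]" else ""))
  print(as.data.frame(x$summary), digits = digits, row.names = FALSE)
  invisible(x)
}

# one row per participant (in factor-level order) for person-level covariates
person_table <- function(design, p, cols) {
  first <- match(seq_len(max(p)), p)
  as.list(design[first, cols, drop = FALSE])
}

design_checks <- function(design, need = character()) {
  if (!inherits(design, "centred_design")) {
    stop("fit functions expect a design from build_design()")
  }
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    stop("design lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  p <- as.integer(factor(design$participant_id))
  if (max(p) < 2) stop("need at least 2 participants")
  if (min(table(p)) < 2) stop("every participant needs at least 2 trials")
  p
}

re_terms <- function(random) {
  match.arg(random, c("slopes", "intercepts"))
}

# --------------------------------------------------------------------------

#' Bivariate exploration model
#'
#' Joint Bayesian multilevel regression of path and head-direction
#' roaming entropy on within-person curiosity and interest deviations,
#' their grand-centred person means, and duration, with participant
#' random intercepts (and, by default, random slopes for the
#' within-person predictors) per outcome and correlated residuals
#' across the two outcomes.
#'
#' @param design a [build_design()] result.
#' @param preset sampler preset, see [sampler_preset()].
#' @param priors prior settings, see [prior_settings()].
#' @param random `"slopes"` (participant intercepts + within-predictor
#'   slopes) or `"intercepts"` (intercepts only).
#' @param level HPDI level for the summary table.
#' @param seed RNG seed for the sampler.
#' @return A `model_fit`: posterior summary table (`summary`), named
#'   draw matrix (`draws`), coda object (`mcmc`) and diagnostics flags.
#' @export
fit_exploration_model <- function(design, preset = sampler_preset("reduced"),
                                  priors = prior_settings(),
                                  random = "slopes", level = 0.93,
                                  seed = 1L) {
  random <- re_terms(random)
  p <- design_checks(design, c("curiosity_w", "interest_w", "curiosity_m",
                               "interest_m", "duration_c", "path_re",
                               "head_re"))
  slopes <- random == "slopes"
  # hierarchically centred: participant intercepts are drawn around the
  # person-level regression on the grand-centred person means
  slope_mu <- if (slopes) " + sc[p[i], o] * cw[i] + si[p[i], o] * iw[i]" else ""
  slope_re <- if (slopes) "
      sc[j, o] ~ dnorm(0, pow(sd_sc[o], -2))
      si[j, o] ~ dnorm(0, pow(sd_si[o], -2))" else ""
  slope_pri <- if (slopes) "
    sd_sc[o] ~ dunif(0, sd_up)
    sd_si[o] ~ dunif(0, sd_up)" else ""
  model <- sprintf("
model {
  for (i in 1:N) {
    y[i, 1:2] ~ dmnorm(mu[i, 1:2], Omega)
    for (o in 1:2) {
      mu[i, o] <- up[p[i], o] + bcw[o] * cw[i] + biw[o] * iw[i] +
                  bdur[o] * dur[i]%s
    }
  }
  for (j in 1:P) {
    for (o in 1:2) {
      up[j, o] ~ dnorm(b0[o] + bcm[o] * cmj[j] + bim[o] * imj[j],
                       pow(sd_u[o], -2))%s
    }
  }
  for (o in 1:2) {
    b0[o] ~ dnorm(0, pow(int_sc, -2))
    bcw[o] ~ dnorm(0, prec_b)
    biw[o] ~ dnorm(0, prec_b)
    bcm[o] ~ dnorm(0, prec_b)
    bim[o] ~ dnorm(0, prec_b)
    bdur[o] ~ dnorm(0, prec_b)
    sigma[o] ~ dunif(0, sd_up)
    sd_u[o] ~ dunif(0, sd_up)%s
  }
  rho ~ dunif(-0.999, 0.999)
  Sigma[1, 1] <- sigma[1] * sigma[1]
  Sigma[2, 2] <- sigma[2] * sigma[2]
  Sigma[1, 2] <- rho * sigma[1] * sigma[2]
  Sigma[2, 1] <- Sigma[1, 2]
  Omega <- inverse(Sigma)
  prec_b <- pow(coef_sc, -2)
}", slope_mu, slope_re, slope_pri)
  pt <- person_table(design, p, c("curiosity_m", "interest_m"))
  data <- list(
    N = nrow(design), P = max(p), p = p,
    y = cbind(design$path_re, design$head_re),
    cw = design$curiosity_w, iw = design$interest_w,
    cmj = pt$curiosity_m, imj = pt$interest_m,
    dur = design$duration_c,
    coef_sc = priors$coef_scale, int_sc = priors$intercept_scale,
    sd_up = priors$sd_upper
  )
  params <- c("b0", "bcw", "biw", "bcm", "bim", "bdur", "sigma", "rho",
              "sd_u", if (slopes) c("sd_sc", "sd_si"))
  mcmc <- run_jags(model, data, params, preset, seed)
  map <- c(
    intercept_path = "b0[1]", intercept_head = "b0[2]",
    b_curiosity_path = "bcw[1]", b_curiosity_head = "bcw[2]",
    b_interest_path = "biw[1]", b_interest_head = "biw[2]",
    b_curiosity_m_path = "bcm[1]", b_curiosity_m_head = "bcm[2]",
    b_interest_m_path = "bim[1]", b_interest_m_head = "bim[2]",
    b_duration_path = "bdur[1]", b_duration_head = "bdur[2]",
    sigma_path = "sigma[1]", sigma_head = "sigma[2]", resid_cor = "rho",
    sd_intercept_path = "sd_u[1]", sd_intercept_head = "sd_u[2]",
    sd_slope_curiosity_path = "sd_sc[1]", sd_slope_curiosity_head = "sd_sc[2]",
    sd_slope_interest_path = "sd_si[1]", sd_slope_interest_head = "sd_si[2]"
  )
  structural <- c("b_curiosity_path", "b_curiosity_head", "b_interest_path",
                  "b_interest_head", "b_curiosity_m_path", "b_curiosity_m_head",
                  "b_interest_m_path", "b_interest_m_head", "b_duration_path",
                  "b_duration_head", "resid_cor")
  new_model_fit(mcmc, map, "exploration (bivariate)", preset, level,
                structural)
}

#' Cross-outcome coefficient contrast
#'
#' Draw-wise difference of one coefficient between two outcomes of a
#' bivariate fit, e.g. the curiosity weight on path RE minus the
#' curiosity weight on head RE, summarised by mean and HPDI.
#'
#' @param fit a `model_fit` from [fit_exploration_model()].
#' @param coefficient base coefficient name, e.g. `"b_curiosity"`.
#' @param outcome_a,outcome_b outcome suffixes (default `"path"`,
#'   `"head"`).
#' @param level HPDI level.
#' @return List with `mean`, `lower`, `upper`, `level`, `draws`.
#' @export
coefficient_contrast <- function(fit, coefficient, outcome_a = "path",
                                 outcome_b = "head", level = 0.93) {
  stopifnot(inherits(fit, "model_fit"))
  ca <- paste0(coefficient, "_", outcome_a)
  cb <- paste0(coefficient, "_", outcome_b)
  for (cn in c(ca, cb)) {
    if (!cn %in% colnames(fit$draws)) {
      stop("unknown coefficient '", cn, "'; available: ",
           paste(colnames(fit$draws), collapse = ", "))
    }
  }
  d <- fit$draws[, ca] - fit$draws[, cb]
  if (all(d == d[1])) {  # degenerate (e.g. a coefficient against itself)
    return(list(mean = d[1], lower = d[1], upper = d[1], level = level,
                draws = d))
  }
  h <- hpdi(d, level = level)
  list(mean = h$mean, lower = h$lower, upper = h$upper, level = level,
       draws = d)
}

#' Trait-moderation model
#'
#' Univariate multilevel regression of path roaming entropy adding the
#' four grand-centred curiosity-trait subscales (Joyous Exploration,
#' Deprivation Sensitivity, Stress Tolerance, Thrill Seeking) and their
#' interactions with the within-person curiosity deviation.
#'
#' @inheritParams fit_exploration_model
#' @return A `model_fit`; interaction parameters are named
#'   `b_curiosity_x_JE` etc.
#' @export
fit_moderation_model <- function(design, preset = sampler_preset("reduced"),
                                 priors = prior_settings(),
                                 random = "slopes", level = 0.93, seed = 1L) {
  random <- re_terms(random)
  traits <- c("trait_JE_c", "trait_DS_c", "trait_ST_c", "trait_TS_c")
  p <- design_checks(design, c("curiosity_w", "interest_w", "curiosity_m",
                               "interest_m", "duration_c", "path_re", traits))
  tr <- as.matrix(design[traits])
  if (any(apply(tr, 2, stats::sd) == 0)) {
    stop("a trait column is constant across participants: ",
         "interaction unidentifiable")
  }
  slopes <- random == "slopes"
  model <- sprintf("
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], pow(sigma, -2))
    mu[i] <- up[p[i]] + bcw * cw[i] + biw * iw[i] + bdur * dur[i] +
             inprod(bint[1:4], trj[p[i], 1:4]) * cw[i]%s
  }
  for (j in 1:P) {
    up[j] ~ dnorm(b0 + bcm * cmj[j] + bim * imj[j] +
                    inprod(btr[1:4], trj[j, 1:4]), pow(sd_u, -2))%s
  }
  for (k in 1:4) {
    btr[k] ~ dnorm(0, prec_b)
    bint[k] ~ dnorm(0, prec_b)
  }
  b0 ~ dnorm(0, pow(int_sc, -2))
  bcw ~ dnorm(0, prec_b); biw ~ dnorm(0, prec_b)
  bcm ~ dnorm(0, prec_b); bim ~ dnorm(0, prec_b); bdur ~ dnorm(0, prec_b)
  sigma ~ dunif(0, sd_up)
  sd_u ~ dunif(0, sd_up)%s
  prec_b <- pow(coef_sc, -2)
}",
    if (slopes) " + sc[p[i]] * cw[i] + si[p[i]] * iw[i]" else "",
    if (slopes) "
    sc[j] ~ dnorm(0, pow(sd_sc, -2))
    si[j] ~ dnorm(0, pow(sd_si, -2))" else "",
    if (slopes) "
  sd_sc ~ dunif(0, sd_up)
  sd_si ~ dunif(0, sd_up)" else "")
  pt <- person_table(design, p, c("curiosity_m", "interest_m", traits))
  data <- list(
    N = nrow(design), P = max(p), p = p, y = design$path_re,
    cw = design$curiosity_w, iw = design$interest_w,
    cmj = pt$curiosity_m, imj = pt$interest_m,
    dur = design$duration_c,
    trj = do.call(cbind, pt[traits]),
    coef_sc = priors$coef_scale, int_sc = priors$intercept_scale,
    sd_up = priors$sd_upper
  )
  params <- c("b0", "bcw", "biw", "bcm", "bim", "bdur", "btr", "bint",
              "sigma", "sd_u", if (slopes) c("sd_sc", "sd_si"))
  mcmc <- run_jags(model, data, params, preset, seed)
  map <- c(
    intercept = "b0", b_curiosity = "bcw", b_interest = "biw",
    b_curiosity_m = "bcm", b_interest_m = "bim", b_duration = "bdur",
    b_trait_JE = "btr[1]", b_trait_DS = "btr[2]", b_trait_ST = "btr[3]",
    b_trait_TS = "btr[4]",
    b_curiosity_x_JE = "bint[1]", b_curiosity_x_DS = "bint[2]",
    b_curiosity_x_ST = "bint[3]", b_curiosity_x_TS = "bint[4]",
    sigma = "sigma", sd_intercept = "sd_u",
    sd_slope_curiosity = "sd_sc", sd_slope_interest = "sd_si"
  )
  structural <- c("b_curiosity", "b_interest", "b_curiosity_m", "b_interest_m",
                  "b_duration", "b_trait_JE", "b_trait_DS", "b_trait_ST",
                  "b_trait_TS", "b_curiosity_x_JE", "b_curiosity_x_DS",
                  "b_curiosity_x_ST", "b_curiosity_x_TS")
  new_model_fit(mcmc, map, "trait moderation (path RE)", preset, level,
                structural)
}

#' Cognitive-map model
#'
#' Multilevel regression of the composite sketch-map precision score on
#' within-person and person-mean terms of curiosity, interest, path RE
#' and head-direction RE, plus duration, with participant random
#' intercepts (and within-predictor random slopes by default).
#'
#' @inheritParams fit_exploration_model
#' @return A `model_fit`.
#' @export
fit_map_model <- function(design, preset = sampler_preset("reduced"),
                          priors = prior_settings(), random = "slopes",
                          level = 0.93, seed = 1L) {
  random <- re_terms(random)
  p <- design_checks(design, c("composite", "curiosity_w", "interest_w",
                               "path_re_w", "head_re_w", "curiosity_m",
                               "interest_m", "path_re_m", "head_re_m",
                               "duration_c"))
  if (stats::sd(design$composite) == 0) stop("composite score is constant")
  slopes <- random == "slopes"
  model <- sprintf("
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], pow(sigma, -2))
    mu[i] <- up[p[i]] + bcw * cw[i] + biw * iw[i] + bpr * pr[i] +
             bhr * hr[i] + bdur * dur[i]%s
  }
  for (j in 1:P) {
    up[j] ~ dnorm(b0 + bcm * cmj[j] + bim * imj[j] + bprm * prmj[j] +
                    bhrm * hrmj[j], pow(sd_u, -2))%s
  }
  b0 ~ dnorm(0, pow(int_sc, -2))
  bcw ~ dnorm(0, prec_b); biw ~ dnorm(0, prec_b)
  bpr ~ dnorm(0, prec_b); bhr ~ dnorm(0, prec_b)
  bcm ~ dnorm(0, prec_b); bim ~ dnorm(0, prec_b)
  bprm ~ dnorm(0, prec_b); bhrm ~ dnorm(0, prec_b)
  bdur ~ dnorm(0, prec_b)
  sigma ~ dunif(0, sd_up)
  sd_u ~ dunif(0, sd_up)%s
  prec_b <- pow(coef_sc, -2)
}",
    if (slopes) paste0(" + s1[p[i]] * cw[i] + s2[p[i]] * iw[i]",
                       " + s3[p[i]] * pr[i] + s4[p[i]] * hr[i]") else "",
    if (slopes) "
    s1[j] ~ dnorm(0, pow(sd_s[1], -2))
    s2[j] ~ dnorm(0, pow(sd_s[2], -2))
    s3[j] ~ dnorm(0, pow(sd_s[3], -2))
    s4[j] ~ dnorm(0, pow(sd_s[4], -2))" else "",
    if (slopes) "
  for (k in 1:4) { sd_s[k] ~ dunif(0, sd_up) }" else "")
  pt <- person_table(design, p, c("curiosity_m", "interest_m",
                                  "path_re_m", "head_re_m"))
  data <- list(
    N = nrow(design), P = max(p), p = p, y = design$composite,
    cw = design$curiosity_w, iw = design$interest_w,
    pr = design$path_re_w, hr = design$head_re_w,
    cmj = pt$curiosity_m, imj = pt$interest_m,
    prmj = pt$path_re_m, hrmj = pt$head_re_m,
    dur = design$duration_c,
    coef_sc = priors$coef_scale, int_sc = priors$intercept_scale,
    sd_up = priors$sd_upper
  )
  params <- c("b0", "bcw", "biw", "bpr", "bhr", "bcm", "bim", "bprm", "bhrm",
              "bdur", "sigma", "sd_u", if (slopes) "sd_s")
  mcmc <- run_jags(model, data, params, preset, seed)
  map <- c(
    intercept = "b0", b_curiosity = "bcw", b_interest = "biw",
    b_path_re = "bpr", b_head_re = "bhr",
    b_curiosity_m = "bcm", b_interest_m = "bim",
    b_path_re_m = "bprm", b_head_re_m = "bhrm", b_duration = "bdur",
    sigma = "sigma", sd_intercept = "sd_u",
    sd_slope_curiosity = "sd_s[1]", sd_slope_interest = "sd_s[2]",
    sd_slope_path_re = "sd_s[3]", sd_slope_head_re = "sd_s[4]"
  )
  structural <- c("b_curiosity", "b_interest", "b_path_re", "b_head_re",
                  "b_curiosity_m", "b_interest_m", "b_path_re_m",
                  "b_head_re_m", "b_duration")
  new_model_fit(mcmc, map, "cognitive map (composite)", preset, level,
                structural)
}

#' Within-person mediation: curiosity -> path RE -> map precision
#'
#' Jointly fits (in one MCMC run) a mediator model of the within-person
#' path-RE deviation on the within-person curiosity deviation and an
#' outcome model of the composite score on curiosity and the path-RE
#' deviation, both with duration and participant random effects. The
#' indirect effect is the draw-wise product `a * b` of the
#' curiosity -> path-RE and path-RE -> composite coefficients,
#' summarised by its posterior mean and HPDI (computed on the product
#' draws, not as the product of means).
#'
#' @inheritParams fit_exploration_model
#' @return A list: `fit` (joint `model_fit`), `indirect` (summary of
#'   the `a * b` draws), `a`, `b`, `direct` (summaries), and
#'   `indirect_draws`.
#' @export
mediation <- function(design, preset = sampler_preset("reduced"),
                      priors = prior_settings(), random = "slopes",
                      level = 0.93, seed = 1L) {
  random <- re_terms(random)
  p <- design_checks(design, c("composite", "curiosity_w", "path_re_w",
                               "duration_c"))
  slopes <- random == "slopes"
  model <- sprintf("
model {
  for (i in 1:N) {
    m[i] ~ dnorm(mu_m[i], pow(sigma_m, -2))
    mu_m[i] <- um[p[i]] + a * cw[i] + adur * dur[i]%s
    y[i] ~ dnorm(mu_y[i], pow(sigma_y, -2))
    mu_y[i] <- uy[p[i]] + cp * cw[i] + b * m[i] + bdur * dur[i]%s
  }
  a0 ~ dnorm(0, pow(int_sc, -2)); b0 ~ dnorm(0, pow(int_sc, -2))
  a ~ dnorm(0, prec_b); b ~ dnorm(0, prec_b); cp ~ dnorm(0, prec_b)
  adur ~ dnorm(0, prec_b); bdur ~ dnorm(0, prec_b)
  sigma_m ~ dunif(0, sd_up); sigma_y ~ dunif(0, sd_up)
  sd_um ~ dunif(0, sd_up); sd_uy ~ dunif(0, sd_up)
  for (j in 1:P) {
    um[j] ~ dnorm(a0, pow(sd_um, -2))
    uy[j] ~ dnorm(b0, pow(sd_uy, -2))%s
  }%s
  indirect <- a * b
  prec_b <- pow(coef_sc, -2)
}",
    if (slopes) " + sm[p[i]] * cw[i]" else "",
    if (slopes) " + sy[p[i]] * m[i]" else "",
    if (slopes) "
    sm[j] ~ dnorm(0, pow(sd_sm, -2))
    sy[j] ~ dnorm(0, pow(sd_sy, -2))" else "",
    if (slopes) "
  sd_sm ~ dunif(0, sd_up)
  sd_sy ~ dunif(0, sd_up)" else "")
  data <- list(
    N = nrow(design), P = max(p), p = p,
    m = design$path_re_w, y = design$composite,
    cw = design$curiosity_w, dur = design$duration_c,
    coef_sc = priors$coef_scale, int_sc = priors$intercept_scale,
    sd_up = priors$sd_upper
  )
  params <- c("a0", "b0", "a", "b", "cp", "adur", "bdur", "sigma_m",
              "sigma_y", "sd_um", "sd_uy", "indirect")
  mcmc <- run_jags(model, data, params, preset, seed)
  map <- c(
    a_curiosity_to_path_re = "a", b_path_re_to_composite = "b",
    direct_curiosity = "cp", indirect_effect = "indirect",
    intercept_mediator = "a0", intercept_outcome = "b0",
    b_duration_mediator = "adur", b_duration_outcome = "bdur",
    sigma_mediator = "sigma_m", sigma_outcome = "sigma_y",
    sd_intercept_mediator = "sd_um", sd_intercept_outcome = "sd_uy"
  )
  structural <- c("a_curiosity_to_path_re", "b_path_re_to_composite",
                  "direct_curiosity", "indirect_effect")
  fit <- new_model_fit(mcmc, map, "mediation (joint)", preset, level,
                       structural)
  sm <- function(pn) {
    h <- hpdi(fit$draws[, pn], level = level)
    list(mean = h$mean, lower = h$lower, upper = h$upper, level = level)
  }
  list(fit = fit, indirect = sm("indirect_effect"),
       a = sm("a_curiosity_to_path_re"), b = sm("b_path_re_to_composite"),
       direct = sm("direct_curiosity"),
       indirect_draws = fit$draws[, "indirect_effect"])
}
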