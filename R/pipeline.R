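#' Pipeline configuration
#'
#' Assembles the configuration of the full workflow: simulation block
#' (or paths to existing data), roaming-entropy options, model options
#' and output directory. Can be read from a YAML file.
#'
#' @param out_dir output directory for the report bundle.
#' @param sim named list of [sim_config()] arguments (used when
#'   simulating) or `NULL` to read data from `data_dir`.
#' @param data_dir directory with `trajectories.csv`, `ratings.csv`,
#'   `traits.csv`, `sketch_scores.csv` and `masks/` (as written by
#'   [write_cohort()]); ignored when `sim` is given.
#' @param as_percent report RE on the 0-100 scale instead of 0-1.
#' @param preset sampler preset name, see [sampler_preset()].
#' @param random random-effect structure, `"slopes"` or `"intercepts"`.
#' @param coef_scale prior SD on coefficients, see [prior_settings()].
#' @param seed global seed, recorded in every output.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "results", sim = list(),
                            data_dir = NULL, as_percent = FALSE,
                            preset = "reduced", random = "slopes",
                            coef_scale = 1, seed = 1L) {
  cfg <- list(out_dir = out_dir, sim = sim, data_dir = data_dir,
              as_percent = as_percent, preset = preset, random = random,
              coef_scale = coef_scale, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) -> roaming entropy -> sketch scoring ->
#' exploration model (+ cross-outcome contrasts) -> trait moderation ->
#' cognitive-map model -> mediation -> report. Every output table is
#' stamped with the configuration hash and seed; per-stage timings and
#' dropped-record counts are logged to the manifest. A stage failure
#' aborts with the stage name while earlier outputs are kept.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every stage result (`cohort` or
#'   loaded data, `re_table`, `scoring`, `fits`, `contrasts`,
#'   `mediation`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- rlang::hash(unclass(config))
  stamp <- sprintf("# config_hash: %s | seed: %d | generated: %s",
                   hash, config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  say <- function(...) if (!quiet) message(...)
  emit <- function(df, name) {
    f <- file.path(config$out_dir, name)
    writeLines(stamp, f)
    suppressWarnings(utils::write.table(
      df, f, append = TRUE, sep = ",", row.names = FALSE, quote = FALSE))
    f
  }
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    say(sprintf("[%s] done in %.1f s", stage,
                manifest$stages[[stage]]$seconds))
    out
  }

  # --- data ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- timed("simulate", {
      generate_cohort(do.call(sim_config,
                              utils::modifyList(config$sim,
                                                list(seed = config$seed))))
    })
    rooms <- cohort$rooms
    trajectories <- cohort$trajectories
    ratings <- cohort$ratings
    traits <- cohort$traits
    sketch <- cohort$sketch_scores
  } else {
    cohort <- NULL
    dd <- config$data_dir
    if (is.null(dd)) stop("either sim or data_dir must be given")
    loaded <- timed("load", {
      mask_files <- list.files(file.path(dd, "masks"), full.names = TRUE)
      if (length(mask_files) == 0) {
        stop("no mask files under ", file.path(dd, "masks"))
      }
      rooms <- lapply(mask_files, read_mask)
      names(rooms) <- vapply(rooms, `[[`, "", "room_id")
      list(rooms = rooms,
           trajectories = read_trajectories(file.path(dd, "trajectories.csv")),
           ratings = read_ratings(file.path(dd, "ratings.csv")),
           traits = read_traits(file.path(dd, "traits.csv")),
           sketch = read_sketch_scores(file.path(dd, "sketch_scores.csv")))
    })
    rooms <- loaded$rooms; trajectories <- loaded$trajectories
    ratings <- loaded$ratings; traits <- loaded$traits
    sketch <- loaded$sketch
  }

  # --- roaming entropy ------------------------------------------------------
  re_table <- timed("entropy", {
    compute_re(trajectories, rooms, as_percent = config$as_percent)
  })
  emit(re_table, "roaming_entropy.csv")
  manifest$stages$entropy$n_dropped <- sum(re_table$n_dropped)

  # --- sketch scoring -------------------------------------------------------
  scoring <- timed("score", {
    comp <- sketch_composite(sketch)
    dm <- dimension_matrix(sketch)
    rel <- lapply(c("OP", "SD", "RP", "SP"), function(d) {
      r <- inter_rater_reliability(sketch, d)
      tibble::tibble(dimension = d, icc = r$icc, pearson = r$pearson,
                     n_units = r$n_units)
    })
    alpha <- cronbach_alpha(dm[c("OP", "SD", "RP", "SP")],
                            seed = config$seed)
    list(composites = comp, reliability = dplyr::bind_rows(rel),
         alpha = alpha)
  })
  emit(scoring$composites, "composites.csv")
  emit(scoring$reliability, "reliability.csv")
  emit(tibble::tibble(statistic = "cronbach_alpha",
                      value = scoring$alpha$alpha,
                      lower = scoring$alpha$lower,
                      upper = scoring$alpha$upper,
                      level = scoring$alpha$level), "alpha.csv")

  # --- models ---------------------------------------------------------------
  design <- timed("design", {
    build_design(join_trials(re_table, ratings, traits = traits,
                             composites = scoring$composites))
  })
  preset <- sampler_preset(config$preset)
  priors <- prior_settings(coef_scale = config$coef_scale)
  fits <- list()
  fits$exploration <- timed("fit_exploration", {
    fit_exploration_model(design, preset = preset, priors = priors,
                          random = config$random, seed = config$seed)
  })
  contrasts <- timed("contrasts", {
    lapply(stats::setNames(nm = c("b_curiosity", "b_interest")), function(cf) {
      coefficient_contrast(fits$exploration, cf)
    })
  })
  fits$moderation <- timed("fit_moderation", {
    fit_moderation_model(design, preset = preset, priors = priors,
                         random = config$random, seed = config$seed + 1L)
  })
  fits$map <- timed("fit_map", {
    fit_map_model(design, preset = preset, priors = priors,
                  random = config$random, seed = config$seed + 2L)
  })
  med <- timed("mediation", {
    mediation(design, preset = preset, priors = priors,
              random = config$random, seed = config$seed + 3L)
  })

  # --- report ---------------------------------------------------------------
  posterior <- dplyr::bind_rows(
    fits$exploration$summary |> dplyr::mutate(model = "exploration"),
    fits$moderation$summary |> dplyr::mutate(model = "moderation"),
    fits$map$summary |> dplyr::mutate(model = "map"),
    med$fit$summary |> dplyr::mutate(model = "mediation"),
    tibble::tibble(
      parameter = paste0("contrast_", sub("^b_", "", names(contrasts))),
      mean = vapply(contrasts, `[[`, 0, "mean"),
      sd = vapply(contrasts, function(x) stats::sd(x$draws), 0),
      hpdi_low = vapply(contrasts, `[[`, 0, "lower"),
      hpdi_high = vapply(contrasts, `[[`, 0, "upper"),
      rhat = NA_real_, ess = NA_real_, model = "exploration"
    )
  )
  emit(posterior, "posterior_summaries.csv")
  if (!is.null(cohort)) {
    gt <- cohort$ground_truth
    keys <- c(b_curiosity_path = "beta_curiosity_path",
              b_interest_path = "beta_interest_path",
              b_curiosity_head = "beta_curiosity_head",
              b_interest_head = "beta_interest_head",
              resid_cor = "resid_cor")
    expl <- fits$exploration$summary
    recov <- tibble::tibble(
      parameter = names(keys),
      truth = unlist(gt[keys]),
      estimate = expl$mean[match(names(keys), expl$parameter)],
      sd = expl$sd[match(names(keys), expl$parameter)]
    )
    recov <- dplyr::bind_rows(recov, tibble::tibble(
      parameter = "indirect_effect", truth = gt$indirect_effect,
      estimate = med$indirect$mean,
      sd = stats::sd(med$indirect_draws)
    ))
    emit(recov, "ground_truth_recovery.csv")
  }
  manifest$flagged_fits <- names(fits)[vapply(fits, `[[`, TRUE, "flagged")]
  yaml::write_yaml(manifest, file.path(config$out_dir, "run_manifest.yml"))

  invisible(list(cohort = cohort, re_table = re_table, scoring = scoring,
                 design = design, fits = fits, contrasts = contrasts,
                 mediation = med, posterior = posterior,
                 manifest = manifest))
}
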