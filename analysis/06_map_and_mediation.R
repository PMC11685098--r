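#!/usr/bin/env Rscript

# Stage 6 -- cognitive-map model and mediation.
#
# Fits the composite-score model (curiosity, interest, path RE, head RE
# and duration as predictors, within/between centred) and the
# within-person mediation of the curiosity effect on map precision
# through path roaming entropy.

suppressPackageStartupMessages({
  library(roament)
  library(dplyr)
})

re <- readr::read_csv("results/re_table.csv", show_col_types = FALSE)
ratings <- read_ratings("results/data/ratings.csv")
composites <- readr::read_csv("results/composites.csv",
                              show_col_types = FALSE)
design <- build_design(join_trials(re, ratings, composites = composites))

cat("Fitting cognitive-map model on", nrow(design), "trials ...\n")
mapfit <- fit_map_model(design, preset = sampler_preset("reduced"), seed = 3)
readr::write_csv(mapfit$summary, "results/map_posterior.csv")
key <- mapfit$summary |>
  filter(parameter %in% c("b_curiosity", "b_interest", "b_path_re",
                          "b_head_re"))
cat("\nWithin-person predictors of map precision:\n")
print(as.data.frame(key[c("parameter", "mean", "hpdi_low", "hpdi_high")]),
      row.names = FALSE, digits = 3)

cat("\nFitting mediation model ...\n")
med <- mediation(design, preset = sampler_preset("reduced"), seed = 4)
readr::write_csv(med$fit$summary, "results/mediation_posterior.csv")
cat(sprintf("a (curiosity -> path RE):    %.4f [%.4f, %.4f]\n",
            med$a$mean, med$a$lower, med$a$upper))
cat(sprintf("b (path RE -> composite):    %.3f  [%.3f, %.3f]\n",
            med$b$mean, med$b$lower, med$b$upper))
cat(sprintf("indirect effect (a x b):     %.4f [%.4f, %.4f]\n",
            med$indirect$mean, med$indirect$lower, med$indirect$upper))

gt <- yaml::read_yaml("results/data/ground_truth.yml")
cat(sprintf("ground-truth indirect effect: %.4f\n", gt$indirect_effect))
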