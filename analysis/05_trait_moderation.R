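#!/usr/bin/env Rscript

# Stage 5 -- trait moderation.
#
# Adds the four curiosity-trait subscales (Joyous Exploration,
# Deprivation Sensitivity, Stress Tolerance, Thrill Seeking) and their
# interactions with within-person curiosity to the path-RE model.

suppressPackageStartupMessages({
  library(roament)
  library(dplyr)
})

re <- readr::read_csv("results/re_table.csv", show_col_types = FALSE)
ratings <- read_ratings("results/data/ratings.csv")
traits <- read_traits("results/data/traits.csv")
design <- build_design(join_trials(re, ratings, traits = traits))

cat("Fitting trait-moderation model on", nrow(design), "trials ...\n")
fit <- fit_moderation_model(design, preset = sampler_preset("reduced"),
                            seed = 2)
readr::write_csv(fit$summary, "results/moderation_posterior.csv")

ints <- fit$summary |> filter(grepl("b_curiosity_x_", parameter))
cat("\nTrait x curiosity interaction weights on path RE:\n")
print(as.data.frame(ints[c("parameter", "mean", "hpdi_low", "hpdi_high")]),
      row.names = FALSE, digits = 3)
st <- fit$draws[, "b_curiosity_x_ST"]
cat(sprintf("\nP(Stress-Tolerance interaction > 0) = %.2f\n", mean(st > 0)))
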