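#!/usr/bin/env Rscript

# Stage 3 -- sketch-map scoring.
#
# Computes composite cognitive-map precision scores (rater means, then
# the mean of the four rubric dimensions), two-rater reliability per
# dimension, and Cronbach's alpha with a 93% bootstrap interval.

suppressPackageStartupMessages({
  library(roament)
  library(dplyr)
})

scores <- read_sketch_scores("results/data/sketch_scores.csv")
composites <- sketch_composite(scores)
readr::write_csv(composites, "results/composites.csv")

rel <- bind_rows(lapply(c("OP", "SD", "RP", "SP"), function(d) {
  r <- inter_rater_reliability(scores, d)
  tibble::tibble(dimension = d, icc = r$icc, pearson = r$pearson)
}))
readr::write_csv(rel, "results/reliability.csv")

dm <- dimension_matrix(scores)
alpha <- cronbach_alpha(dm[c("OP", "SD", "RP", "SP")], seed = 1)

cat("Composite scores for", nrow(composites), "maps; mean",
    round(mean(composites$composite), 2), "\n")
cat("Inter-rater ICC(C,1) by dimension:\n")
print(as.data.frame(rel), row.names = FALSE, digits = 3)
cat(sprintf("Cronbach's alpha = %.3f, %d%% bootstrap interval [%.3f, %.3f]\n",
            alpha$alpha, round(100 * alpha$level), alpha$lower, alpha$upper))
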