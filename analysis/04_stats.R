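#!/usr/bin/env Rscript
# Step 4: permutational statistics on the experimental tables --
#   field survey: nested design (cycle fixed, time random nested in cycle)
#   flume:        temperature x current crossed factorial
#   nutrition:    one-way stimulus design, pairwise follow-up
#   zooplankton:  one-way cycles on fourth-root Bray-Curtis, plus SIMPER
library(polypwatch)

n_perm <- 9999
seed <- 20260923L

field <- read.csv("results/data/field_survey.csv")
nested <- run_stats(field, "nested", "expansion_pct", c("cycle", "time"),
                    n_perm = n_perm, seed = seed,
                    out_dir = "results/stats/field")
print(nested$permanova)

flume <- read.csv("results/data/flume_te_cu.csv")
two <- run_stats(flume, "twoway", "expansion_pct",
                 c("temperature", "current"),
                 n_perm = n_perm, seed = seed,
                 out_dir = "results/stats/flume")
print(two$permanova)

nutrition <- read.csv("results/data/flume_nutrition.csv")
one <- run_stats(nutrition, "oneway", "expansion_pct", "stimulus",
                 n_perm = n_perm, seed = seed,
                 out_dir = "results/stats/nutrition")
print(one$permanova)
if (!is.null(one$pairwise)) {
  cat("\npairwise stimulus comparisons (Monte-Carlo p):\n")
  print(one$pairwise[, c("group1", "group2", "t", "p_perm", "p_mc",
                         "low_perms")], digits = 3)
}

zoo <- read.csv("results/data/zooplankton_counts.csv", check.names = FALSE)
taxa <- grep("^taxon_", names(zoo), value = TRUE)
zres <- run_stats(zoo, "oneway", taxa, "cycle", distance = "bray_curtis",
                  n_perm = n_perm, seed = seed,
                  out_dir = "results/stats/zooplankton")
print(zres$permanova)
cat("\nSIMPER, most dissimilar cycle pairs:\n")
avg <- sort(vapply(zres$simper, `[[`, numeric(1),
                   "average_dissimilarity_pct"), decreasing = TRUE)
print(round(head(avg, 5), 2))
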