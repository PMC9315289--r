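#!/usr/bin/env Rscript
# Stage 3 — decisional-parameter identification.
# Enumerates, by per-node constraint satisfaction at one decisional step
# per assessment interval, every combination of perception thresholds and
# logic weights whose one-step predictions best reproduce the cohort's
# observed node transitions; reports transition coverage, the Manhattan
# alignment error and its decompositions.

library(adherenet)

net <- adherence_network()
cohort <- read_trajectories("results/cohort.csv")

fit <- fit_network(net, cohort, K = 1L, coverage_min = 0.75,
                   max_models = 96L)
print(fit)
cat(sprintf(
  "Retained %d candidate models (of a %s-strong candidate space) at coverage %.1f%%.\n",
  length(fit$models), format(fit$n_candidates, big.mark = ","),
  100 * max(fit$coverage)))

write_models(fit, "results/models.tsv")

ae <- alignment_error(net, fit$models[[1]], cohort, K = 1L)
print(ae)
by_node <- ae$by_node[order(-ae$by_node$error), ]
write.csv(by_node, "results/node_error.csv", row.names = FALSE)
write.csv(fit$trajectory_balance, "results/trajectory_balance.csv",
          row.names = FALSE)
cat(sprintf(
  "Highest-error nodes: %s.\n",
  paste(sprintf("%s (%.1f%%)", head(by_node$node, 3),
                head(by_node$percent, 3)), collapse = ", ")))
cat("wrote results/models.tsv, results/node_error.csv, results/trajectory_balance.csv\n")
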