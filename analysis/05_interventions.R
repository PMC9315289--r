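#!/usr/bin/env Rscript
# Stage 5 — minimal intervention sets.
# Under every candidate model, searches one- and two-node clamp
# combinations on the eight targetable mediators that move each persistent
# non-adherent state back to sustained adherence; pools the strategies into
# a consensus table stratified by demographic (input-node) profile and
# scores the robustness of the top strategies to decisional noise.

library(adherenet)

seed <- 20260105L
net <- adherence_network()
models <- read_models("results/models.tsv", net)

cons <- consensus_interventions(net, models, max_size = 2L, hold_steps = 5L,
                                n_inits = 1000L, max_states = 8L,
                                seed = seed)
print(cons)
write_consensus(cons, "results/consensus_mis.csv")

tab <- cons$table
if (nrow(tab)) {
  unan <- tab$strategy[tab$unanimous]
  cat(sprintf(
    "%d strategies found; %d unanimous across all %d models%s.\n",
    nrow(tab), length(unan), cons$n_models,
    if (length(unan)) paste0(" (", paste(unan, collapse = "; "), ")") else ""))
  cat(sprintf("%d of %d persistent non-adherent states are rescuable.\n",
              cons$n_rescued_states, cons$n_nonadherent_states))

  # robustness, under one model, of every MIS found for its heaviest trap
  details <- Filter(function(d) length(mis_ok <- Filter(
    function(r) !isTRUE(r$already_adherent), d$mis)) > 0, cons$details)
  if (length(details)) {
    d1 <- details[[1]]
    state <- as.integer(strsplit(strsplit(d1$attractor, "|",
                                          fixed = TRUE)[[1]][1], ",")[[1]])
    cat("Robustness to decisional noise (0.05/step, 100 replicates),\n")
    cat(sprintf("model %d, trap %s:\n", d1$model, d1$attractor))
    for (r in Filter(function(r) !isTRUE(r$already_adherent), d1$mis)) {
      rob <- score_robustness(net, models[[d1$model]], state, r$actions,
                              noise_prob = 0.05, n_replicates = 100L,
                              seed = seed + 2L)
      cat(sprintf("  %-28s promptness %s, robustness %.2f\n", r$label,
                  r$promptness, rob))
    }
  }
}
cat("wrote results/consensus_mis.csv\n")
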