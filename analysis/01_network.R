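#!/usr/bin/env Rscript
# Stage 1 — the behavioral circuit.
# Loads the packaged adherence network (18 factors, 43 signed interactions),
# summarizes its structure, and writes the node and edge tables used by the
# later stages.

library(adherenet)

dir.create("results", showWarnings = FALSE)

net <- adherence_network()
print(net)

n_dyn <- sum(net$nodes$kind == "dynamic")
cat(sprintf(
  "Circuit: %d nodes (%d dynamic, %d demographic inputs), %d edges (%d activating, %d inhibiting), %d targetable levers.\n",
  nrow(net$nodes), n_dyn, nrow(net$nodes) - n_dyn, nrow(net$edges),
  sum(net$edges$mode == "activate"), sum(net$edges$mode == "inhibit"),
  sum(net$nodes$targetable)))

write.csv(net$nodes, "results/network_nodes.csv", row.names = FALSE)
write.csv(net$edges[, c("source", "target", "mode")],
          "results/network_edges.csv", row.names = FALSE)
write_sif(net, "results/network.sif")
cat("wrote results/network_nodes.csv, results/network_edges.csv, results/network.sif\n")
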