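#!/usr/bin/env Rscript
# A 10-cell random-walk network, half intrinsic bursters: network-wide
# conversion, and sensitivity of the dynamics to swapping the intrinsic type
# of two cells.
#
# Finds: with clustered bursters all spikers are converted and all cells burst
# in a common rhythm; flipping one burster and one spiker reshuffles the
# event patterns across the network (mixes of spikes, doublets and bursts),
# and any exact periodicity of the label sequence is reported.
#
# Writes: results/small_network_summary.csv, results/small_network_events.csv

library(pitnet)
dir.create("results", showWarnings = FALSE)

net <- random_walk_network(10, p = 0.7, seed = 16)
lab0 <- assign_types(net, 0.5, "defensive")
cat("10-cell network,", nrow(net$edges), "edges; bursters at",
    paste(which(lab0$types == "b") - 1, collapse = ", "), "\n\n")

flip_pair <- function(types) {
  # swap the types of the highest-degree burster and highest-degree spiker
  deg <- pitnet:::network_degrees(net)
  b <- which(types == "b"); s <- which(types == "s")
  i <- b[which.max(deg[b])]; j <- s[which.max(deg[s])]
  types[c(i, j)] <- types[c(j, i)]
  types
}
variants <- list(clustered = lab0$types, flipped = flip_pair(lab0$types))

rows <- list(); all_ev <- list()
for (vn in names(variants)) {
  labnet <- cell_network(net$n, net$edges, variants[[vn]])
  cfg <- sim_config(t_end = 40000, t_transient = 20000, g_c = 0.05, seed = 3)
  traj <- run_network(labnet, cfg)
  sync <- synchrony_index(traj)
  for (cell in seq_len(net$n)) {
    ev <- event_train(traj, cell)
    conv <- is_converted_burster(ev)
    per <- minimal_period(ev$label)
    rows[[length(rows) + 1]] <- data.frame(
      variant = vn, cell = cell - 1, type = labnet$types[cell],
      n_events = nrow(ev),
      modal_label = names(sort(table(ev$label), decreasing = TRUE))[1],
      n_distinct_labels = length(unique(ev$label)),
      burst_fraction = conv$burst_fraction,
      label_period = ifelse(is.na(per), NA, per),
      synchrony = sync)
    ev$variant <- vn
    all_ev[[length(all_ev) + 1]] <- ev
  }
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/small_network_summary.csv", row.names = FALSE)
export_events(do.call(rbind, all_ev)[, c("cell", "t_start", "t_end",
                                         "n_peaks", "label")],
              "results/small_network_events.csv")

print(summary, row.names = FALSE, digits = 3)
clu <- summary[summary$variant == "clustered", ]
fli <- summary[summary$variant == "flipped", ]
cat(sprintf("\n- clustered: %d of %d intrinsic spikers converted; synchrony %.2f\n",
            sum(clu$burst_fraction[clu$type == "s"] >= 0.5),
            sum(clu$type == "s"), clu$synchrony[1]))
cat(sprintf("- flipped: per-cell label variety %s (clustered: %s) -- a two-cell\n",
            paste(range(fli$n_distinct_labels), collapse = "-"),
            paste(range(clu$n_distinct_labels), collapse = "-")))
cat("  type swap reshapes the whole network's event mix.\n")
per <- fli$label_period[!is.na(fli$label_period)]
if (length(per))
  cat(sprintf("- exact label-sequence periods detected in the flipped variant: %s\n",
              paste(sort(unique(per)), collapse = ", ")))
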