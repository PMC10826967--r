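#!/usr/bin/env Rscript
# Fast/slow analysis of the intrinsic spiker (1 fast variable V, 2 slow n, c):
# why coupling to a burster converts the spiker to bursting.
#
# Finds: the spiker's critical manifold has a fold at constant voltage whose
# desingularized reduced flow carries a stable folded node; a depolarized
# partner input shifts the folded node (and with it the canard funnel) to
# higher calcium without changing the eigenvalue-ratio canard bound; a spiker
# driven by burst-phase voltage pulses emits multi-spike bursts whose
# small-oscillation counts respect the canard-sector bound.
#
# Writes: results/folded_node_vs_gc.csv, results/clamped_spiker_events.csv

library(pitnet)
dir.create("results", showWarnings = FALSE)

cat("Folded-node analysis of the intrinsic spiker\n\n")
fn0 <- find_folded_node(reduced_model())
print(fn0)

gcs <- seq(0, 0.05, by = 0.01)
tab <- do.call(rbind, lapply(gcs, function(g) {
  m <- if (g == 0) reduced_model()
       else reduced_model(input = list(g_c = g, V_fix = -20))
  fn <- find_folded_node(m)
  data.frame(g_c = g, V_fix = if (g == 0) NA else -20,
             V_star = fn$V, c_star = fn$c, n_star = fn$n,
             lambda_strong = fn$eigenvalues[1], lambda_weak = fn$eigenvalues[2],
             mu = fn$mu, k = fn$k)
}))
write.csv(tab, "results/folded_node_vs_gc.csv", row.names = FALSE)
cat("\nFolded node vs partner input (V_fix = -20 mV):\n")
print(tab, row.names = FALSE, digits = 5)
cat(sprintf("\n- c* rises monotonically with g_c (%.5f -> %.5f): the canard\n",
            tab$c_star[1], tab$c_star[nrow(tab)]))
cat("  funnel is right-shifted toward the calcium range the driven cell visits.\n")
cat(sprintf("- the eigenvalue-ratio canard bound k = %d is unchanged across the range.\n",
            tab$k[1]))

# trajectory-side check: burst-phase pulses engage the canard machinery
cfg <- sim_config(t_end = 40000, t_transient = 10000, g_c = 0, seed = 6)
ref <- run_single_cell(burster_params(), cfg)
proto <- clamp_protocol_from_burster(ref, g_c = 0.05)
clamped <- run_with_clamped_partner(spiker_params(), proto, cfg)
ev <- event_train(clamped, 1)
export_events(ev, "results/clamped_spiker_events.csv")
bursts <- ev[grepl("burst", ev$label), ]
win <- proto$windows[proto$windows[, 1] >= cfg$t_transient, , drop = FALSE]
hit <- apply(win, 1, function(w) any(ev$n_peaks[ev$t_end > w[1] &
                                                ev$t_start < w[2]] >= 2))
cat(sprintf("\nClamped-partner protocol (V_fix = %.1f mV, %d windows):\n",
            proto$V_fix, nrow(win)))
cat(sprintf("- spiker bursts in %d of %d windows (%.0f%%)\n",
            sum(hit), length(hit), 100 * mean(hit)))
cat(sprintf("- burst sizes observed: %s spikes (canard-sector bound allows up to %d)\n",
            paste(sort(unique(bursts$n_peaks)), collapse = ", "),
            find_folded_node(reduced_model(input = list(g_c = 0.05,
                                                        V_fix = proto$V_fix)))$k + 1))
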