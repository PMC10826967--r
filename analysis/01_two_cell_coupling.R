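#!/usr/bin/env Rscript
# Two coupled lactotroph model cells (one intrinsic burster, one intrinsic
# spiker) at weak and strong gap-junction coupling.
#
# Finds: at g_c = 0.005 nS the pair drifts (low synchrony) and the burster
# keeps much higher calcium and secretion; at g_c = 0.05 nS the spiker is
# converted to 2-spike bursting, the pair synchronizes, the burster's active
# phases shorten, and total secretion rises.
#
# Writes: results/two_cell_summary.csv, results/two_cell_events.csv,
#         results/two_cell_traces_gc*.csv (down-sampled traces)

library(pitnet)
dir.create("results", showWarnings = FALSE)

net <- cell_network(2, matrix(c(0L, 1L), ncol = 2), types = c("b", "s"))
rows <- list(); all_events <- list()

for (g_c in c(0, 0.005, 0.05)) {
  cfg <- sim_config(dt = 0.5, t_end = 60000, t_transient = 20000,
                    g_c = g_c, seed = 1)
  traj <- run_network(net, cfg)
  idx <- pitnet:::window_idx(traj)
  sync <- if (g_c > 0) synchrony_index(traj) else NA_real_
  for (cell in 1:2) {
    ev <- event_train(traj, cell)
    conv <- is_converted_burster(ev)
    rows[[length(rows) + 1]] <- data.frame(
      g_c = g_c, cell = cell - 1, type = net$types[cell],
      n_events = nrow(ev),
      modal_label = names(sort(table(ev$label), decreasing = TRUE))[1],
      burst_fraction = conv$burst_fraction,
      mean_active_ms = mean(ev$t_end - ev$t_start),
      c_mean = mean(traj$c[idx, cell]),
      s_mean = mean(traj$s[idx, cell]),
      synchrony = sync)
    ev$g_c <- g_c
    all_events[[length(all_events) + 1]] <- ev
  }
  # 10-ms-resolution excerpt of the first 5 s after the transient
  excerpt <- structure(
    list(times = traj$times[idx[idx <= idx[1] + 10000]],
         V = traj$V[idx[idx <= idx[1] + 10000], , drop = FALSE],
         n = traj$n[idx[idx <= idx[1] + 10000], , drop = FALSE],
         c = traj$c[idx[idx <= idx[1] + 10000], , drop = FALSE],
         b = traj$b[idx[idx <= idx[1] + 10000], , drop = FALSE],
         s = traj$s[idx[idx <= idx[1] + 10000], , drop = FALSE],
         dt = traj$dt, window = traj$window),
    class = "pitnet_traj")
  export_trajectory(excerpt, sprintf("results/two_cell_traces_gc%g.csv", g_c),
                    stride = 20L)
}

summary <- do.call(rbind, rows)
write.csv(summary, "results/two_cell_summary.csv", row.names = FALSE)
export_events(do.call(rbind, all_events), "results/two_cell_events.csv")

cat("Two-cell coupling experiments (60 s runs, 20 s transient):\n\n")
print(summary, row.names = FALSE, digits = 4)
cat("\nKey observations:\n")
s <- summary
strong <- s[s$g_c == 0.05, ]
weak <- s[s$g_c == 0.005, ]
alone <- s[s$g_c == 0, ]
cat(sprintf("- weak coupling: synchrony %.2f, spiker burst fraction %.2f (not converted)\n",
            weak$synchrony[1], weak$burst_fraction[weak$type == "s"]))
cat(sprintf("- strong coupling: synchrony %.2f, spiker modal event '%s' (converted)\n",
            strong$synchrony[1], strong$modal_label[strong$type == "s"]))
cat(sprintf("- burster active phase: %.0f ms alone vs %.0f ms coupled (shortened)\n",
            alone$mean_active_ms[alone$type == "b"],
            strong$mean_active_ms[strong$type == "b"]))
cat(sprintf("- total secretion (sum of s): %.3f weak vs %.3f strong\n",
            sum(weak$s_mean), sum(strong$s_mean)))
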