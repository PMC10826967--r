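# shared fixtures: tiny networks and short simulation configs

pair_network <- function(types = c("b", "s")) {
  cell_network(2, matrix(c(0L, 1L), ncol = 2), types = types)
}

path_network <- function(n, types = NULL) {
  cell_network(n, cbind(0:(n - 2), 1:(n - 1)), types = types)
}

complete_network <- function(n, types = NULL) {
  cell_network(n, t(utils::combn(0:(n - 1), 2)), types = types)
}

# short two-cell run used by several suites (4 s transient, 4 s analysis)
short_pair_cfg <- function(g_c = 0.05, seed = 1) {
  sim_config(t_end = 8000, t_transient = 4000, g_c = g_c, seed = seed)
}

# brute-force homophily oracle: plain neighbor counting over the edge list
homophily_oracle <- function(net) {
  isb <- net$types == "b"
  n <- net$n
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1] + 1; j <- net$edges[k, 2] + 1
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  frac <- sapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    if (!length(nb)) NA_real_ else sum(isb[nb]) / length(nb)
  })
  list(Gamma_b = if (any(isb)) mean(frac[isb]) else NA_real_,
       Gamma_s = if (any(!isb)) mean(frac[!isb]) else NA_real_)
}

# random connected labelled graph for oracle comparisons
random_labelled_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    m <- sample(n:(n * (n - 1) / 2), 1)
    all_e <- t(utils::combn(0:(n - 1), 2))
    e <- all_e[sample(nrow(all_e), m), , drop = FALSE]
    types <- sample(c("b", "s"), n, replace = TRUE)
    net <- try(cell_network(n, e, types), silent = TRUE)
    if (!inherits(net, "try-error") && pitnet:::is_connected(net)) return(net)
  }
}
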