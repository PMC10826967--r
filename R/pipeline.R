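# Placement-sweep pipeline: secretion averaging, burster-placement sweeps,
# binned strategy curves, and gamma_s distribution comparisons.

#' Network- and time-averaged secretion
#'
#' Mean of the secretion variable over all cells and all samples of the
#' analysis window.
#'
#' @param traj a `pitnet_traj`.
#' @param window analysis window `c(from, to)` in ms; defaults to the
#'   trajectory's post-transient window.
#' @return scalar mean secretion in (0, 1).
#' @export
average_secretion <- function(traj, window = traj$window) {
  idx <- window_idx(traj, window)
  if (!length(idx)) stop("empty analysis window")
  mean(traj$s[idx, ])
}

# distinct random burster sets of size k (1-based ids), canonical dedup
sample_placements <- function(n, k, n_placements, max_draw_factor = 50L) {
  seen <- character(0)
  sets <- list()
  draws <- 0L
  while (length(sets) < n_placements) {
    draws <- draws + 1L
    if (draws > max_draw_factor * n_placements)
      stop("could not sample enough distinct placements")
    s <- sort(sample.int(n, k))
    key <- paste(s, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sets[[length(sets) + 1L]] <- s
  }
  sets
}

#' Sweep burster placements on a fixed structural network
#'
#' Distributes `round(fraction * n)` intrinsic bursters across the network in
#' `n_placements` distinct random ways (sampled without replacement over
#' burster sets). Each placement is labelled, simulated, and summarized by its
#' burster/spiker homophily, network-averaged secretion, and the number of
#' intrinsic spikers converted to bursting. Fully seeded: placement sampling
#' uses `seed`, and placement `i` is simulated with initial-condition seed
#' `seed + i`.
#'
#' @param net unlabelled (or labelled; labels ignored) `cell_network`.
#' @param fraction intrinsic-burster fraction.
#' @param n_placements number of distinct placements.
#' @param simcfg a `sim_config` (its `seed` is overridden per placement).
#' @param seed master seed.
#' @param detect_conversion also run event detection per spiker (slower).
#' @return data.frame of class `placement_sweep` with columns `placement_id`,
#'   `seed`, `burster_ids` (semicolon-separated 0-based ids), `gamma_b_mean`,
#'   `gamma_s_mean`, `s_mean`, `n_converted` (`NA` when conversion detection is
#'   off). The structural network is attached as attribute `net`.
#' @export
sweep_placements <- function(net, fraction, n_placements,
                             simcfg = sim_config(), seed = 1L,
                             detect_conversion = TRUE) {
  stopifnot(n_placements >= 1)
  k <- round(fraction * net$n)
  if (k < 1) stop("fraction yields zero bursters")
  if (choose(net$n, k) < n_placements)
    stop("more placements requested than distinct burster sets exist")
  set.seed(seed)
  sets <- sample_placements(net$n, k, n_placements)
  rows <- vector("list", n_placements)
  for (i in seq_len(n_placements)) {
    lab <- assign_types(net, placement = "explicit", bursters = sets[[i]] - 1L)
    hom <- homophily(lab)
    cfg_i <- simcfg
    cfg_i$seed <- seed + i
    traj <- run_network(lab, cfg_i)
    s_mean <- average_secretion(traj)
    n_conv <- NA_integer_
    if (detect_conversion) {
      spikers <- which(lab$types == "s")
      conv <- vapply(spikers, function(cl)
        isTRUE(is_converted_burster(event_train(traj, cl))$converted), logical(1))
      n_conv <- sum(conv)
    }
    rows[[i]] <- data.frame(
      placement_id = i, seed = cfg_i$seed,
      burster_ids = paste(sets[[i]] - 1L, collapse = ";"),
      gamma_b_mean = hom$Gamma_b, gamma_s_mean = hom$Gamma_s,
      s_mean = s_mean, n_converted = n_conv)
  }
  out <- do.call(rbind, rows)
  attr(out, "net") <- net
  class(out) <- c("placement_sweep", class(out))
  out
}

#' Rebuild labelled networks from sweep rows
#'
#' @param sweep a `placement_sweep` (or compatible data.frame with
#'   `burster_ids`).
#' @param net the structural network (defaults to the sweep's attribute).
#' @return list of labelled `cell_network`s, one per row.
#' @export
placements_to_networks <- function(sweep, net = attr(sweep, "net")) {
  if (is.null(net)) stop("structural network not available")
  lapply(strsplit(sweep$burster_ids, ";", fixed = TRUE), function(ids)
    assign_types(net, placement = "explicit", bursters = as.integer(ids)))
}

#' Bin placements by burster homophily and average secretion
#'
#' Equal-width bins on `Gamma_b` in \[0, 1\] (right-open except the last);
#' per-bin placement count and mean network-averaged secretion. Empty bins are
#' reported with count 0 and `NA` mean, never zero-filled.
#'
#' @param results a `placement_sweep` data.frame.
#' @param n_bins number of bins.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `s_mean`.
#' @export
bin_average <- function(results, n_bins = 10) {
  stopifnot(nrow(results) >= 1)
  br <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(results$gamma_b_mean, br, rightmost.closed = TRUE),
              n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  sm <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins))
    if (cnt[b] > 0) sm[b] <- mean(results$s_mean[idx == b])
  data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
             count = cnt, s_mean = sm)
}

#' Pooled spiker-homophily histogram of a subpopulation
#'
#' Pools the per-spiker `gamma_s` values (fraction of a spiker's neighbors
#' that are intrinsic bursters) over a set of labelled networks and bins them.
#'
#' @param nets list of labelled `cell_network`s.
#' @param breaks histogram breaks on \[0, 1\].
#' @return list with `counts`, `breaks`, `values` (pooled gamma_s), and
#'   `variance` of the pooled values.
#' @export
gamma_s_histogram <- function(nets, breaks = seq(0, 1, by = 0.1)) {
  vals <- unlist(lapply(nets, function(nt) {
    h <- homophily(nt)
    if (!length(h$gamma_s)) stop("subpopulation contains a network with no spikers")
    h$gamma_s
  }))
  hh <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                       include.lowest = TRUE, right = FALSE)
  list(counts = hh$counts, breaks = hh$breaks, values = unname(vals),
       variance = stats::var(vals))
}

#' Split a matched subpopulation by secretion
#'
#' Selects the placements whose `(Gamma_b, Gamma_s)` fall in the most populous
#' cell of a grid with the given widths (a matched subpopulation), then splits
#' it into low- and high-secreting halves at the median network-averaged
#' secretion.
#'
#' @param sweep a `placement_sweep`.
#' @param width grid width on both homophily axes.
#' @param min_n minimal matched-subpopulation size.
#' @return list with `low` and `high` row subsets of the sweep (the sweep's
#'   network attribute is preserved) and the matched cell's homophily ranges.
#' @export
matched_secretion_split <- function(sweep, width = 0.05, min_n = 20) {
  gb <- floor(sweep$gamma_b_mean / width)
  gs <- floor(sweep$gamma_s_mean / width)
  key <- paste(gb, gs)
  tab <- sort(table(key), decreasing = TRUE)
  if (tab[1] < min_n)
    stop("no matched (Gamma_b, Gamma_s) cell with at least ", min_n, " placements")
  sel <- key == names(tab)[1]
  sub <- sweep[sel, , drop = FALSE]
  med <- stats::median(sub$s_mean)
  low <- sub[sub$s_mean < med, , drop = FALSE]
  high <- sub[sub$s_mean >= med, , drop = FALSE]
  attr(low, "net") <- attr(sweep, "net")
  attr(high, "net") <- attr(sweep, "net")
  list(low = low, high = high,
       Gamma_b_range = range(sub$gamma_b_mean),
       Gamma_s_range = range(sub$gamma_s_mean))
}

#' Export a placement sweep as CSV
#'
#' @param sweep a `placement_sweep`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
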