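# Structural networks: random-walk generation, burster placement,
# homophily statistics, and edge-list file I/O.

#' Cell network constructor
#'
#' An undirected labelled graph of cells: node ids are `0 .. n-1`, edges are
#' unordered pairs, and each node may carry an intrinsic-type label
#' (`"b"` burster, `"s"` spiker).
#'
#' @param n_nodes node count (>= 1).
#' @param edges two-column integer matrix of 0-based node ids, one row per
#'   undirected edge.
#' @param types optional character vector of per-node labels, `"b"` or `"s"`.
#' @return object of class `cell_network` with fields `n`, `edges` (rows
#'   sorted, `i < j`), and `types` (or `NULL` if unlabelled).
#' @export
cell_network <- function(n_nodes, edges, types = NULL) {
  stopifnot(n_nodes >= 1)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 0L) || any(edges >= n_nodes)) stop("edge ids out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- t(apply(edges, 1, sort))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  }
  if (!is.null(types)) {
    if (length(types) != n_nodes) stop("types must have one label per node")
    if (!all(types %in% c("b", "s"))) stop('types must be "b" or "s"')
  }
  structure(list(n = as.integer(n_nodes), edges = edges, types = types),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  lab <- if (is.null(x$types)) "unlabelled"
         else sprintf("%d bursters / %d spikers",
                      sum(x$types == "b"), sum(x$types == "s"))
  cat(sprintf("<cell_network> %d nodes, %d edges, %s\n",
              x$n, nrow(x$edges), lab))
  invisible(x)
}

# neighbor list, 1-based internally
neighbor_list <- function(net) {
  nb <- vector("list", net$n)
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges[k, 1] + 1L; j <- net$edges[k, 2] + 1L
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

network_degrees <- function(net) lengths(neighbor_list(net))

is_connected <- function(net) {
  if (net$n == 1L) return(TRUE)
  nb <- neighbor_list(net)
  seen <- logical(net$n); seen[1] <- TRUE
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in nb[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

#' Random-walk network generator
#'
#' Grows a connected undirected network by the random-walk rule: start from two
#' connected nodes; repeatedly pick a uniform random existing node and, with
#' probability `p`, attach a brand-new node to it, otherwise add an edge from
#' it to a uniform random distinct existing node (resampling a bounded number
#' of times when the drawn edge already exists); stop when `n` nodes exist.
#' With `p = 1` the result is a tree with `n - 1` edges; smaller `p` adds
#' shortcut edges, with expected edge count close to `1 + (n - 2) / p` (biased
#' slightly low by the duplicate-edge resampling).
#'
#' @param n target node count (>= 2).
#' @param p node-addition probability in (0, 1].
#' @param seed optional RNG seed for reproducibility.
#' @param max_retry resampling bound for duplicate edge draws.
#' @return unlabelled `cell_network`, connected, no self-loops or multi-edges.
#' @export
random_walk_network <- function(n, p = 0.7, seed = NULL, max_retry = 50L) {
  stopifnot(n >= 2)
  if (!is.numeric(p) || p <= 0 || p > 1)
    stop("p must lie in (0, 1]; p = 0 would never terminate")
  if (!is.null(seed)) set.seed(seed)
  n_now <- 2L
  emat <- matrix(c(0L, 1L), ncol = 2)  # grows; 0-based ids
  ekey <- c("0|1")
  while (n_now < n) {
    v <- sample.int(n_now, 1L) - 1L
    if (stats::runif(1) <= p) {
      emat <- rbind(emat, sort(c(v, n_now)))
      ekey <- c(ekey, paste(min(v, n_now), max(v, n_now), sep = "|"))
      n_now <- n_now + 1L
    } else {
      for (try in seq_len(max_retry)) {
        w <- sample.int(n_now, 1L) - 1L
        if (w == v) next
        key <- paste(min(v, w), max(v, w), sep = "|")
        if (!(key %in% ekey)) {
          emat <- rbind(emat, sort(c(v, w)))
          ekey <- c(ekey, key)
          break
        }
      }
    }
  }
  net <- cell_network(n, emat)
  stopifnot(is_connected(net), all(network_degrees(net) >= 1L))
  net
}

#' Assign intrinsic types to network nodes
#'
#' Labels `round(fraction * n)` nodes as intrinsic bursters and the rest as
#' spikers. Placement strategies: `"random"` draws the burster set uniformly;
#' `"defensive"` grows a connected burster cluster greedily so as to maximize
#' the burster homophily; `"offensive"` greedily picks nodes that minimize it
#' (preferring high-degree nodes not adjacent to already-chosen bursters);
#' `"explicit"` uses `bursters` as given (0-based ids).
#'
#' @param net an (unlabelled or labelled) `cell_network`.
#' @param fraction burster fraction in \[0, 1\] (ignored for `"explicit"`).
#' @param placement one of `"random"`, `"defensive"`, `"offensive"`,
#'   `"explicit"`.
#' @param bursters 0-based node ids for `placement = "explicit"`.
#' @param seed optional RNG seed (used by `"random"`).
#' @return labelled `cell_network`.
#' @export
assign_types <- function(net, fraction = 0.5,
                         placement = c("random", "defensive", "offensive", "explicit"),
                         bursters = NULL, seed = NULL) {
  placement <- match.arg(placement)
  n <- net$n
  if (placement == "explicit") {
    if (is.null(bursters)) stop("explicit placement needs a burster id list")
    bursters <- as.integer(bursters)
    if (any(bursters < 0L) || any(bursters >= n) || anyDuplicated(bursters))
      stop("explicit burster ids out of range or duplicated")
    set <- bursters + 1L
  } else {
    k <- round(fraction * n)
    if (k < 0 || k > n) stop("burster fraction out of range")
    if (!is.null(seed)) set.seed(seed)
    set <- switch(placement,
      random    = if (k > 0) sample.int(n, k) else integer(0),
      defensive = place_defensive(net, k),
      offensive = place_offensive(net, k))
  }
  types <- rep("s", n)
  types[set] <- "b"
  cell_network(n, net$edges, types)
}

# Gamma_b of a candidate burster set (1-based ids); NA when the set is empty
gamma_b_of_set <- function(nb, set) {
  if (!length(set)) return(NA_real_)
  mean(vapply(set, function(v) {
    d <- length(nb[[v]])
    if (d == 0L) return(NA_real_)
    sum(nb[[v]] %in% set) / d
  }, numeric(1)), na.rm = TRUE)
}

# greedy connected-cluster growth maximizing Gamma_b, best over all seeds
place_defensive <- function(net, k) {
  if (k == 0L) return(integer(0))
  nb <- neighbor_list(net)
  best <- NULL; best_gb <- -Inf
  for (start in seq_len(net$n)) {
    set <- start
    while (length(set) < k) {
      cand <- setdiff(unique(unlist(nb[set])), set)
      if (!length(cand)) cand <- setdiff(seq_len(net$n), set)
      sc <- vapply(cand, function(v) gamma_b_of_set(nb, c(set, v)), numeric(1))
      set <- c(set, cand[which.max(sc)])
    }
    gb <- gamma_b_of_set(nb, set)
    if (gb > best_gb) { best_gb <- gb; best <- set }
  }
  sort(best)
}

# greedy selection minimizing Gamma_b: prefer high-degree nodes away from
# already-chosen bursters
place_offensive <- function(net, k) {
  if (k == 0L) return(integer(0))
  nb <- neighbor_list(net)
  deg <- lengths(nb)
  set <- which.max(deg)
  while (length(set) < k) {
    cand <- setdiff(seq_len(net$n), set)
    sc <- vapply(cand, function(v) gamma_b_of_set(nb, c(set, v)), numeric(1))
    pick <- cand[sc == min(sc)]
    set <- c(set, pick[which.max(deg[pick])])
  }
  sort(set)
}

#' Burster and spiker homophily
#'
#' For every intrinsic burster, `gamma_b` is the fraction of its neighbors that
#' are bursters; `Gamma_b` is the mean of `gamma_b` over all bursters. The
#' spiker-side analogue `gamma_s` is the fraction of a spiker's neighbors that
#' are bursters, with mean `Gamma_s`. When a population is empty its mean is
#' flagged undefined (`NA`), never silently 0.
#'
#' @param net a labelled `cell_network`.
#' @return list with `gamma_b`, `gamma_s` (per-node values, named by 0-based
#'   node id), and scalar means `Gamma_b`, `Gamma_s` (`NA` when undefined).
#' @export
homophily <- function(net) {
  if (is.null(net$types)) stop("homophily needs a labelled network")
  nb <- neighbor_list(net)
  isb <- net$types == "b"
  frac_b <- vapply(seq_len(net$n), function(v) {
    d <- length(nb[[v]])
    if (d == 0L) return(NA_real_)
    sum(isb[nb[[v]]]) / d
  }, numeric(1))
  gb <- frac_b[isb]; names(gb) <- which(isb) - 1L
  gs <- frac_b[!isb]; names(gs) <- which(!isb) - 1L
  list(gamma_b = gb, gamma_s = gs,
       Gamma_b = if (any(isb)) mean(gb) else NA_real_,
       Gamma_s = if (any(!isb)) mean(gs) else NA_real_)
}

#' Read and write a cell network as a TSV edge list
#'
#' Format: a header line `#nodes N`, an optional header `#types b,s,...`
#' (comma-separated per-node labels), then one line `i<TAB>j` per undirected
#' edge with 0-based ids. The round-trip is bit-exact.
#'
#' @param net a `cell_network`.
#' @param path file path.
#' @return `read_network` returns a `cell_network`; `write_network` returns
#'   `path` invisibly.
#' @export
write_network <- function(net, path) {
  lines <- sprintf("#nodes %d", net$n)
  if (!is.null(net$types))
    lines <- c(lines, paste0("#types ", paste(net$types, collapse = ",")))
  if (nrow(net$edges))
    lines <- c(lines, sprintf("%d\t%d", net$edges[, 1], net$edges[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  nline <- grep("^#nodes ", lines, value = TRUE)
  if (length(nline) != 1L) stop("missing #nodes header")
  n <- as.integer(sub("^#nodes ", "", nline))
  tline <- grep("^#types ", lines, value = TRUE)
  types <- if (length(tline) == 1L)
    strsplit(sub("^#types ", "", tline), ",", fixed = TRUE)[[1]] else NULL
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.integer))
  } else matrix(integer(0), ncol = 2)
  cell_network(n, edges, types)
}
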