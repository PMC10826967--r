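# Event detection and classification on voltage traces, conversion and
# synchrony measures, and periodic-pattern detection.

# local maxima of a segment with at least the given prominence.
# Prominence of a peak is its height minus the higher of the two minima
# separating it from the nearest higher samples (or the segment ends).
peaks_with_prominence <- function(x, prominence) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]; h <- x[i]
    left <- x[seq_len(i)]
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[max(hi):i]) else min(left)
    right <- x[i:n]
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[seq_len(min(hi))]) else min(right)
    keep[k] <- (h - max(lmin, rmin)) >= prominence
  }
  cand[keep]
}

#' Detect depolarization events in a voltage trace
#'
#' Hysteresis detector: an event spans from an upward crossing of `V_on` to the
#' next downward crossing of `V_off` (`V_on > V_off`). Within each event, local
#' maxima with prominence of at least `prominence` mV are counted; an event
#' whose interior shows no prominent maximum still counts one peak (its
#' absolute maximum). Incomplete events at the window edges are dropped.
#'
#' @param V voltage samples (mV) on a uniform grid.
#' @param dt sample spacing (ms).
#' @param V_on onset threshold (mV).
#' @param V_off offset threshold (mV), below `V_on`.
#' @param prominence minimal peak prominence (mV).
#' @param t0 time of the first sample (ms); event times are absolute.
#' @return data.frame with columns `t_start`, `t_end` (ms) and `n_peaks`.
#' @export
detect_events <- function(V, dt, V_on = -35, V_off = -45, prominence = 2,
                          t0 = 0) {
  if (V_on <= V_off) stop("hysteresis requires V_on > V_off")
  n <- length(V)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      n_peaks = integer(0))
  if (n < 2L) return(empty)
  up <- which(V[-n] < V_on & V[-1] >= V_on) + 1L
  down <- which(V[-n] >= V_off & V[-1] < V_off) + 1L
  if (!length(up)) return(empty)
  rows <- list()
  i <- 1L
  for (u in up) {
    if (length(rows) && u <= rows[[length(rows)]]$end_i) next
    d <- down[down > u]
    if (!length(d)) break
    d <- d[1]
    seg <- V[u:d]
    np <- length(peaks_with_prominence(seg, prominence))
    rows[[length(rows) + 1L]] <- list(start_i = u, end_i = d,
                                      n_peaks = max(np, 1L))
  }
  if (!length(rows)) return(empty)
  data.frame(
    t_start = t0 + (vapply(rows, `[[`, numeric(1), "start_i") - 1) * dt,
    t_end   = t0 + (vapply(rows, `[[`, numeric(1), "end_i") - 1) * dt,
    n_peaks = vapply(rows, `[[`, integer(1), "n_peaks"))
}

#' Classify detected events
#'
#' Taxonomy: a single-peak event is a `"spike"`; two single-peak events whose
#' gap is below `doublet_gap` ms (the voltage re-crossing `V_off` in between)
#' are merged into one `"doublet"`; an event with `k >= 2` prominent peaks
#' inside one supra-threshold envelope is a `"k-spike burst"`; a burst whose
#' duration exceeds `long_factor` times the median burst duration of the train
#' is relabelled `"long burst"`.
#'
#' @param events data.frame from [detect_events()].
#' @param doublet_gap maximal gap (ms) merging two single spikes into a doublet.
#' @param long_factor long-burst duration factor.
#' @return data.frame with columns `t_start`, `t_end`, `n_peaks`, `label`.
#' @export
classify_events <- function(events, doublet_gap = 40, long_factor = 1.5) {
  n <- nrow(events)
  if (!n) {
    out <- events
    out$label <- character(0)
    return(out)
  }
  # merge successive single-peak events separated by a short sub-threshold gap
  merged <- list()
  k <- 1L
  while (k <= n) {
    if (k < n && events$n_peaks[k] == 1L && events$n_peaks[k + 1L] == 1L &&
        (events$t_start[k + 1L] - events$t_end[k]) < doublet_gap) {
      merged[[length(merged) + 1L]] <- data.frame(
        t_start = events$t_start[k], t_end = events$t_end[k + 1L],
        n_peaks = 2L, label = "doublet")
      k <- k + 2L
    } else {
      np <- events$n_peaks[k]
      merged[[length(merged) + 1L]] <- data.frame(
        t_start = events$t_start[k], t_end = events$t_end[k],
        n_peaks = np,
        label = if (np == 1L) "spike" else sprintf("%d-spike burst", np))
      k <- k + 1L
    }
  }
  out <- do.call(rbind, merged)
  isb <- grepl("burst", out$label)
  if (any(isb)) {
    dur <- out$t_end - out$t_start
    med <- stats::median(dur[isb])
    out$label[isb & dur > long_factor * med] <- "long burst"
  }
  out
}

#' Event train of one cell
#'
#' Convenience wrapper: detect and classify the events of one cell of a
#' trajectory over its analysis window.
#'
#' @param traj a `pitnet_traj`.
#' @param cell cell column index (1-based).
#' @param window analysis window `c(t_from, t_to)` in ms; defaults to the
#'   trajectory's post-transient window.
#' @param ... passed to [detect_events()] / [classify_events()].
#' @return classified event data.frame with an added `cell` column (0-based id).
#' @export
event_train <- function(traj, cell = 1L, window = traj$window, ...) {
  idx <- window_idx(traj, window)
  dots <- list(...)
  det_args <- dots[names(dots) %in% c("V_on", "V_off", "prominence")]
  cls_args <- dots[names(dots) %in% c("doublet_gap", "long_factor")]
  ev <- do.call(detect_events,
                c(list(V = traj$V[idx, cell], dt = traj$dt,
                       t0 = traj$times[idx[1]]), det_args))
  ev <- do.call(classify_events, c(list(events = ev), cls_args))
  if (nrow(ev)) ev$cell <- cell - 1L else ev$cell <- integer(0)
  ev
}

#' Export event trains as CSV
#'
#' @param trains a classified event data.frame (or rbind of several), with
#'   columns `cell`, `t_start`, `t_end`, `n_peaks`, `label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_events <- function(trains, path) {
  utils::write.csv(trains[, c("cell", "t_start", "t_end", "n_peaks", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Conversion test for a cell's event train
#'
#' A cell counts as converted to bursting when at least half of its classified
#' events are bursts (two or more peaks within one supra-threshold envelope;
#' doublets, being re-polarizing spike pairs, do not count).
#'
#' @param train classified event data.frame of one cell.
#' @param threshold burst fraction required for conversion.
#' @return list with `converted` (logical, `NA` for an empty train) and
#'   `burst_fraction`.
#' @export
is_converted_burster <- function(train, threshold = 0.5) {
  if (!nrow(train))
    return(list(converted = NA, burst_fraction = NA_real_))
  frac <- mean(grepl("burst", train$label))
  list(converted = frac >= threshold, burst_fraction = frac)
}

#' Minimal period of a symbol sequence
#'
#' Smallest `k` such that the sequence repeats with period `k` over the whole
#' window (exact symbol matching), requiring at least two full repeats
#' (`k <= length(symbols) / 2`). Returns `NA` when the sequence is aperiodic
#' within the window.
#'
#' @param symbols character (or atomic) vector of event labels.
#' @return integer period or `NA`.
#' @export
minimal_period <- function(symbols) {
  n <- length(symbols)
  for (k in seq_len(n %/% 2)) {
    if (all(symbols[seq_len(n - k)] == symbols[seq_len(n - k) + k]))
      return(k)
  }
  NA_integer_
}

#' Voltage synchrony index
#'
#' Mean over cell pairs of the maximum normalized cross-correlation of the
#' voltage traces within lags of +-`max_lag_ms`. With `max_lag_ms = 0` this is
#' the plain mean pairwise Pearson correlation. Allowing a small lag makes the
#' index report burst-level synchrony for phase-locked cells whose waveforms
#' align up to a short constant delay. Pairs involving a constant trace are
#' excluded with a warning.
#'
#' @param traj a `pitnet_traj` (or a numeric matrix of voltage columns).
#' @param window analysis window in ms (trajectory input only).
#' @param max_lag_ms maximal lag magnitude scanned (ms).
#' @param lag_step_ms lag grid spacing (ms); defaults to the sample spacing.
#' @return synchrony index in \[-1, 1\] (`NA` when no valid pair exists).
#' @export
synchrony_index <- function(traj, window = NULL, max_lag_ms = 50,
                            lag_step_ms = NULL) {
  if (inherits(traj, "pitnet_traj")) {
    if (is.null(window)) window <- traj$window
    idx <- window_idx(traj, window)
    V <- traj$V[idx, , drop = FALSE]
    dt <- traj$dt
  } else {
    V <- as.matrix(traj)
    dt <- if (is.null(lag_step_ms)) 1 else lag_step_ms
  }
  m <- ncol(V)
  if (m < 2L) stop("synchrony needs at least two cells")
  if (is.null(lag_step_ms)) lag_step_ms <- dt
  lag_n <- round(max_lag_ms / dt)
  lags <- unique(round(seq(-lag_n, lag_n, by = max(1, round(lag_step_ms / dt)))))
  sds <- apply(V, 2, stats::sd)
  vals <- c()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (sds[i] == 0 || sds[j] == 0) {
      warning(sprintf("constant trace: pair (%d, %d) excluded", i - 1, j - 1))
      next
    }
    nr <- nrow(V)
    best <- -Inf
    for (L in lags) {
      if (L >= 0) {
        a <- V[(1 + L):nr, i]; b <- V[1:(nr - L), j]
      } else {
        a <- V[1:(nr + L), i]; b <- V[(1 - L):nr, j]
      }
      best <- max(best, stats::cor(a, b))
    }
    vals <- c(vals, best)
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
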