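#' Per-sample microstate segmentation
#'
#' Holds the winner-take-all labeling of a recording: per-sample state
#' labels (0 = unlabeled), the absolute spatial correlation with the
#' winning map, and the GFP series. The full K x T squared-correlation
#' matrix is carried along (as `corr2`) so that temporal smoothing can
#' re-score candidate states without access to the raw recording.
#'
#' @param labels Integer vector, values in `0..K`.
#' @param abs_corr Numeric vector in `[0, 1]`, same length.
#' @param gfp Numeric vector, same length.
#' @param srate Sampling rate (Hz).
#' @param K Number of states.
#' @param corr2 Optional K x T squared-correlation matrix.
#' @return An object of class `ms_segmentation`.
#' @export
ms_segmentation <- function(labels, abs_corr, gfp, srate, K, corr2 = NULL) {
  n <- length(labels)
  if (length(abs_corr) != n || length(gfp) != n)
    stop("labels, abs_corr and gfp must have equal length")
  if (any(abs_corr < -1e-9 | abs_corr > 1 + 1e-9))
    stop("abs_corr must lie in [0, 1]")
  structure(list(labels = as.integer(labels),
                 abs_corr = pmin(pmax(abs_corr, 0), 1),
                 gfp = as.numeric(gfp),
                 srate = srate, K = as.integer(K), corr2 = corr2),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat("<ms_segmentation> ", length(x$labels), " samples @ ", x$srate,
      " Hz, K = ", x$K, ", unlabeled ",
      round(100 * mean(x$labels == 0L), 1), "%\n", sep = "")
  invisible(x)
}

# ms -> samples, round half up (32 ms at 250 Hz = 8 samples).
ms_to_samples <- function(ms, srate) as.integer(floor(ms * srate / 1000 + 0.5))

#' Normalize a recording by its median GFP
#'
#' Divides every sample by the scalar median of the GFP series, removing
#' between-subject scalp-potential scale differences (e.g. skull
#' conductivity) before backfitting. The resulting median GFP is 1.
#'
#' @param rec An [ms_recording()].
#' @return The rescaled recording.
#' @export
normalize_by_median_gfp <- function(rec) {
  g <- stats::median(gfp(rec))
  if (g <= 0) stop("median GFP is zero; cannot normalize")
  rec$data <- rec$data / g
  rec
}

#' Winner-take-all backfitting
#'
#' Labels every sample of a recording with the group map it correlates
#' best with, ignoring polarity. Samples whose best absolute correlation
#' falls below `min_corr` (default 0.50) remain unlabeled (state 0). Ties
#' go to the smallest state index.
#'
#' @param rec An [ms_recording()]; channels must match the maps.
#' @param maps An [ms_maps()].
#' @param min_corr Minimum absolute correlation for assignment.
#' @return An [ms_segmentation()].
#' @export
backfit <- function(rec, maps, min_corr = 0.50) {
  stopifnot(inherits(rec, "ms_recording"), inherits(maps, "ms_maps"))
  if (ncol(maps$maps) != nrow(rec$data))
    stop("maps have ", ncol(maps$maps), " channels but the recording has ",
         nrow(rec$data))
  U <- unit_columns(rec$data)$u
  C <- abs(maps$maps %*% U)                 # K x T absolute correlations
  winner <- max.col(t(C), ties.method = "first")
  ac <- C[cbind(winner, seq_len(ncol(C)))]
  labels <- ifelse(ac >= min_corr, winner, 0L)
  ms_segmentation(labels, ac, gfp(rec), rec$srate, nrow(maps$maps),
                  corr2 = C^2)
}

#' Temporal smoothing of microstate labels
#'
#' Iterative windowed relabeling in the spirit of the classic segmentation
#' smoother: for each labeled sample t, every candidate state k receives
#' the score `(1 - corr2[k, t]) * gfp(t)^2 - lambda * N_k(t)`, where
#' `N_k(t)` counts the labeled samples within +/- the window half-size
#' currently labeled k (the sample itself excluded), and all labeled
#' samples are simultaneously relabeled to their arg-min state. Sweeps
#' repeat until no label changes or `max_sweeps` is reached. The penalty
#' weight is `lambda = besag_factor * r / (2w + 1)` with `r` the mean
#' residual (GFP-squared-weighted unexplained variance) of the labeled
#' samples, which normalizes the Besag factor by the noise scale and makes
#' the smoothing invariant to microvolt rescaling. Unlabeled samples are
#' never relabeled and do not count as neighbours.
#'
#' @param seg An [ms_segmentation()] carrying `corr2` (as produced by
#'   [backfit()]).
#' @param window_half_size_ms Window half-size in ms (default 32).
#' @param besag_factor Penalty factor (default 10); 0 disables smoothing.
#' @param max_sweeps Sweep cap (default 50).
#' @return The smoothed [ms_segmentation()] (with `abs_corr` updated to
#'   the final label's map).
#' @export
smooth_labels <- function(seg, window_half_size_ms = 32, besag_factor = 10,
                          max_sweeps = 50L) {
  stopifnot(inherits(seg, "ms_segmentation"))
  if (is.null(seg$corr2))
    stop("segmentation lacks the corr2 matrix needed for smoothing")
  w <- max(1L, ms_to_samples(window_half_size_ms, seg$srate))
  K <- seg$K
  T_ <- length(seg$labels)
  lab <- seg$labels
  labeled <- lab != 0L
  if (!any(labeled) || besag_factor < 0) return(seg)
  # penalty scale: the mean residual (unexplained GFP power) of the
  # labeled samples, in the spirit of the original noise-variance
  # normalization; scale-free under microvolt rescaling
  resid <- (1 - seg$corr2[cbind(lab[labeled], which(labeled))]) *
    seg$gfp[labeled]^2
  lambda <- besag_factor * mean(resid) / (2 * w + 1)
  seg$labels <- smooth_labels_core(lab, seg$corr2, seg$gfp^2, as.integer(w),
                                   lambda, as.integer(max_sweeps))
  refresh_abs_corr(seg)
}

# Recompute abs_corr against the final label's map (unlabeled keep the
# winning-map correlation from backfit).
refresh_abs_corr <- function(seg) {
  if (is.null(seg$corr2)) return(seg)
  labeled <- seg$labels != 0L
  seg$abs_corr[labeled] <-
    sqrt(seg$corr2[cbind(seg$labels[labeled], which(labeled))])
  seg
}

#' Reject improbably small segments
#'
#' Every maximal run shorter than `min_duration_ms` is divided in half:
#' the first `ceiling(L/2)` samples take the preceding segment's label and
#' the remaining `floor(L/2)` the following segment's. Runs at the
#' sequence edges merge entirely into their single neighbour. The rule is
#' applied iteratively (shortest run first, ties to the leftmost) until no
#' run shorter than the minimum remains; merged runs only grow, so the
#' procedure terminates. Unlabeled runs are treated like ordinary states.
#'
#' @param seg An [ms_segmentation()].
#' @param min_duration_ms Minimum segment duration in ms (default 32).
#' @return The cleaned [ms_segmentation()].
#' @export
reject_small_segments <- function(seg, min_duration_ms = 32) {
  stopifnot(inherits(seg, "ms_segmentation"))
  min_len <- ms_to_samples(min_duration_ms, seg$srate)
  lab <- reject_small_core(seg$labels, as.integer(min_len))
  seg$labels <- as.integer(lab)
  refresh_abs_corr(seg)
}

#' Full backfitting stack for one continuous block
#'
#' Median-GFP normalization, winner-take-all backfitting, temporal
#' smoothing, and small-segment rejection, in that order.
#'
#' @param rec An [ms_recording()].
#' @param maps An [ms_maps()].
#' @param min_corr,smooth_half_ms,besag_factor,min_seg_ms Stage
#'   parameters (defaults 0.50, 32 ms, 10, 32 ms).
#' @param normalize Apply median-GFP normalization first (default TRUE).
#' @return An [ms_segmentation()].
#' @export
segment_recording <- function(rec, maps, min_corr = 0.50,
                              smooth_half_ms = 32, besag_factor = 10,
                              min_seg_ms = 32, normalize = TRUE) {
  if (normalize) rec <- normalize_by_median_gfp(rec)
  seg <- backfit(rec, maps, min_corr = min_corr)
  seg <- smooth_labels(seg, window_half_size_ms = smooth_half_ms,
                       besag_factor = besag_factor)
  reject_small_segments(seg, min_duration_ms = min_seg_ms)
}

# Runs of each block of a segmentation (or list of segmentations treated
# as independent continuous blocks). Returns a data.frame with state,
# length (samples), edge (touches a block boundary).
segment_runs <- function(segs) {
  if (inherits(segs, "ms_segmentation")) segs <- list(segs)
  out <- lapply(segs, function(s) {
    r <- rle(s$labels)
    n <- length(r$lengths)
    data.frame(state = r$values, length = r$lengths,
               edge = seq_len(n) == 1L | seq_len(n) == n)
  })
  do.call(rbind, out)
}

#' Temporal properties of a segmentation
#'
#' Per state: global explained variance
#' `gev_k = sum over t labeled k of (gfp(t) * abs_corr(t))^2 / sum of
#' gfp(t)^2`, coverage (fraction of all samples), mean segment duration
#' (ms), and occurrence (segments per second). By default segments
#' touching the sequence edges are excluded from duration and occurrence
#' (they are truncated by the recording boundary) but still count towards
#' coverage and GEV; set `exclude_edge_segments = FALSE` for the exact
#' identity `coverage = occurrence * duration / 1000`. A state that never
#' occurs has `NA` duration and zero coverage/occurrence/GEV.
#'
#' A list of segmentations is treated as independent continuous blocks of
#' the same subject (e.g. the even or odd blocks of a split half): runs
#' never span blocks and block boundaries count as edges.
#'
#' @param seg An [ms_segmentation()] or a list of them.
#' @param exclude_edge_segments Exclude boundary-touching runs from
#'   duration/occurrence (default TRUE).
#' @return A list of class `ms_metrics`: `states` (data.frame with
#'   `state`, `gev`, `mean_duration_ms`, `coverage`, `occurrence`),
#'   `total_gev`, `unlabeled_fraction`, `n_samples`, `srate`.
#' @export
temporal_metrics <- function(seg, exclude_edge_segments = TRUE) {
  segs <- if (inherits(seg, "ms_segmentation")) list(seg) else seg
  K <- segs[[1L]]$K
  srate <- segs[[1L]]$srate
  labels <- unlist(lapply(segs, `[[`, "labels"))
  ac <- unlist(lapply(segs, `[[`, "abs_corr"))
  g <- unlist(lapply(segs, `[[`, "gfp"))
  T_ <- length(labels)
  if (!T_) stop("empty segmentation")
  denom <- sum(g^2)
  runs <- segment_runs(segs)
  if (exclude_edge_segments) runs_do <- runs[!runs$edge, , drop = FALSE]
  else runs_do <- runs
  states <- data.frame(state = seq_len(K), gev = NA_real_,
                       mean_duration_ms = NA_real_, coverage = NA_real_,
                       occurrence = NA_real_)
  total_sec <- T_ / srate
  for (k in seq_len(K)) {
    sel <- labels == k
    states$coverage[k] <- sum(sel) / T_
    states$gev[k] <- if (denom > 0) sum((g[sel] * ac[sel])^2) / denom else 0
    rk <- runs_do$length[runs_do$state == k]
    states$mean_duration_ms[k] <- if (length(rk)) mean(rk) * 1000 / srate
                                  else NA_real_
    states$occurrence[k] <- length(rk) / total_sec
  }
  structure(list(states = states, total_gev = sum(states$gev),
                 unlabeled_fraction = mean(labels == 0L),
                 n_samples = T_, srate = srate),
            class = "ms_metrics")
}

#' @export
print.ms_metrics <- function(x, ...) {
  cat("<ms_metrics> total GEV ", round(x$total_gev, 3), ", unlabeled ",
      round(100 * x$unlabeled_fraction, 1), "%\n", sep = "")
  print(x$states, digits = 3)
  invisible(x)
}

#' First-order Markov transition statistics
#'
#' Counts transitions between consecutive distinct labeled segments.
#' Unlabeled runs break the chain: no transition is counted across them.
#' Observed probabilities normalize each origin's counts to 1; expected
#' probabilities under an occurrence-matched null are
#' `expected[A, B] = seg_count(B) / sum over C != A of seg_count(C)`,
#' where `seg_count` is the number of labeled segments of each state; the
#' normalized matrix is their elementwise ratio (0/0 reported as `NA`).
#'
#' @param seg An [ms_segmentation()] or a list of them (blocks; chains
#'   never span blocks).
#' @return A list of class `ms_transitions`: `observed`, `expected`,
#'   `normalized` (K x K, zero diagonal), `counts`, `n_transitions`,
#'   `seg_counts`.
#' @export
transition_probabilities <- function(seg) {
  segs <- if (inherits(seg, "ms_segmentation")) list(seg) else seg
  K <- segs[[1L]]$K
  counts <- matrix(0, K, K)
  seg_counts <- numeric(K)
  for (s in segs) {
    r <- rle(s$labels)
    v <- r$values
    for (k in seq_len(K)) seg_counts[k] <- seg_counts[k] + sum(v == k)
    # split the run sequence at unlabeled runs; count within stretches
    stretch <- split(v, cumsum(v == 0L))
    for (st in stretch) {
      st <- st[st != 0L]
      if (length(st) >= 2L)
        for (i in seq_len(length(st) - 1L))
          counts[st[i], st[i + 1L]] <- counts[st[i], st[i + 1L]] + 1
    }
  }
  if (sum(seg_counts) < 2L)
    stop("need at least 2 labeled segments for transition statistics")
  obs <- counts
  rs <- rowSums(counts)
  obs[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  expd <- matrix(0, K, K)
  for (a in seq_len(K)) {
    denom <- sum(seg_counts[-a])
    if (denom > 0) expd[a, ] <- seg_counts / denom
    expd[a, a] <- 0
  }
  norm <- obs / expd
  norm[expd == 0 & obs == 0] <- NA_real_
  diag(norm) <- 0
  dimnames(counts) <- dimnames(obs) <- dimnames(expd) <- dimnames(norm) <-
    list(from = seq_len(K), to = seq_len(K))
  structure(list(observed = obs, expected = expd, normalized = norm,
                 counts = counts, n_transitions = sum(counts),
                 seg_counts = seg_counts),
            class = "ms_transitions")
}

#' Tidy per-subject metric table
#'
#' Long-format export of temporal properties and (optionally) normalized
#' transition probabilities, one row per subject x state x metric, ready
#' for external mixed-model tooling.
#'
#' @param metrics An `ms_metrics` (from [temporal_metrics()]).
#' @param transitions Optional `ms_transitions`.
#' @param subject Subject identifier.
#' @param duration_min Data duration label.
#' @return A data.frame with columns `subject`, `duration_min`, `state`,
#'   `metric`, `value`.
#' @export
metrics_table <- function(metrics, transitions = NULL, subject = NA,
                          duration_min = NA) {
  st <- metrics$states
  long <- do.call(rbind, lapply(
    c("gev", "mean_duration_ms", "coverage", "occurrence"),
    function(m) data.frame(subject = subject, duration_min = duration_min,
                           state = as.character(st$state), metric = m,
                           value = st[[m]])))
  if (!is.null(transitions)) {
    K <- nrow(transitions$normalized)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      if (a == b) next
      long <- rbind(long, data.frame(
        subject = subject, duration_min = duration_min,
        state = paste0(a, "->", b), metric = "transition_norm",
        value = transitions$normalized[a, b]))
    }
  }
  rownames(long) <- NULL
  long
}
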