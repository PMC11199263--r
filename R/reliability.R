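#' Even/odd split of a recording
#'
#' Divides a recording into `n_segments` contiguous equal blocks (any
#' trailing remainder shorter than `n_segments` samples is dropped) and
#' concatenates the odd-numbered blocks into one half and the even ones
#' into the other. Both halves are returned as lists of block recordings
#' so that downstream backfitting treats every block as an independent
#' continuous stretch (smoothing windows and transition chains do not
#' cross block joins).
#'
#' @param rec An [ms_recording()] with at least `n_segments` samples.
#' @param n_segments Number of blocks (default 6).
#' @return A list: `odd` and `even`, each a list of [ms_recording()]
#'   blocks, plus `block_len`.
#' @export
split_even_odd <- function(rec, n_segments = 6L) {
  T_ <- n_samples(rec)
  if (T_ < n_segments) stop("recording too short to split into ",
                            n_segments, " segments")
  block_len <- T_ %/% n_segments
  take <- function(b) {
    idx <- ((b - 1L) * block_len + 1L):(b * block_len)
    r <- rec
    r$data <- rec$data[, idx, drop = FALSE]
    r
  }
  blocks <- lapply(seq_len(n_segments), take)
  list(odd = blocks[seq(1L, n_segments, by = 2L)],
       even = blocks[seq(2L, n_segments, by = 2L)],
       block_len = block_len)
}

#' Spearman-Brown split-half coefficient
#'
#' Pearson correlation of the two half measurements across subjects,
#' corrected to full test length: `sb = 2 r / (1 + r)`. Undefined (`NA`)
#' when fewer than 3 finite pairs remain, when either half has zero
#' variance, or when r = -1.
#'
#' @param x,y Per-subject values from half A and half B.
#' @return A list with `r` and `sb`.
#' @export
spearman_brown <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, sb = NA_real_))
  r <- stats::cor(x, y)
  sb <- if (r <= -1) NA_real_ else 2 * r / (1 + r)
  list(r = r, sb = sb)
}

#' Boxplot-rule outlier mask
#'
#' Flags values above `Q3 + factor * IQR` or below `Q1 - factor * IQR`,
#' with quartiles computed by linear interpolation between order
#' statistics (R's default quantile type 7).
#'
#' @param values Numeric vector (>= 4 values).
#' @param factor IQR multiplier (default 3, the extreme-outlier rule).
#' @return Logical mask, `TRUE` = outlier. `NA` values are never flagged.
#' @export
boxplot_outliers <- function(values, factor = 3) {
  if (sum(is.finite(values)) < 4L) return(rep(FALSE, length(values)))
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7)
  iqr <- q[2L] - q[1L]
  out <- values > q[2L] + factor * iqr | values < q[1L] - factor * iqr
  out[!is.finite(values)] <- FALSE
  out
}

#' Qualitative reliability descriptor
#'
#' Bands a reliability estimate: poor below 0.40, fair from 0.40 up to
#' (but excluding) 0.60, good from 0.60 up to (but excluding) 0.75,
#' excellent at 0.75 and above. Comparison is literal on the raw value,
#' with no rounding.
#'
#' @param value Numeric (vectorized).
#' @return Character vector of descriptors (`NA` in, `NA` out).
#' @export
qualitative_descriptor <- function(value) {
  out <- rep(NA_character_, length(value))
  fin <- is.finite(value)
  out[fin & value < 0.40] <- "poor"
  out[fin & value >= 0.40 & value < 0.60] <- "fair"
  out[fin & value >= 0.60 & value < 0.75] <- "good"
  out[fin & value >= 0.75] <- "excellent"
  out
}

# Per-subject half metrics: backfit the blocks of one half and return the
# tidy metric vector (temporal properties per state + normalized
# transition directions).
half_metrics <- function(blocks, maps, backfit_params) {
  segs <- lapply(blocks, function(b)
    do.call(segment_recording, c(list(rec = b, maps = maps), backfit_params)))
  met <- temporal_metrics(segs)
  tr <- tryCatch(transition_probabilities(segs), error = function(e) NULL)
  metrics_table(met, tr)
}

#' Even/odd split-half internal consistency suite
#'
#' For every data duration: crops each subject's recording, splits it into
#' even and odd block halves, runs the full backfitting stack on every
#' block, computes per-state temporal properties and normalized transition
#' probabilities on each half, and correlates the two halves across
#' subjects with the Spearman-Brown correction. Results are reported both
#' without and with outlier removal (the boxplot rule applied per metric
#' x state x duration cell, separately within each half; a subject
#' flagged in either half is dropped for that cell only). Per-cell
#' failures propagate as `NA` rather than aborting the table.
#'
#' @param recordings List of [ms_recording()] (one per subject, all at
#'   least `max(durations)` minutes long).
#' @param maps Group-level [ms_maps()] used for backfitting.
#' @param durations Data durations in minutes (default 1:5).
#' @param n_segments Blocks per split (default 6).
#' @param outlier_factor IQR multiplier of the boxplot rule (default 3).
#' @param backfit_params Named list overriding [segment_recording()]
#'   defaults.
#' @return A data.frame of class `ms_splithalf`: one row per duration x
#'   metric x state x outlier-handling, with `pearson_r`, `sb`,
#'   `descriptor`, `n_subjects_used`.
#' @export
internal_consistency_suite <- function(recordings, maps, durations = 1:5,
                                       n_segments = 6L, outlier_factor = 3,
                                       backfit_params = list()) {
  rows <- list()
  for (d in durations) {
    valsA <- list(); valsB <- list()
    for (s in seq_along(recordings)) {
      rec <- crop_to_duration(recordings[[s]], d)
      halves <- split_even_odd(rec, n_segments = n_segments)
      a <- tryCatch(half_metrics(halves$odd, maps, backfit_params),
                    error = function(e) NULL)
      b <- tryCatch(half_metrics(halves$even, maps, backfit_params),
                    error = function(e) NULL)
      valsA[[s]] <- a; valsB[[s]] <- b
    }
    ok <- !vapply(valsA, is.null, logical(1L)) &
          !vapply(valsB, is.null, logical(1L))
    if (!any(ok)) next
    template <- valsA[[which(ok)[1L]]]
    cells <- unique(template[, c("metric", "state")])
    for (i in seq_len(nrow(cells))) {
      m <- cells$metric[i]; st <- cells$state[i]
      pick <- function(v) {
        if (is.null(v)) return(NA_real_)
        val <- v$value[v$metric == m & v$state == st]
        if (length(val) != 1L) NA_real_ else val
      }
      xa <- vapply(valsA, pick, numeric(1L))
      xb <- vapply(valsB, pick, numeric(1L))
      for (remove_out in c(FALSE, TRUE)) {
        keep <- rep(TRUE, length(xa))
        if (remove_out)
          keep <- !(boxplot_outliers(xa, outlier_factor) |
                    boxplot_outliers(xb, outlier_factor))
        sbres <- spearman_brown(xa[keep], xb[keep])
        rows[[length(rows) + 1L]] <- data.frame(
          duration_min = d, metric = m, state = st,
          outliers_removed = remove_out,
          n_subjects_used = sum(keep & is.finite(xa) & is.finite(xb)),
          pearson_r = sbres$r, sb = sbres$sb,
          descriptor = qualitative_descriptor(sbres$sb))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ms_splithalf", class(out))
  out
}

#' Stability of maps and metrics across data durations
#'
#' Runs the full two-level clustering at every data duration, matches the
#' resulting group maps across all duration pairs by absolute spatial
#' correlation, backfits every subject at every duration with that
#' duration's maps (states aligned to the longest duration's maps), and
#' summarizes per metric and state the paired differences between
#' durations (mean, SD) and their Pearson correlation across subjects.
#'
#' @param recordings List of [ms_recording()] per subject.
#' @param durations Durations in minutes (default 1:5).
#' @param k_range_individual,k_range_group Search ranges for the two
#'   clustering levels.
#' @param n_epochs_individual,n_epochs_group,n_repeats Resampling effort.
#' @param seed Master seed.
#' @param force_k Optional fixed group-level k (applied at every
#'   duration).
#' @param backfit_params Named list overriding [segment_recording()]
#'   defaults.
#' @return A list of class `ms_stability`: `map_corr` (data.frame of
#'   matched-map |correlations| per duration pair), `chosen_k` (per
#'   duration), `metrics` (tidy per subject x duration x state table),
#'   `pairwise` (per duration pair x metric x state: mean and SD of
#'   paired differences, Pearson r), `group_maps` (per duration).
#' @export
stability_suite <- function(recordings, durations = 1:5,
                            k_range_individual = 2:7,
                            k_range_group = 2:8,
                            n_epochs_individual = 8L,
                            n_epochs_group = 20L,
                            n_repeats = 5L, seed = 1L, force_k = NULL,
                            backfit_params = list()) {
  group_by_dur <- list()
  for (d in durations) {
    ind <- lapply(seq_along(recordings), function(s)
      individual_clustering(crop_to_duration(recordings[[s]], d),
                            k_range = k_range_individual,
                            n_epochs = n_epochs_individual,
                            n_repeats = n_repeats,
                            seed = derive_seed(seed, "stab-ind", d, s)))
    group_by_dur[[as.character(d)]] <-
      group_level_clustering(ind, k_range = k_range_group,
                             n_epochs = n_epochs_group,
                             n_repeats = n_repeats,
                             seed = derive_seed(seed, "stab-group", d),
                             force_k = force_k)
  }
  ref <- as.character(max(durations))
  # align every duration's maps to the longest duration's state order
  aligned <- list()
  for (d in as.character(durations)) {
    g <- group_by_dur[[d]]
    mm <- match_maps(group_by_dur[[ref]]$maps, g$maps)
    ord <- mm$pairs$b[order(mm$pairs$a)]
    extra <- setdiff(seq_len(nrow(g$maps$maps)), ord)
    aligned[[d]] <- ms_maps(g$maps$maps[c(ord, extra), , drop = FALSE])
  }
  # matched-map correlations for every duration pair
  map_rows <- list()
  dd <- as.character(durations)
  for (i in seq_along(dd)) for (j in seq_along(dd)) {
    if (i >= j) next
    mm <- match_maps(aligned[[dd[i]]], aligned[[dd[j]]])
    map_rows[[length(map_rows) + 1L]] <- data.frame(
      duration_a = durations[i], duration_b = durations[j],
      state = mm$pairs$a, abs_corr = mm$pairs$abs_corr)
  }
  map_corr <- do.call(rbind, map_rows)
  # backfit everyone at every duration
  met_rows <- list()
  for (d in durations) {
    maps_d <- aligned[[as.character(d)]]
    for (s in seq_along(recordings)) {
      rec <- crop_to_duration(recordings[[s]], d)
      seg <- do.call(segment_recording,
                     c(list(rec = rec, maps = maps_d), backfit_params))
      met <- temporal_metrics(seg)
      tr <- tryCatch(transition_probabilities(seg), error = function(e) NULL)
      met_rows[[length(met_rows) + 1L]] <-
        metrics_table(met, tr, subject = s, duration_min = d)
    }
  }
  metrics <- do.call(rbind, met_rows)
  pairwise <- pairwise_duration_stats(metrics)
  structure(list(map_corr = map_corr,
                 chosen_k = vapply(group_by_dur, `[[`, numeric(1L),
                                   "chosen_k"),
                 metrics = metrics, pairwise = pairwise,
                 group_maps = aligned),
            class = "ms_stability")
}

# Mean/SD of paired differences and Pearson r for every duration pair,
# computed from the tidy metrics table.
pairwise_duration_stats <- function(metrics) {
  durs <- sort(unique(metrics$duration_min))
  cells <- unique(metrics[, c("metric", "state")])
  rows <- list()
  for (i in seq_along(durs)) for (j in seq_along(durs)) {
    if (i >= j) next
    for (c_ in seq_len(nrow(cells))) {
      m <- cells$metric[c_]; st <- cells$state[c_]
      a <- metrics[metrics$duration_min == durs[i] & metrics$metric == m &
                     metrics$state == st, ]
      b <- metrics[metrics$duration_min == durs[j] & metrics$metric == m &
                     metrics$state == st, ]
      merged <- merge(a[, c("subject", "value")], b[, c("subject", "value")],
                      by = "subject", suffixes = c("_a", "_b"))
      ok <- is.finite(merged$value_a) & is.finite(merged$value_b)
      dif <- merged$value_b[ok] - merged$value_a[ok]
      r <- if (sum(ok) >= 3L && stats::sd(merged$value_a[ok]) > 0 &&
               stats::sd(merged$value_b[ok]) > 0)
        stats::cor(merged$value_a[ok], merged$value_b[ok]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        duration_a = durs[i], duration_b = durs[j], metric = m, state = st,
        mean_diff = if (length(dif)) mean(dif) else NA_real_,
        sd_diff = if (length(dif) > 1L) stats::sd(dif) else NA_real_,
        pearson_r = r, n = sum(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Slice-wise Dice similarity coefficient
#'
#' For each of the three axes, computes the Dice coefficient
#' `2 |A and B| / (|A| + |B|)` on every slice where either volume has at
#' least one nonzero voxel, averages over those slices, and then averages
#' the three axis values.
#'
#' @param a,b [ms_volume()] objects with identical grid shape.
#' @return A list: `mean` (grand mean over axes), `by_axis` (length 3),
#'   `global` (whole-volume Dice, for reference).
#' @export
dice_slicewise <- function(a, b) {
  stopifnot(inherits(a, "ms_volume"), inherits(b, "ms_volume"))
  if (!identical(dim(a$grid), dim(b$grid))) stop("volume shapes differ")
  A <- a$grid; B <- b$grid
  if (sum(A) == 0 && sum(B) == 0) stop("both volumes are empty")
  axis_mean <- numeric(3L)
  for (ax in 1:3) {
    n_slices <- dim(A)[ax]
    vals <- numeric(0)
    for (s in seq_len(n_slices)) {
      sa <- slice_of(A, ax, s); sb <- slice_of(B, ax, s)
      na <- sum(sa); nb <- sum(sb)
      if (na + nb == 0) next
      vals <- c(vals, 2 * sum(sa & sb) / (na + nb))
    }
    axis_mean[ax] <- if (length(vals)) mean(vals) else NA_real_
  }
  list(mean = mean(axis_mean),
       by_axis = axis_mean,
       global = 2 * sum(A & B) / (sum(A) + sum(B)))
}

slice_of <- function(arr, axis, i) {
  switch(axis,
         arr[i, , , drop = TRUE],
         arr[, i, , drop = TRUE],
         arr[, , i, drop = TRUE])
}
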