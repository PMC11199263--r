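#' Robust spatial filtering of topographies
#'
#' Instantaneous spatial cleaning applied independently at every time
#' point: each channel is compared with the median of its `n_neighbors`
#' spatially nearest channels; channels deviating from that median by more
#' than `mad_factor` times the median absolute deviation of all
#' channel-vs-median residuals are replaced by the median (topographic
#' outlier removal), and all channels are then blended 50/50 with their
#' neighbour medians (topographic smoothing). The output is
#' re-average-referenced. This is an instantaneous robust neighbour
#' filter in the spirit of interpolation-based topographic cleaning; it
#' is optional and makes no claim of equivalence with any specific
#' software's filter.
#'
#' @param rec An [ms_recording()]; the montage must carry positions.
#' @param n_neighbors Number of nearest neighbours (>= 3, less than the
#'   channel count; default 6).
#' @param mad_factor Outlier threshold in MADs (default 3).
#' @param blend Smoothing weight of the neighbour median (default 0.5).
#' @return The filtered, average-referenced recording.
#' @export
spatial_filter <- function(rec, n_neighbors = 6L, mad_factor = 3,
                           blend = 0.5) {
  stopifnot(inherits(rec, "ms_recording"))
  N <- nrow(rec$data)
  if (n_neighbors < 3L) stop("n_neighbors must be >= 3")
  if (n_neighbors >= N) stop("n_neighbors must be below the channel count")
  pos <- rec$montage$positions
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nbr <- t(apply(d, 1L, function(x) order(x)[seq_len(n_neighbors)])) - 1L
  out <- spatial_filter_core(rec$data, nbr, mad_factor, blend)
  rec$data <- out
  average_reference(rec)
}
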