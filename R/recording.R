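#' Channel montage
#'
#' A montage pairs channel names with 3-D sensor positions (head-centred,
#' arbitrary but consistent units). Positions are needed by the spatial
#' filter and by the synthetic map generator; purely temporal operations
#' only use the channel names.
#'
#' @param names Character vector of unique, non-empty channel identifiers.
#' @param positions Numeric matrix, one row per channel, three columns
#'   (x, y, z). All values must be finite.
#' @return An object of class `ms_montage`.
#' @export
ms_montage <- function(names, positions) {
  names <- as.character(names)
  positions <- as.matrix(positions)
  if (length(names) < 2L) stop("a montage needs at least 2 channels")
  if (anyDuplicated(names) || any(!nzchar(names)))
    stop("channel names must be unique and non-empty")
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    stop("positions must be a ", length(names), " x 3 matrix")
  if (!all(is.finite(positions))) stop("montage positions must be finite")
  rownames(positions) <- names
  structure(list(names = names, positions = positions), class = "ms_montage")
}

#' @export
print.ms_montage <- function(x, ...) {
  cat("<ms_montage> ", length(x$names), " channels\n", sep = "")
  invisible(x)
}

#' Continuous EEG recording
#'
#' A recording is a channels x samples matrix of scalp potentials in
#' microvolts, together with its sampling rate and montage. The
#' `is_avg_ref` flag records whether the data are average-referenced
#' (every column sums to zero); most downstream operations require it.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param srate Sampling rate in Hz (> 0).
#' @param montage An [ms_montage()] whose size matches `nrow(data)`.
#' @param is_avg_ref Logical; declare the data average-referenced. Checked
#'   against the data within a tolerance of 1e-8 of the matrix maximum
#'   absolute value.
#' @return An object of class `ms_recording`.
#' @export
ms_recording <- function(data, srate, montage, is_avg_ref = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("srate must be a single positive number")
  if (!inherits(montage, "ms_montage")) stop("montage must be an ms_montage")
  if (nrow(data) != length(montage$names))
    stop("data has ", nrow(data), " rows but montage lists ",
         length(montage$names), " channels")
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  if (isTRUE(is_avg_ref)) {
    tol <- 1e-8 * max(abs(data), 1e-12)
    if (max(abs(colSums(data))) > tol * nrow(data))
      stop("is_avg_ref = TRUE but column sums are not zero")
  }
  rownames(data) <- montage$names
  structure(list(data = data, srate = srate, montage = montage,
                 is_avg_ref = isTRUE(is_avg_ref)),
            class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat("<ms_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz (",
      round(ncol(x$data) / x$srate, 2), " s), ",
      if (x$is_avg_ref) "average-referenced" else "not average-referenced",
      "\n", sep = "")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Re-reference a recording to the common average
#'
#' Subtracts the mean across channels from every time point so that each
#' column of the data matrix sums to zero. Idempotent.
#'
#' @param rec An [ms_recording()].
#' @return The average-referenced recording (`is_avg_ref = TRUE`).
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "ms_recording"))
  d <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec$data <- d
  rec$is_avg_ref <- TRUE
  rec
}

#' Crop a recording to its first N minutes
#'
#' Returns the first `minutes * 60 * srate` samples, so crops of increasing
#' duration are nested prefixes of one another.
#'
#' @param rec An [ms_recording()].
#' @param minutes Duration to keep, in minutes.
#' @return The cropped recording.
#' @export
crop_to_duration <- function(rec, minutes) {
  stopifnot(inherits(rec, "ms_recording"))
  n <- as.integer(round(minutes * 60 * rec$srate))
  if (n_samples(rec) < n)
    stop("recording has ", n_samples(rec), " samples but ", n,
         " were requested (", minutes, " min at ", rec$srate, " Hz)")
  rec$data <- rec$data[, seq_len(n), drop = FALSE]
  rec
}
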