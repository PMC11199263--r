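#' Read a continuous recording
#'
#' The native interchange format is a channels x samples TSV (channels as
#' rows, no header) accompanied by a JSON sidecar named `<path>.json` with
#' fields `srate_hz`, `channel_names`, `reference`, `units` and, optionally,
#' `channel_positions` (n x 3). Time is serialized 0-based; durations are in
#' ms. Units are fixed to microvolts; no unit inference is performed.
#'
#' Standard EEG containers (EEGLAB `.set`, BrainVision, EDF) are accepted
#' format names for forward compatibility but currently raise an error:
#' no reader for them ships with this package. Preprocessed data should be
#' exported to the tabular format.
#'
#' @param path Path to the TSV data file.
#' @param format_name One of `"tabular+sidecar"`, `"eeglab-set"`,
#'   `"brainvision"`, `"edf"`.
#' @return An [ms_recording()].
#' @export
read_recording <- function(path, format_name = "tabular+sidecar") {
  format_name <- match.arg(format_name,
                           c("tabular+sidecar", "eeglab-set", "brainvision", "edf"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format_name != "tabular+sidecar")
    stop("no reader for format '", format_name,
         "' is available; export the data to the tabular+sidecar format")
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar file: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("srate_hz", "channel_names"))
    if (is.null(meta[[f]])) stop("sidecar is missing required field '", f, "'")
  dat <- unname(as.matrix(data.table::fread(path, header = FALSE, sep = "\t")))
  if (!is.numeric(dat)) stop("non-numeric cells in ", path)
  if (nrow(dat) != length(meta$channel_names))
    stop("data file has ", nrow(dat), " rows but sidecar lists ",
         length(meta$channel_names), " channels")
  pos <- meta$channel_positions
  if (is.null(pos)) {
    # no positions recorded: place channels on a default hemispheric layout
    pos <- hemisphere_positions(length(meta$channel_names))
  }
  montage <- ms_montage(meta$channel_names, pos)
  ms_recording(dat, meta$srate_hz, montage,
               is_avg_ref = identical(meta$reference, "average"))
}

#' Write a continuous recording
#'
#' Writes the tabular TSV + JSON sidecar format read by [read_recording()].
#'
#' @param rec An [ms_recording()].
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ms_recording"))
  # %.17g round-trips IEEE doubles exactly through the text format
  lines <- apply(rec$data, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  meta <- list(srate_hz = rec$srate,
               channel_names = rec$montage$names,
               channel_positions = unname(rec$montage$positions),
               reference = if (rec$is_avg_ref) "average" else "unknown",
               units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a set of microstate topographies
#'
#' Maps are serialized as a channels x K TSV with a header of state names
#' and channel names in the first column.
#'
#' @param maps An [ms_maps()] object.
#' @param path TSV path.
#' @return For the reader, an [ms_maps()]; for the writer, `path` invisibly.
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "ms_maps"))
  m <- t(maps$maps)  # channels x K
  df <- data.frame(channel = colnames(maps$maps), m, check.names = FALSE)
  colnames(df) <- c("channel", rownames(maps$maps))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  ch <- df[[1L]]
  m <- t(as.matrix(df[, -1L]))
  colnames(m) <- ch
  ms_maps(m, state_names = rownames(m))
}

#' Write / read a segmentation
#'
#' Per-sample TSV with columns `sample` (0-based), `time_ms`, `label`
#' (0 = unlabeled), `abs_corr`, `gfp`.
#'
#' @param seg An [ms_segmentation()].
#' @param path TSV path.
#' @return For the reader, an [ms_segmentation()]; for the writer, `path`
#'   invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "ms_segmentation"))
  n <- length(seg$labels)
  df <- data.frame(sample = seq_len(n) - 1L,
                   time_ms = (seq_len(n) - 1L) * 1000 / seg$srate,
                   label = seg$labels,
                   abs_corr = seg$abs_corr,
                   gfp = seg$gfp)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path, K = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE)
  n <- nrow(df)
  srate <- if (n >= 2L) 1000 / (df$time_ms[2L] - df$time_ms[1L]) else 1
  if (is.null(K)) K <- max(df$label)
  ms_segmentation(labels = df$label, abs_corr = df$abs_corr, gfp = df$gfp,
                  srate = srate, K = K)
}

#' Binary 3-D volume
#'
#' A 0/1 voxel grid with its voxel size in mm per axis; the container used
#' by the slice-wise Dice overlap.
#'
#' @param grid 3-D array of 0/1 values.
#' @param voxel_size Numeric length-3, mm per axis.
#' @return An object of class `ms_volume`.
#' @export
ms_volume <- function(grid, voxel_size = c(1, 1, 1)) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3L) stop("grid must be a 3-D array")
  if (!all(grid %in% c(0, 1))) stop("grid values must be 0 or 1")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "ms_volume")
}

#' Write / read a binary volume as NIfTI-1
#'
#' Round-trips a 0/1 grid losslessly, preserving the voxel size. Reading a
#' non-binary volume is an error unless `binarize = TRUE`, in which case
#' values above zero become 1.
#'
#' @param vol An [ms_volume()].
#' @param path `.nii` or `.nii.gz` path.
#' @param binarize Logical; threshold non-binary data at zero on read.
#' @return For the reader, an [ms_volume()]; for the writer, `path`
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ms_volume"))
  img <- RNifti::asNifti(1 * vol$grid)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, binarize = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (!all(arr %in% c(0, 1))) {
    if (!binarize) stop("volume at ", path,
                        " is not binary; pass binarize = TRUE to threshold it")
    arr <- 1 * (arr > 0)
  }
  ms_volume(arr, voxel_size = RNifti::pixdim(img)[seq_len(3)])
}
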