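# File I/O: multichannel volumes as multi-page TIFF with a YAML sidecar,
# sweep sets as delimited text with a YAML sidecar, tables as CSV.
# Roundtrips preserve 8-bit intensities bit-exactly and floats to < 1e-9.

sidecar_path <- function(path) paste0(path, ".yml")

#' Write a multichannel volume to TIFF
#'
#' Pages are written channel-major (all z sections of channel 1, then
#' channel 2, ...) at 8-bit depth; a YAML sidecar (`<path>.yml`) records
#' channel names, dimensions and voxel size so the channel axis can be
#' reconstructed.
#'
#' @param stack named list of 3-d integer arrays `[y, x, z]` in 0..255.
#' @param path output TIFF path.
#' @param voxel_size_um voxel size recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(stack, path, voxel_size_um = c(0.1, 0.1, 0.2)) {
  d <- dim(stack[[1L]])
  for (ch in stack) stopifnot(identical(dim(ch), d))
  pages <- list()
  for (ch in names(stack)) {
    for (z in seq_len(d[3L])) {
      pages[[length(pages) + 1L]] <- stack[[ch]][, , z] / 255
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  meta <- list(channels = as.list(names(stack)),
               dim_yxz = as.list(as.integer(d)),
               voxel_size_um = as.list(as.numeric(voxel_size_um)),
               bit_depth = 8L, page_order = "channel_major")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multichannel volume written by [write_volume()]
#'
#' @param path TIFF path (sidecar `<path>.yml` must exist).
#' @return list with `stack` (named list of integer arrays) and
#'   `voxel_size_um`.
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("volume sidecar not found: %s", sc), call. = FALSE)
  meta <- yaml::read_yaml(sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(unlist(meta$dim_yxz))
  chs <- unlist(meta$channels)
  if (length(pages) != length(chs) * d[3L])
    stop(sprintf("volume file malformed: expected %d pages, found %d",
                 length(chs) * d[3L], length(pages)), call. = FALSE)
  stack <- list()
  k <- 0L
  for (ch in chs) {
    a <- array(0L, dim = d)
    for (z in seq_len(d[3L])) {
      k <- k + 1L
      a[, , z] <- as.integer(round(pages[[k]] * 255))
    }
    stack[[ch]] <- a
  }
  class(stack) <- "channel_stack"
  list(stack = stack, voxel_size_um = as.numeric(unlist(meta$voxel_size_um)))
}

#' Write a sweep set as delimited text with a metadata sidecar
#'
#' The CSV has a `time_s` column followed by one column per trial; the YAML
#' sidecar (`<path>.yml`) carries sampling rate, stimulus times, holding
#' and reversal potentials and filter cutoff. Ground-truth tables, when
#' present, are written next to the data as `<path>.truth.csv`.
#'
#' @param sweeps a `sweep_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweepset <- function(sweeps, path) {
  acq <- sweeps$acquisition
  df <- data.frame(time_s = sweep_times(sweeps), sweeps$current)
  names(df) <- c("time_s", paste0("trial_", seq_len(ncol(sweeps$current))))
  data.table::fwrite(df, path)
  meta <- list(sampling_rate_hz = acq$sampling_rate_hz,
               filter_cutoff_hz = acq$filter_cutoff_hz,
               sweep_duration_s = acq$sweep_duration_s,
               holding_mv = acq$holding_mv, reversal_mv = acq$reversal_mv,
               stimulus_times_s = as.list(acq$stimulus_times_s),
               artifact_blank_ms = acq$artifact_blank_ms)
  yaml::write_yaml(meta, sidecar_path(path))
  if (!is.null(sweeps$truth))
    utils::write.csv(sweeps$truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a sweep set written by [write_sweepset()]
#'
#' @param path CSV path (sidecar `<path>.yml` must exist).
#' @return A `sweep_set`.
#' @export
read_sweepset <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("sweep sidecar not found: %s", sc), call. = FALSE)
  meta <- yaml::read_yaml(sc)
  need <- c("sampling_rate_hz", "sweep_duration_s", "holding_mv")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop(sprintf("sweep sidecar malformed: missing field(s) %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  if (names(df)[1L] != "time_s")
    stop("sweep file malformed: first column must be 'time_s'", call. = FALSE)
  cur <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(cur) <- NULL
  acq <- acquisition_spec(
    sampling_rate_hz = meta$sampling_rate_hz,
    filter_cutoff_hz = meta$filter_cutoff_hz %||% (meta$sampling_rate_hz / 2 - 1),
    sweep_duration_s = meta$sweep_duration_s,
    holding_mv = meta$holding_mv,
    reversal_mv = meta$reversal_mv %||% 0,
    stimulus_times_s = as.numeric(unlist(meta$stimulus_times_s)),
    artifact_blank_ms = meta$artifact_blank_ms %||% 0)
  truth <- NULL
  tp <- paste0(path, ".truth.csv")
  if (file.exists(tp)) truth <- utils::read.csv(tp)
  new_sweep_set(cur, acq, truth = truth)
}
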