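# Plain-text interchange: EMG cycle matrices as CSV with a JSON sidecar
# carrying the cycle geometry and provenance, and marker trajectories as CSV.

#' Write an EMG cycle matrix to CSV (+ JSON sidecar)
#'
#' The CSV has one row per muscle (first column `muscle`, then one column per
#' sample). The sidecar `<path>.json` records the samples-per-cycle, cycle
#' count, per-muscle normalisation constants and any metadata (ground-truth
#' synergy count, seed, ...).
#'
#' @param x an [emg_cycle_matrix].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(x, path) {
  stopifnot(inherits(x, "emg_cycle_matrix"))
  df <- data.frame(muscle = x$labels, x$E, check.names = FALSE)
  colnames(df) <- c("muscle", paste0("s", seq_len(ncol(x$E))))
  write.csv(df, path, row.names = FALSE)
  side <- list(T_cycle = x$T_cycle, k = x$k, labels = x$labels,
               norms = x$norms,
               meta = x$meta[setdiff(names(x$meta), "W_subject")])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an EMG cycle matrix written by [write_emg_csv]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return An [emg_cycle_matrix].
#' @export
read_emg_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  E <- as.matrix(df[, -1L, drop = FALSE])
  emg_cycle_matrix(E, side$T_cycle, side$k, labels = df$muscle,
                   norms = side$norms, meta = as.list(side$meta))
}

#' Write marker trajectories to CSV
#'
#' Frame index, time in seconds, then x/y coordinates (metres, bar at the
#' origin, y up) for each joint marker.
#'
#' @param markers data frame as returned by [simulate_giant_swing].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}

#' Read marker trajectories from CSV
#'
#' @param path CSV path.
#' @return A data frame of marker trajectories.
#' @export
read_markers_csv <- function(path) {
  read.csv(path, check.names = FALSE)
}
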