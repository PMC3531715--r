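#' Multi-channel EMG recording
#'
#' Container for raw (or partially processed) surface EMG: a muscles-by-samples
#' numeric matrix with its sampling rate, channel labels and the sample indices
#' at which each movement cycle starts (for a giant swing, the instants at
#' which the body passes the vertical position under the bar).
#'
#' @param data numeric matrix, muscles in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param labels character vector of muscle names, one per row.
#' @param cycle_events strictly increasing integer sample indices (1-based)
#'   marking cycle starts; consecutive events delimit one cycle, so `m` events
#'   define `m - 1` cycles.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, fs, labels = NULL, cycle_events = integer()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("`labels` must have one entry per muscle row", call. = FALSE)
  cycle_events <- as.integer(cycle_events)
  # the final event may sit at N + 1: it closes the last half-open cycle
  if (length(cycle_events) &&
      (any(diff(cycle_events) <= 0) || min(cycle_events) < 1L ||
       max(cycle_events) > ncol(data) + 1L))
    stop("`cycle_events` must be strictly increasing sample indices within the record",
         call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 cycle_events = cycle_events),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d muscles x %d samples @ %g Hz, %d cycle events\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$cycle_events)))
  invisible(x)
}

#' Normalised cycle matrix of EMG envelopes
#'
#' The matrix `E` consumed by synergy extraction: muscles in rows, `k` cycles
#' of `T` time-normalised samples concatenated in columns, every muscle scaled
#' so that its maximum over all retained cycles equals 1.
#'
#' @param E non-negative numeric matrix, `p` muscles by `k * T` columns.
#' @param T_cycle samples per cycle.
#' @param k number of cycles.
#' @param labels muscle names.
#' @param norms per-muscle amplitude normalisation constants (the envelope
#'   maxima divided out), or `NULL` when unknown.
#' @param meta optional named list of provenance metadata (ground-truth synergy
#'   count, seed, subject id, ...).
#' @return An object of class `emg_cycle_matrix`.
#' @export
emg_cycle_matrix <- function(E, T_cycle, k, labels = NULL, norms = NULL,
                             meta = list()) {
  E <- as.matrix(E)
  if (any(E < 0)) stop("cycle matrix entries must be non-negative", call. = FALSE)
  if (ncol(E) != T_cycle * k)
    stop("column count must equal k * T_cycle", call. = FALSE)
  if (is.null(labels)) labels <- rownames(E)
  if (is.null(labels)) labels <- paste0("M", seq_len(nrow(E)))
  rownames(E) <- labels
  structure(list(E = E, T_cycle = as.integer(T_cycle), k = as.integer(k),
                 labels = labels, norms = norms, meta = meta),
            class = "emg_cycle_matrix")
}

#' @export
print.emg_cycle_matrix <- function(x, ...) {
  cat(sprintf("<emg_cycle_matrix> %d muscles x %d samples (%d cycles of %d)\n",
              nrow(x$E), ncol(x$E), x$k, x$T_cycle))
  invisible(x)
}

# Accept either a bare non-negative matrix or an emg_cycle_matrix.
as_cycle_mat <- function(E) {
  if (inherits(E, "emg_cycle_matrix")) E$E else as.matrix(E)
}

#' Band-pass filter an EMG recording
#'
#' Zero-phase Butterworth band-pass applied channel by channel. The stated
#' `order` is the order of the underlying one-pass design; the forward-backward
#' application doubles the effective roll-off while cancelling phase lag, which
#' matters because timing (lag) is a downstream output of the analysis.
#'
#' @param rec an [emg_recording].
#' @param low,high band edges in Hz (defaults 20 and 450).
#' @param order Butterworth design order (default 2).
#' @return A filtered [emg_recording].
#' @export
bandpass <- function(rec, low = 20, high = 450, order = 2) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < fs/2 = %g Hz", nyq),
         call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  pad_n <- round(3 * rec$fs / low)
  rec$data <- t(apply(rec$data, 1L, function(x) filtfilt_reflect(bf, x, pad_n)))
  rownames(rec$data) <- rec$labels
  rec
}

#' Full-wave rectify an EMG recording
#'
#' @param rec an [emg_recording].
#' @return The recording with every sample replaced by its absolute value.
#' @export
rectify <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  rec$data <- abs(rec$data)
  rec
}

#' Low-pass envelope of a rectified EMG recording
#'
#' Zero-lag (forward-backward) Butterworth low-pass, the classic linear
#' envelope step (default 9 Hz, 2nd order).
#'
#' @param rec an [emg_recording].
#' @param cutoff low-pass cutoff in Hz.
#' @param order Butterworth design order.
#' @return A smoothed [emg_recording].
#' @export
envelope <- function(rec, cutoff = 9, order = 2) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop(sprintf("cutoff must lie in (0, fs/2 = %g) Hz", nyq), call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  pad_n <- round(3 * rec$fs / cutoff)
  rec$data <- t(apply(rec$data, 1L, function(x) filtfilt_reflect(bf, x, pad_n)))
  rownames(rec$data) <- rec$labels
  rec
}

#' Segment an envelope recording into a normalised cycle matrix
#'
#' Each cycle (the half-open interval from one cycle event to the next) is
#' linearly resampled to `T_cycle` points; retained cycles are concatenated and
#' each muscle is divided by its maximum over all retained cycles. With
#' `drop_edges = TRUE` the first and last cycles are discarded (transient
#' cycles at the start and end of a series of linked swings).
#'
#' @param rec an [emg_recording] whose `cycle_events` are populated.
#' @param T_cycle samples per normalised cycle (default 200, i.e. 0.5% of
#'   cycle resolution).
#' @param drop_edges drop the first and last cycle before normalisation.
#' @return An [emg_cycle_matrix].
#' @export
segment_and_normalize <- function(rec, T_cycle = 200, drop_edges = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  T_cycle <- stop_if_not_scalar_count(T_cycle, "T_cycle")
  ev <- rec$cycle_events
  n_cyc <- length(ev) - 1L
  min_needed <- if (drop_edges) 3L else 1L
  if (n_cyc < min_needed)
    stop(sprintf("need at least %d cycles (%d found)", min_needed, n_cyc),
         call. = FALSE)
  keep <- if (drop_edges) 2L:(n_cyc - 1L) else seq_len(n_cyc)
  blocks <- lapply(keep, function(ci) {
    a <- ev[ci]; b <- ev[ci + 1L]
    len <- b - a
    # resample the half-open cycle [a, b) at T_cycle equispaced points
    pos <- a + (seq_len(T_cycle) - 1L) * len / T_cycle
    t(apply(rec$data, 1L, function(x)
      approx(seq_along(x), x, xout = pos, rule = 2)$y))
  })
  E <- do.call(cbind, blocks)
  norms <- apply(E, 1L, max)
  zero <- norms <= 0
  if (any(zero))
    stop(sprintf("muscle(s) with no activity across retained cycles: %s",
                 paste(rec$labels[zero], collapse = ", ")), call. = FALSE)
  E <- sweep(E, 1L, norms, "/")
  emg_cycle_matrix(E, T_cycle, length(keep), labels = rec$labels, norms = norms)
}

#' Run the full envelope preprocessing chain
#'
#' Band-pass, rectify, low-pass envelope, then segment and normalise — the
#' fixed order of the standard synergy-analysis pipeline.
#'
#' @param rec an [emg_recording].
#' @param low,high band-pass edges in Hz.
#' @param env_cutoff envelope low-pass cutoff in Hz.
#' @param order Butterworth design order for both filters.
#' @param T_cycle samples per normalised cycle.
#' @param drop_edges drop first and last cycles.
#' @return An [emg_cycle_matrix].
#' @export
preprocess_emg <- function(rec, low = 20, high = 450, env_cutoff = 9,
                           order = 2, T_cycle = 200, drop_edges = TRUE) {
  rec |>
    bandpass(low = low, high = high, order = order) |>
    rectify() |>
    envelope(cutoff = env_cutoff, order = order) |>
    segment_and_normalize(T_cycle = T_cycle, drop_edges = drop_edges)
}

#' Cycle-averaged waveforms of a cycle matrix
#'
#' Averages the `k` cycles of each muscle (or of each activation coefficient
#' row) into a single `T_cycle`-sample waveform.
#'
#' @param E an [emg_cycle_matrix], or a matrix whose columns are `k` blocks of
#'   `T_cycle` samples (then `T_cycle` and `k` must be given).
#' @param T_cycle,k cycle geometry, taken from `E` when it is an
#'   [emg_cycle_matrix].
#' @return A matrix with the same rows and `T_cycle` columns.
#' @export
cycle_average <- function(E, T_cycle = NULL, k = NULL) {
  if (inherits(E, "emg_cycle_matrix")) {
    T_cycle <- E$T_cycle; k <- E$k; M <- E$E
  } else M <- as.matrix(E)
  stopifnot(!is.null(T_cycle), !is.null(k), ncol(M) == T_cycle * k)
  out <- matrix(0, nrow(M), T_cycle, dimnames = list(rownames(M), NULL))
  for (ci in seq_len(k))
    out <- out + M[, (ci - 1L) * T_cycle + seq_len(T_cycle), drop = FALSE]
  out / k
}
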