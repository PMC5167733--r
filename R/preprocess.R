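#' Continuous sensor recording
#'
#' @param data `[channels x samples]` matrix.
#' @param sample_rate Sampling rate, Hz.
#' @param event_times Stimulus onsets in seconds (already carrying any
#'   stimulus-device onset correction).
#' @param artifact_events Optional named list of event-time vectors
#'   (seconds), e.g. `list(cardiac = ..., ocular = ...)`.
#' @return Object of class `recording`.
#' @export
recording <- function(data, sample_rate, event_times = numeric(0),
                      artifact_events = list()) {
  stopifnot(is.matrix(data), sample_rate > 0)
  dur <- ncol(data) / sample_rate
  if (length(event_times) && (min(event_times) < 0 || max(event_times) > dur))
    stop("event_times must lie within the record duration")
  structure(list(data = data, sample_rate = sample_rate,
                 event_times = as.numeric(event_times),
                 artifact_events = artifact_events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sample_rate, length(x$event_times)))
  invisible(x)
}

# zero-phase 4th-order Butterworth (applied forward-backward)
.filtfilt_rows <- function(data, flt) {
  t(apply(data, 1, function(ch) signal::filtfilt(flt, ch)))
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high-pass followed by
#' low-pass.  Removes DC; passband amplitude is preserved to within 1%.
#'
#' @param rec A [recording()].
#' @param hp High-pass cutoff, Hz.
#' @param lp Low-pass cutoff, Hz; must be below Nyquist.
#' @return Filtered [recording()].
#' @export
bandpass <- function(rec, hp = 0.5, lp = 100) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sample_rate / 2
  if (lp >= nyq || hp >= nyq) stop("filter cutoff must be below Nyquist")
  bh <- signal::butter(4, hp / nyq, type = "high")
  bl <- signal::butter(4, lp / nyq, type = "low")
  out <- .filtfilt_rows(.filtfilt_rows(rec$data, bh), bl)
  recording(out, rec$sample_rate, rec$event_times, rec$artifact_events)
}

#' Epoched trial data
#'
#' @param data `[channels x samples x trials]` array.
#' @param times Peri-stimulus times, ms.
#' @param sample_rate Hz.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sample_rate = 500) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(times))
  structure(list(data = data, times = as.numeric(times),
                 sample_rate = sample_rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d channels x %d samples x %d trials, %g..%g ms\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Downsample, epoch and baseline-correct
#'
#' Anti-alias low-pass filters (when decimating), downsamples to
#' `target_rate`, cuts epochs over the closed peri-stimulus interval
#' `[-50, 300]` ms around each event (176 samples at 500 Hz) and subtracts,
#' per channel and trial, the mean over the half-open baseline window
#' `[-50, 0)` ms.  Events too close to the record edges are dropped with a
#' warning.
#'
#' @param rec A [recording()].
#' @param target_rate Hz; must divide the recording rate.
#' @param epoch_window Closed epoch interval, ms relative to stimulus onset.
#' @param baseline Baseline interval, ms; samples with
#'   `baseline[1] <= t < baseline[2]` are used.
#' @return An [epoch_set()].
#' @export
downsample_epoch_baseline <- function(rec, target_rate = 500,
                                      epoch_window = c(-50, 300),
                                      baseline = c(-50, 0)) {
  stopifnot(inherits(rec, "recording"))
  if (length(rec$event_times) == 0) stop("recording has no events")
  dec <- rec$sample_rate / target_rate
  if (abs(dec - round(dec)) > 1e-9)
    stop("target_rate must divide the recording sample rate")
  dec <- as.integer(round(dec))
  data <- rec$data
  if (dec > 1L) {
    aa <- signal::butter(4, 0.8 * (target_rate / 2) / (rec$sample_rate / 2),
                         type = "low")
    data <- .filtfilt_rows(data, aa)
    data <- data[, seq(1, ncol(data), by = dec), drop = FALSE]
  }
  step_ms <- 1000 / target_rate
  rel <- seq(epoch_window[1], epoch_window[2], by = step_ms)
  n_s <- length(rel)
  bl_idx <- which(rel >= baseline[1] & rel < baseline[2])

  ev_samp <- round(rec$event_times * target_rate) + 1L
  off <- round(rel / step_ms)
  keep <- ev_samp + off[1] >= 1L & ev_samp + off[n_s] <= ncol(data)
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: event too close to record edge")
  ev_samp <- ev_samp[keep]
  n_tr <- length(ev_samp)
  if (n_tr == 0) stop("no usable trials")

  out <- array(0, c(nrow(data), n_s, n_tr))
  for (k in seq_len(n_tr)) {
    ep <- data[, ev_samp[k] + off, drop = FALSE]
    ep <- ep - rowMeans(ep[, bl_idx, drop = FALSE])
    out[, , k] <- ep
  }
  epoch_set(out, rel, target_rate)
}

#' Signal-space projection away from artifact topographies
#'
#' For each artifact class, the leading principal component of the
#' concatenated artifact segments defines a sensor topography `u`; all data
#' are orthogonally projected with `I - u u'`.  Rank is reduced by exactly
#' one per class.
#'
#' @param epochs An [epoch_set()].
#' @param artifact_segments Named list (one entry per artifact class) of
#'   `[channels x samples]` matrices of artifact-dominated data.
#' @return The projected [epoch_set()]; attribute `"projectors"` carries the
#'   removed topographies (`[channels x classes]`).
#' @export
artifact_project <- function(epochs, artifact_segments) {
  stopifnot(inherits(epochs, "epoch_set"), length(artifact_segments) >= 1)
  n_ch <- dim(epochs$data)[1]
  P <- diag(n_ch)
  topos <- matrix(0, n_ch, length(artifact_segments))
  colnames(topos) <- names(artifact_segments)
  for (k in seq_along(artifact_segments)) {
    seg <- artifact_segments[[k]]
    stopifnot(is.matrix(seg), nrow(seg) == n_ch)
    if (sum(seg^2) == 0) stop("degenerate (zero-variance) artifact segment")
    u <- svd(seg, nu = 1, nv = 0)$u[, 1]
    topos[, k] <- u
    P <- (diag(n_ch) - tcrossprod(u)) %*% P
  }
  dat <- epochs$data
  for (tr in seq_len(dim(dat)[3])) dat[, , tr] <- P %*% dat[, , tr]
  out <- epoch_set(dat, epochs$times, epochs$sample_rate)
  attr(out, "projectors") <- topos
  out
}

#' Extract artifact-locked segments from a recording
#'
#' Cuts `[channels x samples]` windows around the labeled artifact events
#' and returns their event-locked average per class, for use with
#' [artifact_project()].  Averaging across events cancels brain activity
#' that is not phase-locked to the artifact, so the leading principal
#' component of the averaged segment isolates the artifact topography.
#' Events whose window would cross a record edge are skipped.
#'
#' @param rec A [recording()] with `artifact_events`.
#' @param window Segment window around each event, seconds.
#' @return Named list of `[channels x samples]` averaged segment matrices.
#' @export
extract_artifact_segments <- function(rec, window = c(-0.05, 0.15)) {
  stopifnot(inherits(rec, "recording"))
  lapply(rec$artifact_events, function(ev) {
    idx_off <- seq(round(window[1] * rec$sample_rate),
                   round(window[2] * rec$sample_rate))
    acc <- matrix(0, nrow(rec$data), length(idx_off))
    used <- 0L
    for (t0 in ev) {
      i <- round(t0 * rec$sample_rate) + 1L + idx_off
      if (i[1] >= 1 && i[length(i)] <= ncol(rec$data)) {
        acc <- acc + rec$data[, i, drop = FALSE]
        used <- used + 1L
      }
    }
    if (used == 0L) stop("no usable artifact segments in the record")
    acc / used
  })
}

#' Trial-average event-related field
#'
#' @param epochs An [epoch_set()] with at least one trial.
#' @return Object of class `erf`: `times` (ms), `data`
#'   (`[channels x samples]`), `n_trials_averaged`.
#' @export
average_erf <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[3]
  if (n_tr < 1) stop("empty epoch set")
  structure(list(times = epochs$times,
                 data = apply(epochs$data, c(1, 2), mean),
                 n_trials_averaged = n_tr),
            class = "erf")
}

#' @export
print.erf <- function(x, ...) {
  cat(sprintf("<erf> %d channels x %d samples, average of %d trials\n",
              nrow(x$data), ncol(x$data), x$n_trials_averaged))
  invisible(x)
}
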