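#' Ground truth for a synthetic group study
#'
#' Defines the generating conditions of a multi-subject synthetic MEG-like
#' dataset: the routing architecture, the group-mean network model, the
#' between-subject variability of gains and input amplitudes (log scale),
#' the gain-matrix seed and the single-trial signal-to-noise ratio (ratio of
#' clean ERF RMS to single-trial sensor-noise RMS).
#'
#' @param architecture One of `"A"`, `"B"`, `"C"`, `"D"` (or the
#'   single-input `"serial"` / `"parallel"`).
#' @param snr Single-trial SNR (> 0); default 5.
#' @param subject_sd Between-subject SD of log gains/amplitudes; default 0.2.
#' @param gain_seed Seed of the synthetic gain matrix.
#' @param n_channels Sensor count (102 whole-scalp map by default; 306
#'   optional).
#' @param components,params Passed to [build_model()].
#' @param input_gains Optional named multipliers on the per-target input
#'   gains of the group-mean model (e.g. `c(SIc = 2, SIIc = 1)` makes the
#'   thalamic drive to SI twice as strong as to SII).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(architecture = "C", snr = 5, subject_sd = 0.2,
                         gain_seed = 1L, n_channels = 102,
                         components = default_components(),
                         params = node_dynamics_params(),
                         input_gains = NULL) {
  if (snr <= 0) stop("snr must be > 0")
  model <- build_model(architecture, params = params, components = components)
  if (!is.null(input_gains)) {
    for (j in seq_along(model$inputs)) {
      g <- model$inputs[[j]]$gains
      hit <- intersect(names(g), names(input_gains))
      g[hit] <- g[hit] * input_gains[hit]
      model$inputs[[j]]$gains <- g
    }
  }
  structure(list(architecture = architecture, model = model, snr = snr,
                 subject_sd = subject_sd, gain_seed = gain_seed,
                 n_channels = n_channels),
            class = "ground_truth")
}

#' Sample one subject from the group distribution
#'
#' Log-normal perturbation of the extrinsic connection gains and input
#' amplitudes around the group means, with the stated between-subject SD.
#' Deterministic given the seed.
#'
#' @param gt A [ground_truth()].
#' @param seed Integer seed.
#' @param subject_id Identifier carried through.
#' @param n_trials Trials per subject (default 154).
#' @param isi_range Inter-stimulus interval range, seconds (default
#'   2 to 3.8 s).
#' @return Object of class `subject_spec`: `model` (the subject's sampled
#'   [network_model()]), trial/noise/artifact settings and the seed.
#' @export
sample_subject <- function(gt, seed, subject_id = paste0("S", seed),
                           n_trials = 154, isi_range = c(2, 3.8)) {
  stopifnot(inherits(gt, "ground_truth"), n_trials >= 1,
            all(isi_range > 0), all(isi_range <= 10))
  model <- gt$model
  model <- .with_seed(seed, {
    m <- model
    for (slot in c("forward", "backward")) {
      nz <- which(m[[slot]] != 0)
      m[[slot]][nz] <- m[[slot]][nz] * exp(rnorm(length(nz), 0, gt$subject_sd))
    }
    for (j in seq_along(m$inputs)) {
      g <- m$inputs[[j]]$gains
      m$inputs[[j]]$gains <- g * exp(rnorm(length(g), 0, gt$subject_sd))
    }
    m
  })
  structure(list(subject_id = subject_id, model = model,
                 n_trials = n_trials, isi_range = isi_range,
                 noise = list(ar = 0.95),
                 artifacts = list(cardiac_period = 1.0, blink_rate = 0.2),
                 snr = gt$snr, seed = seed),
            class = "subject_spec")
}

# clean projected epoch [channels x samples] and its post-onset RMS
.clean_epoch <- function(spec, gain, times) {
  src <- simulate_sources(spec$model, times)
  y <- project_to_sensors(src, gain)
  rms <- sqrt(mean(y[, times >= 0]^2))
  list(y = y, rms = rms)
}

# AR(1) noise matrix [channels x samples] with stationary SD `sd`;
# the first sample is drawn from the stationary distribution, so the
# process is stationary from the first column
.ar1_noise <- function(n_ch, n_s, phi, sd) {
  innov_sd <- sd * sqrt(1 - phi^2)
  out <- matrix(0, n_ch, n_s)
  out[, 1] <- rnorm(n_ch, 0, sd)
  for (t in 2:n_s)
    out[, t] <- phi * out[, t - 1] + rnorm(n_ch, 0, innov_sd)
  out
}

#' Synthesize a continuous sensor recording for one subject
#'
#' Builds a 2 kHz continuous record: the subject's deterministic source
#' response is simulated once, projected to sensors and inserted at each
#' stimulus onset (inter-stimulus intervals uniform over `isi_range`);
#' additive AR(1) sensor noise (coefficient 0.95 at 2 kHz, IID across
#' channels) is scaled so that clean-ERF RMS / noise RMS equals the
#' requested SNR.  Event markers carry the stimulus-device onset correction
#' by construction (time zero of the inserted response is the corrected
#' onset).  Optional cardiac (~1 s period) and ocular (blink) artifacts are
#' injected as fixed topographies with scheduled waveforms and recorded in
#' `artifact_events`.  Deterministic given the spec's seed.
#'
#' @param spec A [sample_subject()] result.
#' @param gain A `gain_matrix` over the same channel set.
#' @param sample_rate Hz (default 2000).
#' @param artifacts Logical; inject cardiac/ocular artifacts (default
#'   FALSE).
#' @param artifact_snr Amplitude of each artifact topography relative to the
#'   clean ERF RMS (used when `artifacts = TRUE`).
#' @return A [recording()].
#' @export
synthesize_recording <- function(spec, gain, sample_rate = 2000,
                                 artifacts = FALSE, artifact_snr = 1) {
  stopifnot(inherits(spec, "subject_spec"))
  G <- if (inherits(gain, "gain_matrix")) gain$values else gain
  n_ch <- nrow(G)
  step_ms <- 1000 / sample_rate
  # simulate well past the epoch so the inserted response decays naturally
  ep_times <- seq(-100, 650, by = step_ms)
  ce <- .clean_epoch(spec, gain, ep_times)
  ce$rms <- sqrt(mean(ce$y[, ep_times >= 0 & ep_times <= 300]^2))
  noise_sd <- ce$rms / spec$snr

  .with_seed(spec$seed + 1L, {
    isi <- runif(spec$n_trials, spec$isi_range[1], spec$isi_range[2])
    onsets <- 1 + cumsum(isi) - isi[1]          # first event at 1 s
    onsets <- round(onsets * 500) / 500         # align to the 500 Hz epoch grid
    dur_s <- onsets[spec$n_trials] + 1
    n_s <- ceiling(dur_s * sample_rate)
    data <- .ar1_noise(n_ch, n_s, spec$noise$ar, noise_sd)
    off <- round(ep_times / step_ms)
    for (t0 in onsets) {
      i0 <- round(t0 * sample_rate) + 1L
      cols <- i0 + off
      data[, cols] <- data[, cols] + ce$y
    }
    art_ev <- list()
    if (artifacts) {
      amp <- artifact_snr * ce$rms
      # cardiac: sharp biphasic pulse, quasi-periodic
      topo_c <- rnorm(n_ch); topo_c <- topo_c / sqrt(sum(topo_c^2))
      beats <- seq(0.5, dur_s - 0.5, by = spec$artifacts$cardiac_period) +
        rnorm(length(seq(0.5, dur_s - 0.5, by = spec$artifacts$cardiac_period)),
              0, 0.02)
      wt <- seq(-0.05, 0.1, by = 1 / sample_rate)
      wave_c <- sin(2 * pi * wt / 0.1) * exp(-((wt - 0.01) / 0.03)^2)
      for (tb in beats) {
        i <- round(tb * sample_rate) + 1L + round(wt * sample_rate)
        ok <- i >= 1 & i <= n_s
        data[, i[ok]] <- data[, i[ok]] +
          amp * 3 * tcrossprod(topo_c, wave_c[ok])
      }
      # ocular: slow blink bumps, Poisson schedule
      topo_o <- rnorm(n_ch); topo_o <- topo_o / sqrt(sum(topo_o^2))
      n_bl <- stats::rpois(1, spec$artifacts$blink_rate * dur_s)
      blinks <- sort(runif(n_bl, 0.5, dur_s - 0.5))
      wt2 <- seq(-0.15, 0.15, by = 1 / sample_rate)
      wave_o <- exp(-(wt2 / 0.06)^2)
      for (tb in blinks) {
        i <- round(tb * sample_rate) + 1L + round(wt2 * sample_rate)
        ok <- i >= 1 & i <= n_s
        data[, i[ok]] <- data[, i[ok]] +
          amp * 5 * tcrossprod(topo_o, wave_o[ok])
      }
      art_ev <- list(cardiac = beats[beats > 0 & beats < dur_s],
                     ocular = blinks)
    }
    recording(data, sample_rate, event_times = onsets,
              artifact_events = art_ev)
  })
}

#' Synthesize epoched data directly (fast path)
#'
#' Generates the epoch set a clean preprocessing run would produce, without
#' materializing the continuous 2 kHz record: the subject's deterministic
#' response on the 500 Hz epoch grid plus per-trial AR(1) noise (the 2 kHz
#' coefficient mapped to the epoch rate as `phi^(2000/rate)`), baseline
#' corrected over `[-50, 0)` ms.  Used by the large recovery studies.
#'
#' @param spec A [sample_subject()] result.
#' @param gain A `gain_matrix`.
#' @param target_rate Hz (default 500).
#' @return An [epoch_set()]; attribute `"noise_sd"` records the stationary
#'   single-trial noise SD.
#' @export
synthesize_epochs <- function(spec, gain, target_rate = 500) {
  stopifnot(inherits(spec, "subject_spec"))
  step_ms <- 1000 / target_rate
  times <- seq(-50, 300, by = step_ms)
  ce <- .clean_epoch(spec, gain, times)
  noise_sd <- ce$rms / spec$snr
  phi <- spec$noise$ar^(2000 / target_rate)
  n_ch <- nrow(ce$y); n_s <- length(times)
  bl <- which(times >= -50 & times < 0)
  .with_seed(spec$seed + 1L, {
    # all trials' noise in one recursive filter pass (columns = channel x trial)
    noise <- .ar1_noise(n_ch * spec$n_trials, n_s, phi, noise_sd)
    dat <- array(0, c(n_ch, n_s, spec$n_trials))
    for (tr in seq_len(spec$n_trials)) {
      ep <- ce$y + noise[(tr - 1L) * n_ch + seq_len(n_ch), , drop = FALSE]
      dat[, , tr] <- ep - rowMeans(ep[, bl, drop = FALSE])
    }
    out <- epoch_set(dat, times, target_rate)
    attr(out, "noise_sd") <- noise_sd
    out
  })
}

#' Synthesize a whole group
#'
#' Draws independent per-subject seeds from the master seed, samples each
#' subject from the group distribution and synthesizes their data.
#' Bit-reproducible given the master seed.
#'
#' @param gt A [ground_truth()].
#' @param n_subjects Group size (default 17).
#' @param seed Master seed.
#' @param gain Optional `gain_matrix`; defaults to [synthetic_gain()] with
#'   the ground truth's seed and channel count.
#' @param mode `"epochs"` (fast path, default) or `"recording"`
#'   (continuous 2 kHz records).
#' @param n_trials,isi_range Per-subject trial settings.
#' @param ... Passed on to [synthesize_recording()] (e.g. `artifacts`).
#' @return Object of class `synthetic_group`: `subjects` (list of
#'   `subject_spec`), `data` (list of [epoch_set()] or [recording()]),
#'   `gain`, `gt`, `seed`.
#' @export
synthesize_group <- function(gt, n_subjects = 17, seed = 1L, gain = NULL,
                             mode = c("epochs", "recording"),
                             n_trials = 154, isi_range = c(2, 3.8), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ground_truth"), n_subjects >= 2)
  if (is.null(gain))
    gain <- synthetic_gain(sensor_layout(gt$n_channels), seed = gt$gain_seed)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i)
    sample_subject(gt, seeds[i], subject_id = paste0("S", i),
                   n_trials = n_trials, isi_range = isi_range))
  data <- lapply(subjects, function(sp)
    switch(mode,
           epochs = synthesize_epochs(sp, gain),
           recording = synthesize_recording(sp, gain, ...)))
  structure(list(subjects = subjects, data = data, gain = gain, gt = gt,
                 seed = seed, mode = mode),
            class = "synthetic_group")
}

#' Trial-averaged ERFs of a synthetic group
#'
#' @param group A [synthesize_group()] result in `"epochs"` mode.
#' @return List of `erf` objects.
#' @export
group_erfs <- function(group) {
  stopifnot(inherits(group, "synthetic_group"), group$mode == "epochs")
  lapply(group$data, average_erf)
}

#' @export
print.synthetic_group <- function(x, ...) {
  cat(sprintf("<synthetic_group> architecture %s, %d subjects, SNR %g (%s)\n",
              x$gt$architecture, length(x$subjects), x$gt$snr, x$mode))
  invisible(x)
}
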