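# Default pseudo-orthogonal lead projection weights. Normalized so the
# vector magnitude of the synthesized leads equals the model waveform, which
# keeps the T-amplitude parameter on the measurement scale.
default_lead_weights <- function(n_leads = 3) {
  w <- switch(as.character(n_leads),
    "1" = 1,
    "2" = c(0.85, 0.527),
    "3" = c(0.80, 0.50, 0.332),
    {
      raw <- seq(1, 0.4, length.out = n_leads)
      raw / sqrt(sum(raw^2))
    }
  )
  w / sqrt(sum(w^2))
}

# R-peak offset (ms after QRS onset) of the QRS shape.
truth_r_offset_ms <- function(params) {
  stats::optimize(function(t) -qrs_shape(t, params$qrs_duration_ms),
                  interval = c(0, params$qrs_duration_ms))$minimum
}

#' Synthesize a single beat with ground-truth fiducials
#'
#' @param params A [beat_params()] object.
#' @param fs_hz Sampling rate (`>= 250` Hz).
#' @param pre_ms Baseline padding before QRS onset, ms.
#' @param post_ms Padding after the ground-truth T end, ms.
#' @param n_leads Number of leads to emit.
#' @return A list with `samples` (matrix samples x leads, microvolts),
#'   `fs_hz`, and `truth` (one-row tibble of fiducial times in ms relative
#'   to the waveform start).
#' @export
synthesize_beat <- function(params, fs_hz = 500, pre_ms = 200, post_ms = 200,
                            n_leads = 3) {
  stopifnot(inherits(params, "beat_params"))
  if (fs_hz < 250) stop("sampling rate must be at least 250 Hz")
  total_ms <- pre_ms + params$qt_ms + post_ms
  t_ms <- seq(0, total_ms, by = 1000 / fs_hz)
  shape <- beat_waveform(t_ms - pre_ms, params)
  w <- default_lead_weights(n_leads)
  samples <- outer(shape, w)
  truth <- tibble::tibble(
    qrs_onset_ms = pre_ms,
    qrs_offset_ms = pre_ms + params$qrs_duration_ms,
    r_ms = pre_ms + truth_r_offset_ms(params),
    t_peak_ms = pre_ms + params$qrs_duration_ms + params$j_to_tpeak_ms,
    t_end_ms = pre_ms + params$qt_ms
  )
  list(samples = samples, fs_hz = fs_hz, truth = truth)
}

# Band-limited noise: white Gaussian noise smoothed by a short moving
# average and rescaled to the requested RMS.
band_limited_noise <- function(n, fs_hz, rms_uv) {
  if (rms_uv == 0) return(numeric(n))
  x <- moving_avg(stats::rnorm(n), max(3, round(0.008 * fs_hz)))
  x / stats::sd(x) * rms_uv
}

#' Synthesize a 10-second multi-lead recording
#'
#' Concatenates beats with jittered RR intervals on a zero baseline, adds
#' band-limited noise, and quantizes the amplitude at the acquisition
#' resolution. Identical seeds give bit-identical output.
#'
#' @param params A [beat_params()] object.
#' @param duration_s Recording duration, seconds (`>= 2 * rr_s`).
#' @param fs_hz Sampling rate, Hz.
#' @param rr_variability Fractional standard deviation of the beat-to-beat
#'   RR jitter.
#' @param noise_uv_rms Additive noise RMS, microvolts (`>= 0`).
#' @param quantum_uv Amplitude quantization step, microvolts.
#' @param n_leads Number of leads.
#' @param metadata Metadata list stored on the recording.
#' @param seed Integer seed; the recording is a pure function of
#'   `(params, arguments, seed)`.
#' @return An [ecg_recording()] with per-beat `truth` annotations
#'   (times in seconds).
#' @export
synthesize_recording <- function(params, duration_s = 10, fs_hz = 500,
                                 rr_variability = 0.02, noise_uv_rms = 12,
                                 quantum_uv = 2.5, n_leads = 3,
                                 metadata = list(), seed = 1) {
  stopifnot(inherits(params, "beat_params"))
  if (noise_uv_rms < 0) stop("noise_uv_rms must be nonnegative")
  if (duration_s < 2 * params$rr_s) stop("duration must cover at least two beats")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n <- round(duration_s * fs_hz)
  shape_sum <- numeric(n)
  # beat onset times (s): first beat starts shortly after t = 0
  onsets <- numeric(0)
  t0 <- 0.05
  while (t0 < duration_s) {
    onsets <- c(onsets, t0)
    t0 <- t0 + params$rr_s * (1 + rr_variability * stats::rnorm(1))
  }
  beat_ms <- seq(0, params$qt_ms + 120, by = 1000 / fs_hz)
  beat_y <- beat_waveform(beat_ms, params)
  r_off_s <- truth_r_offset_ms(params) / 1000
  truth <- vector("list", length(onsets))
  for (b in seq_along(onsets)) {
    i0 <- round(onsets[b] * fs_hz) + 1
    idx <- i0:min(n, i0 + length(beat_y) - 1)
    shape_sum[idx] <- shape_sum[idx] + beat_y[seq_along(idx)]
    truth[[b]] <- tibble::tibble(
      beat = b,
      qrs_onset_s = (i0 - 1) / fs_hz,
      qrs_offset_s = (i0 - 1) / fs_hz + params$qrs_duration_ms / 1000,
      r_s = (i0 - 1) / fs_hz + r_off_s,
      t_peak_s = (i0 - 1) / fs_hz +
        (params$qrs_duration_ms + params$j_to_tpeak_ms) / 1000,
      t_end_s = (i0 - 1) / fs_hz + params$qt_ms / 1000
    )
  }
  w <- default_lead_weights(n_leads)
  samples <- outer(shape_sum, w)
  if (noise_uv_rms > 0) {
    for (k in seq_len(n_leads)) {
      samples[, k] <- samples[, k] + band_limited_noise(n, fs_hz, noise_uv_rms)
    }
  }
  samples <- round(samples / quantum_uv) * quantum_uv
  ecg_recording(samples, fs_hz, metadata = metadata,
                truth = dplyr::bind_rows(truth))
}

# Save/restore .Random.seed so synthesis does not disturb the caller's RNG
# stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
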