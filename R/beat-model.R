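#' Beat-shape parameters for the synthetic ECG generator
#'
#' A single ventricular beat is modelled as a compact-support biphasic QRS
#' complex followed by a T wave built from two half-bell limbs: the ascending
#' limb is Gaussian with width `sigma_asc_ms`; the descending limb is a
#' mixture of a Gaussian of width `sigma_desc_ms` and a broad "shoulder"
#' Gaussian (width `shoulder_ratio * sigma_desc_ms`) weighted by
#' `t_tail_weight`. The shoulder weight gives independent control of T-wave
#' flatness and of the tangent-method T-end without moving the peak.
#'
#' The QT interval is not free: it is derived as
#' `qrs_duration_ms + j_to_tpeak_ms + tangent T-end of the descending limb`,
#' so the generator's ground-truth fiducials are internally consistent with
#' the tangent measurement convention used by the delineator.
#'
#' @param qrs_duration_ms QRS duration (onset to J point), ms.
#' @param j_to_tpeak_ms J point to T-wave peak, ms.
#' @param sigma_asc_ms Width of the ascending T limb, ms.
#' @param sigma_desc_ms Width of the (narrow component of the) descending
#'   T limb, ms.
#' @param t_amplitude_uv T-wave peak amplitude on the vector-magnitude lead,
#'   microvolts.
#' @param t_tail_weight Mixing weight in `[0, 1)` of the broad shoulder
#'   component of the descending limb (dimensionless).
#' @param rr_s RR interval, seconds.
#' @param r_amplitude_uv R-wave amplitude on the vector-magnitude lead,
#'   microvolts.
#' @param shoulder_ratio Width ratio of the shoulder component to
#'   `sigma_desc_ms`.
#' @return An object of class `beat_params` (a named list) with the derived
#'   `qt_ms` field.
#' @export
beat_params <- function(qrs_duration_ms = 87,
                        j_to_tpeak_ms = 226.5,
                        sigma_asc_ms = 59.3,
                        sigma_desc_ms = 36,
                        t_amplitude_uv = 569,
                        t_tail_weight = 0.1,
                        rr_s = 0.99,
                        r_amplitude_uv = 1100,
                        shoulder_ratio = 5) {
  stopifnot(
    qrs_duration_ms > 0, j_to_tpeak_ms > 0,
    sigma_asc_ms > 0, sigma_desc_ms > 0,
    t_amplitude_uv > 0, t_tail_weight >= 0, t_tail_weight < 1,
    rr_s > 0, shoulder_ratio > 1
  )
  p <- list(
    qrs_duration_ms = qrs_duration_ms,
    j_to_tpeak_ms = j_to_tpeak_ms,
    sigma_asc_ms = sigma_asc_ms,
    sigma_desc_ms = sigma_desc_ms,
    t_amplitude_uv = t_amplitude_uv,
    t_tail_weight = t_tail_weight,
    rr_s = rr_s,
    r_amplitude_uv = r_amplitude_uv,
    shoulder_ratio = shoulder_ratio
  )
  p$tpeak_to_tend_ms <- tangent_tend_ms(sigma_desc_ms, t_tail_weight, shoulder_ratio)
  p$qt_ms <- qrs_duration_ms + j_to_tpeak_ms + p$tpeak_to_tend_ms
  if (p$qt_ms >= 1000 * rr_s) {
    stop("inadmissible beat parameters: QT (", round(p$qt_ms), " ms) exceeds the RR interval")
  }
  structure(p, class = "beat_params")
}

# Descending T limb (peak-normalized), u >= 0 ms past the peak.
t_limb_desc <- function(u, sigma, w, k = 3) {
  (1 - w) * exp(-u^2 / (2 * sigma^2)) + w * exp(-u^2 / (2 * (k * sigma)^2))
}

t_limb_desc_deriv <- function(u, sigma, w, k = 3) {
  -(1 - w) * u / sigma^2 * exp(-u^2 / (2 * sigma^2)) -
    w * u / (k * sigma)^2 * exp(-u^2 / (2 * (k * sigma)^2))
}

# Tangent-method T-end of the descending limb: the steepest descending
# tangent is extended to the isoelectric baseline (0 for the peak-normalized
# limb). Returns ms past the T peak. Closed-form geometry evaluated by
# one-dimensional minimization of the analytic derivative.
tangent_tend_ms <- function(sigma_desc, tail_weight, shoulder_ratio = 5) {
  # the derivative can have two local minima (core and shoulder); locate the
  # global one on a grid, then refine locally
  grid <- seq(1e-3, 4 * shoulder_ratio * sigma_desc, length.out = 200)
  dg <- t_limb_desc_deriv(grid, sigma_desc, tail_weight, shoulder_ratio)
  i <- which.min(dg)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(
    t_limb_desc_deriv, interval = c(lo, hi),
    sigma = sigma_desc, w = tail_weight, k = shoulder_ratio
  )
  tstar <- opt$minimum
  slope <- opt$objective
  tstar + t_limb_desc(tstar, sigma_desc, tail_weight, shoulder_ratio) / abs(slope)
}

# Crossing (ms past the peak) of `level` x peak on the descending limb.
desc_level_cross_ms <- function(sigma_desc, tail_weight, level, shoulder_ratio = 5) {
  stopifnot(level > 0, level < 1)
  upper <- shoulder_ratio * sigma_desc * sqrt(2 * log(1 / level)) + sigma_desc
  stats::uniroot(
    function(u) t_limb_desc(u, sigma_desc, tail_weight, shoulder_ratio) - level,
    lower = 1e-9, upper = upper, tol = 1e-8
  )$root
}

# Crossing (ms before the peak) of `level` x peak on the pure-Gaussian
# ascending limb: closed form.
asc_level_cross_ms <- function(sigma_asc, level) {
  stopifnot(level > 0, level < 1)
  sigma_asc * sqrt(2 * log(1 / level))
}

# Peak-normalized T wave as a function of u = t - t_peak (ms); ascending
# limb is pure Gaussian, descending limb carries the shoulder mixture.
t_wave_shape <- function(u, params) {
  out <- numeric(length(u))
  asc <- u <= 0
  out[asc] <- exp(-u[asc]^2 / (2 * params$sigma_asc_ms^2))
  out[!asc] <- t_limb_desc(u[!asc], params$sigma_desc_ms, params$t_tail_weight,
                           params$shoulder_ratio)
  out
}

# Compact-support QRS shape on t in [0, D] ms (0 elsewhere), peak-normalized
# to the R amplitude. Sum of three squared-sine lobes (Q, R, S); value and
# first derivative vanish at both support ends.
qrs_shape <- function(t, qrs_duration_ms) {
  D <- qrs_duration_ms
  lobe <- function(t, t0, width) {
    y <- numeric(length(t))
    inside <- t >= t0 & t <= t0 + width
    y[inside] <- sin(pi * (t[inside] - t0) / width)^2
    y
  }
  -0.15 * lobe(t, 0, 0.30 * D) +
    1.00 * lobe(t, 0.12 * D, 0.50 * D) -
    0.22 * lobe(t, 0.65 * D, 0.35 * D)
}

# Clean single-beat waveform on the vector-magnitude scale, sampled at
# `times_ms` relative to QRS onset.
beat_waveform <- function(times_ms, params) {
  params$r_amplitude_uv * qrs_shape(times_ms, params$qrs_duration_ms) +
    params$t_amplitude_uv *
      t_wave_shape(times_ms - params$qrs_duration_ms - params$j_to_tpeak_ms, params)
}

#' Ground-truth biomarkers implied by a set of beat parameters
#'
#' Evaluates every biomarker the measurement pipeline reports directly from
#' the analytic beat model, using the same measurement conventions as the
#' delineation/morphology stages (tangent T-end, level-crossing ERD/LRD,
#' kurtosis flatness, mirror-difference asymmetry). Used as the oracle for
#' delineation accuracy and as the target function for calibration.
#'
#' @param params A [beat_params()] object.
#' @param erd_level Amplitude fraction for the ERD/LRD crossings.
#' @param seg_level Amplitude fraction defining the T-onset surrogate of the
#'   morphology segment.
#' @return A one-row tibble of truth biomarkers (uncorrected scale).
#' @export
truth_biomarkers <- function(params, erd_level = 0.70, seg_level = 0.05) {
  tpte <- params$tpeak_to_tend_ms
  u_on <- asc_level_cross_ms(params$sigma_asc_ms, seg_level)
  u <- seq(-u_on, tpte, by = 0.25)
  y <- t_wave_shape(u, params)
  tibble::tibble(
    rr_s = params$rr_s,
    qt_ms = params$qt_ms,
    jtpeak_ms = params$j_to_tpeak_ms,
    tpeaktend_ms = tpte,
    flatness = moment_flatness(u, y),
    asymmetry = mirror_asymmetry(u, y, peak_index = which.max(y)),
    erd_ms = asc_level_cross_ms(params$sigma_asc_ms, erd_level),
    lrd_ms = desc_level_cross_ms(params$sigma_desc_ms, params$t_tail_weight,
                                 erd_level, params$shoulder_ratio),
    amplitude_uv = params$t_amplitude_uv
  )
}
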