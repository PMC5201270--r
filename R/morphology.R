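#' @importFrom rlang .data
NULL

# --- shared numeric primitives -------------------------------------------

# Kurtosis-based flatness of a rectified amplitude profile treated as a
# density over time: F = 1 - kappa^(-1/2), kappa = mu4 / mu2^2. A Gaussian
# profile gives 1 - 3^(-1/2) ~ 0.4226; heavier shoulders raise F.
moment_flatness <- function(t, y) {
  y <- abs(y)
  a <- sum(y)
  if (a <= 0) stop("zero-area T-wave segment")
  w <- y / a
  mu <- sum(w * t)
  m2 <- sum(w * (t - mu)^2)
  m4 <- sum(w * (t - mu)^4)
  if (m2 <= 0) stop("degenerate (zero-width) T-wave segment")
  1 - (m4 / m2^2)^(-1 / 2)
}

# Mirror-difference asymmetry about the peak of a peak-normalized rectified
# wave: sum |w(p+u) - w(p-u)| / sum (w(p+u) + w(p-u)) over the symmetric
# overlap. Zero iff mirror-symmetric; invariant to time reversal.
mirror_asymmetry <- function(t, y, peak_index) {
  y <- abs(y)
  n <- length(y)
  if (peak_index <= 1 || peak_index >= n) {
    stop("T peak lies on the segment boundary; asymmetry undefined")
  }
  y <- y / y[peak_index]
  m <- min(peak_index - 1, n - peak_index)
  right <- y[peak_index + seq_len(m)]
  left <- y[peak_index - seq_len(m)]
  sum(abs(right - left)) / sum(right + left)
}

# Linear-interpolation crossing of `level` on a sampled limb. `t`, `y` run
# away from the peak; returns the first time at which y falls through level.
first_down_cross <- function(t, y, level) {
  below <- which(y < level)
  if (length(below) == 0 || below[1] == 1) {
    stop("no level crossing found on the T-wave limb")
  }
  i <- below[1]
  t[i - 1] + (y[i - 1] - level) / (y[i - 1] - y[i]) * (t[i] - t[i - 1])
}

# --- segment construction -------------------------------------------------

#' Extract the T-wave segment of a delineated median beat
#'
#' The segment runs from a T-onset surrogate (the last pre-peak crossing of
#' `seg_level` x peak amplitude on the vector-magnitude lead) to the T end.
#'
#' @param beat A `median_beat` object (see [build_median_beat()]).
#' @param fid A one-row fiducial tibble (see [delineate_beat()]).
#' @param seg_level Amplitude fraction defining the T-onset surrogate.
#' @return A list of class `t_segment` with fields `t_ms`, `y_uv`,
#'   `peak_index`, `fs_hz`.
#' @export
t_wave_segment <- function(beat, fid, seg_level = 0.05) {
  vm <- vector_magnitude(beat$beat)
  t_ms <- (seq_along(vm) - 1) / beat$fs_hz * 1000
  peak_i <- which.min(abs(t_ms - fid$t_peak_ms))
  end_i <- which.min(abs(t_ms - fid$t_end_ms))
  peak_amp <- vm[peak_i]
  if (peak_amp <= 0) stop("nonpositive T-wave peak amplitude")
  j_i <- which.min(abs(t_ms - fid$qrs_offset_ms))
  pre <- vm[j_i:peak_i]
  below <- which(pre < seg_level * peak_amp)
  start_i <- if (length(below)) j_i + max(below) - 1 else j_i
  idx <- start_i:end_i
  seg <- list(
    t_ms = t_ms[idx], y_uv = vm[idx],
    peak_index = peak_i - start_i + 1, fs_hz = beat$fs_hz
  )
  if (seg$peak_index <= 1 || seg$peak_index >= length(idx)) {
    stop("T peak lies on the segment boundary")
  }
  class(seg) <- "t_segment"
  seg
}

# --- biomarker operations -------------------------------------------------

#' T-wave flatness
#'
#' Treats the rectified, area-normalized segment as a density over time and
#' returns `1 - kurtosis^(-1/2)` (dimensionless, in `[0, 1)`).
#'
#' @param seg A `t_segment` (or any list with `t_ms` and `y_uv`).
#' @return Flatness (dimensionless).
#' @export
t_flatness <- function(seg) {
  moment_flatness(seg$t_ms, seg$y_uv)
}

#' T-wave asymmetry
#'
#' Mirror-difference asymmetry of the peak-aligned, peak-normalized wave:
#' 0 for a wave mirror-symmetric about its peak, increasing with limb
#' imbalance; invariant to time reversal and amplitude scaling.
#'
#' @param seg A `t_segment`.
#' @return Asymmetry (dimensionless, `>= 0`).
#' @export
t_asymmetry <- function(seg) {
  mirror_asymmetry(seg$t_ms, seg$y_uv, seg$peak_index)
}

#' Early and late repolarization durations (ERD/LRD)
#'
#' Time from the last pre-peak crossing of `level` x peak amplitude to the
#' peak (ERD) and from the peak to the first post-peak crossing (LRD), with
#' linear interpolation between samples.
#'
#' @param seg A `t_segment`.
#' @param level Amplitude fraction at which the limbs are crossed.
#' @return A tibble with `erd_ms` and `lrd_ms`.
#' @export
erd_lrd <- function(seg, level = 0.30) {
  stopifnot(level > 0, level <= 1)
  p <- seg$peak_index
  peak_amp <- seg$y_uv[p]
  if (peak_amp <= 0) stop("nonpositive T-wave peak amplitude")
  if (level == 1) {
    return(tibble::tibble(erd_ms = 0, lrd_ms = 0))
  }
  # ascending limb, walking backwards from the peak
  t_asc <- seg$t_ms[p] - rev(seg$t_ms[1:p])
  y_asc <- rev(seg$y_uv[1:p])
  erd <- first_down_cross(t_asc, y_asc, level * peak_amp)
  # descending limb
  t_desc <- seg$t_ms[p:length(seg$t_ms)] - seg$t_ms[p]
  y_desc <- seg$y_uv[p:length(seg$y_uv)]
  lrd <- first_down_cross(t_desc, y_desc, level * peak_amp)
  tibble::tibble(erd_ms = erd, lrd_ms = lrd)
}

#' T-wave amplitude
#'
#' Maximum of the vector-magnitude signal within the T-wave support (equal
#' to the value at the T peak), in microvolts.
#'
#' @param seg A `t_segment`.
#' @return Amplitude in microvolts.
#' @export
t_amplitude <- function(seg) {
  max(seg$y_uv)
}

#' Ventricular gradient of a median beat
#'
#' Magnitude of the vector of per-lead time integrals over QRS onset to
#' T end, in microvolt-seconds.
#'
#' @param beat A `median_beat` object with at least two leads.
#' @param fid A one-row fiducial tibble.
#' @return Ventricular gradient in microvolt-seconds.
#' @export
ventricular_gradient <- function(beat, fid) {
  m <- beat$beat
  if (is.null(dim(m)) || ncol(m) < 2) {
    stop("ventricular gradient requires a multi-lead beat")
  }
  t_ms <- (seq_len(nrow(m)) - 1) / beat$fs_hz * 1000
  idx <- t_ms >= fid$qrs_onset_ms & t_ms <= fid$t_end_ms
  dt_s <- 1 / beat$fs_hz
  comps <- colSums(m[idx, , drop = FALSE]) * dt_s
  sqrt(sum(comps^2))
}

#' All T-wave morphology biomarkers for one delineated beat
#'
#' @param beat A `median_beat` object.
#' @param fid A one-row fiducial tibble from [delineate_beat()].
#' @param erd_level Amplitude fraction for the ERD/LRD crossings.
#' @param seg_level Amplitude fraction for the T-onset surrogate.
#' @return A one-row tibble with `flatness`, `asymmetry`, `erd_ms`,
#'   `lrd_ms`, `amplitude_uv` and, for multi-lead beats, `vg_uvs`.
#' @export
morphology_record <- function(beat, fid, erd_level = 0.70, seg_level = 0.05) {
  seg <- t_wave_segment(beat, fid, seg_level = seg_level)
  el <- erd_lrd(seg, level = erd_level)
  vg <- if (!is.null(dim(beat$beat)) && ncol(beat$beat) >= 2) {
    ventricular_gradient(beat, fid)
  } else {
    NA_real_
  }
  tibble::tibble(
    flatness = t_flatness(seg),
    asymmetry = t_asymmetry(seg),
    erd_ms = el$erd_ms,
    lrd_ms = el$lrd_ms,
    amplitude_uv = t_amplitude(seg),
    vg_uvs = vg
  )
}
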