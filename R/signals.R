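#' Construct a single physiological channel
#'
#' A channel is an ordered vector of samples taken at a constant sampling
#' rate. It is the atomic unit the cleaning, segmentation and synthesis
#' functions operate on.
#'
#' @param name Channel identifier, e.g. `"ecg"`, `"hr"`, `"foot_gsr"`.
#' @param samples Numeric vector of sample values (finite).
#' @param fs Sampling rate in Hz (> 0).
#' @param units Free-text unit label.
#' @return An object of class `channel_signal`.
#' @examples
#' channel_signal("hr", 60 + sin(seq_len(100) / 10), fs = 15.5, units = "bpm")
#' @export
channel_signal <- function(name, samples, fs, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  assert_scalar_number(fs, "fs", lower = 0, closed_lower = FALSE)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stopf("channel '%s': samples must be finite (no NA/NaN/Inf)", name)
  }
  structure(list(name = name, samples = samples, fs = fs, units = units),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$name, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Describe a linear filter stage
#'
#' Declarative description of one filtering stage. Band edges are given in
#' Hz; any edge at or above `0.45 * fs` is clipped to `0.45 * fs` when the
#' filter is realised (with a warning), mirroring the situation where a
#' recommended analogue band exceeds what the digital sampling rate can
#' represent. A spec whose band degenerates after clipping is invalid.
#'
#' @param family One of `"butterworth-bandpass"`, `"butterworth-highpass"`,
#'   `"butterworth-lowpass"`, `"fir-bandpass"`, `"notch"`, `"gaussian"`.
#' @param edges Numeric band edges in Hz: length 2 for band-pass/notch,
#'   length 1 for high-/low-pass. Ignored for `"gaussian"`.
#' @param order Filter order (>= 1). Defaults: Butterworth 4, FIR 101,
#'   notch 2 (realised as an order-2 band-stop).
#' @param zero_phase Apply forward-backward (no net delay)? Default `TRUE`.
#' @param sigma_s Gaussian smoothing width in seconds (family `"gaussian"`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(family, edges = NULL, order = NULL,
                        zero_phase = TRUE, sigma_s = 0.5) {
  families <- c("butterworth-bandpass", "butterworth-highpass",
                "butterworth-lowpass", "fir-bandpass", "notch", "gaussian")
  family <- match.arg(family, families)
  order <- order %||% switch(family,
    "fir-bandpass" = 101L, "notch" = 2L, "gaussian" = 1L, 4L)
  if (order < 1) stopf("filter order must be >= 1")
  n_edges <- switch(family,
    "butterworth-bandpass" = 2L, "fir-bandpass" = 2L, "notch" = 2L,
    "butterworth-highpass" = 1L, "butterworth-lowpass" = 1L, 0L)
  if (n_edges > 0L) {
    if (length(edges) != n_edges || any(edges <= 0)) {
      stopf("family '%s' needs %d positive edge(s) in Hz", family, n_edges)
    }
    if (n_edges == 2L && edges[1] >= edges[2]) {
      stopf("band edges must be increasing")
    }
  }
  assert_scalar_number(sigma_s, "sigma_s", lower = 0, closed_lower = FALSE)
  structure(list(family = family, edges = as.numeric(edges), order = order,
                 zero_phase = isTRUE(zero_phase), sigma_s = sigma_s),
            class = "filter_spec")
}

# Clip band edges to 0.45*fs; error if the band degenerates.
clip_edges <- function(edges, fs, family) {
  cap <- 0.45 * fs
  if (any(edges > cap)) {
    warnf("%s: band edge(s) %s Hz exceed 0.45*fs = %g Hz at fs = %g Hz; clipped",
          family, paste(format(edges[edges > cap]), collapse = ", "), cap, fs)
    edges <- pmin(edges, cap)
  }
  if (length(edges) == 2L && edges[1] >= edges[2]) {
    stopf("invalid filter spec: %s band (%g-%g Hz) degenerates after clipping at fs = %g Hz",
          family, edges[1], edges[2], fs)
  }
  if (any(edges >= fs / 2)) {
    stopf("invalid filter spec: %s edge at/above Nyquist (fs = %g Hz)", family, fs)
  }
  edges
}

gaussian_smooth <- function(x, fs, sigma_s) {
  sigma <- sigma_s * fs
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  # reflect-pad so the smoother is length preserving and edge-stable
  xp <- c(rev(x[seq_len(min(half, n))]), x, rev(x[seq.int(max(1L, n - half + 1L), n)]))
  if (length(xp) < n + 2L * half) xp <- c(xp, rep(x[n], n + 2L * half - length(xp)))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Apply a filter stage to a channel
#'
#' Realises a [filter_spec()] at the channel's sampling rate and applies it.
#' The output has the same length and sampling rate as the input; with
#' `zero_phase = TRUE` the filter is run forward and backward so it
#' introduces no net delay.
#'
#' @param x A [channel_signal()].
#' @param spec A [filter_spec()].
#' @return The filtered [channel_signal()].
#' @examples
#' fs <- 496
#' t <- seq(0, 2, by = 1 / fs)
#' hum <- channel_signal("ecg", sin(2 * pi * 60 * t), fs)
#' quiet <- apply_filter(hum, filter_spec("notch", c(59, 61)))
#' sd(quiet$samples) / sd(hum$samples) # < 0.05
#' @export
apply_filter <- function(x, spec) {
  stopifnot(inherits(x, "channel_signal"), inherits(spec, "filter_spec"))
  if (length(x$samples) == 0L) stopf("empty signal: nothing to filter")
  y <- run_filter_stage(x$samples, x$fs, spec)
  channel_signal(x$name, y, x$fs, x$units)
}

run_filter_stage <- function(v, fs, spec) {
  if (spec$family == "gaussian") {
    return(gaussian_smooth(v, fs, spec$sigma_s))
  }
  edges <- clip_edges(spec$edges, fs, spec$family)
  w <- edges / (fs / 2)
  flt <- switch(spec$family,
    "butterworth-bandpass" = signal::butter(spec$order, w, type = "pass"),
    "butterworth-highpass" = signal::butter(spec$order, w, type = "high"),
    "butterworth-lowpass"  = signal::butter(spec$order, w, type = "low"),
    "notch"                = signal::butter(spec$order, w, type = "stop"),
    "fir-bandpass"         = signal::Arma(b = as.numeric(signal::fir1(spec$order, w, type = "pass")),
                                          a = 1))
  # odd-reflection padding suppresses the start/end transients of both the
  # single-pass and the forward-backward application
  n <- length(v)
  np <- min(n - 1L, 3L * max(length(flt$b), length(flt$a), 34L))
  vp <- if (np > 0L) {
    c(2 * v[1] - rev(v[2:(np + 1L)]), v, 2 * v[n] - rev(v[(n - np):(n - 1L)]))
  } else v
  yp <- if (spec$zero_phase) {
    as.numeric(signal::filtfilt(flt, vp))
  } else {
    as.numeric(signal::filter(flt, vp))
  }
  yp[(np + 1L):(np + n)]
}

#' Min-max normalisation to [0, 1]
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' input (zero range) maps to all zeros rather than dividing by zero.
#'
#' @param x Numeric vector (non-empty).
#' @return Numeric vector in `[0, 1]` of the same length.
#' @examples
#' minmax_normalize(c(0, 5, 10)) # 0.0 0.5 1.0
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L) stopf("empty input")
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# "normalised to the maximum value": divide by the (positive) maximum so a
# constant positive level maps to 1 everywhere.
scale_to_max <- function(x) {
  m <- max(x)
  if (m <= 0) m <- max(abs(x))
  if (m == 0) return(rep(0, length(x)))
  x / m
}

#' Clean a physiological channel with its standard recipe
#'
#' Applies the per-modality cleaning chain used throughout the package:
#' \describe{
#'   \item{ecg, hr}{notch 59-61 Hz, then zero-phase FIR band-pass
#'     1.5-150 Hz, then min-max normalisation.}
#'   \item{gsr}{Butterworth low-pass 4 Hz, then Gaussian smoothing
#'     (`sigma_s` seconds), then scaling to the maximum value.}
#'   \item{emg}{Butterworth band-pass 0.5-500 Hz (the upper edge is clipped
#'     to `0.45 * fs` when the sampling rate cannot represent it), then a
#'     59-61 Hz notch, then min-max normalisation.}
#'   \item{resp}{Butterworth high-pass 0.05 Hz then low-pass 0.70 Hz.}
#' }
#' Band edges the sampling rate cannot carry are clipped with a warning; a
#' stage whose whole band falls away raises an error naming the stage.
#'
#' @param x A [channel_signal()].
#' @param kind One of `"ecg"`, `"hr"`, `"gsr"`, `"emg"`, `"resp"`.
#' @param butter_order,fir_order,notch_order Filter orders for the stages.
#' @param sigma_s Gaussian smoothing width for GSR, in seconds.
#' @return The cleaned [channel_signal()].
#' @seealso [ecg_qrs_band()] for the narrow QRS-emphasis band.
#' @export
clean_channel <- function(x, kind = c("ecg", "hr", "gsr", "emg", "resp"),
                          butter_order = 4L, fir_order = 101L,
                          notch_order = 2L, sigma_s = 0.5) {
  stopifnot(inherits(x, "channel_signal"))
  kind <- match.arg(kind)
  stage <- function(label, spec) {
    tryCatch(run_filter_stage(v, x$fs, spec),
             error = function(e) stopf("stage '%s' (%s): %s", label, kind,
                                       conditionMessage(e)))
  }
  v <- x$samples
  if (length(v) == 0L) stopf("empty signal")
  if (kind %in% c("ecg", "hr")) {
    v <- stage("notch", filter_spec("notch", c(59, 61), notch_order))
    # a Hamming-window FIR needs ~3.3*fs/edge taps before its transition
    # band is narrow enough to realise the 1.5 Hz low edge; grow the order
    # with fs so baseline wander below the passband is actually attenuated
    fir_eff <- max(fir_order, 2L * ceiling(1.65 * x$fs / 1.5) + 1L)
    v <- stage("fir-bandpass", filter_spec("fir-bandpass", c(1.5, 150), fir_eff))
    v <- minmax_normalize(v)
  } else if (kind == "gsr") {
    v <- stage("lowpass", filter_spec("butterworth-lowpass", 4, butter_order))
    v <- gaussian_smooth(v, x$fs, sigma_s)
    v <- scale_to_max(v)
  } else if (kind == "emg") {
    v <- stage("bandpass", filter_spec("butterworth-bandpass", c(0.5, 500), butter_order))
    v <- stage("notch", filter_spec("notch", c(59, 61), notch_order))
    v <- minmax_normalize(v)
  } else { # resp
    v <- stage("highpass", filter_spec("butterworth-highpass", 0.05, butter_order))
    v <- stage("lowpass", filter_spec("butterworth-lowpass", 0.70, butter_order))
  }
  channel_signal(x$name, v, x$fs, x$units)
}

#' Narrow QRS-emphasis band of an ECG channel
#'
#' 5-15 Hz Butterworth band-pass, the classic band that emphasises the QRS
#' complex for beat detection. Offered alongside [clean_channel()] (whose
#' wide 1.5-150 Hz band preserves full ECG morphology).
#'
#' @param x An ECG [channel_signal()].
#' @param order Butterworth order.
#' @return The band-passed [channel_signal()].
#' @export
ecg_qrs_band <- function(x, order = 4L) {
  apply_filter(x, filter_spec("butterworth-bandpass", c(5, 15), order))
}

# Linear resampling of a channel to a new rate (same time span).
resample_channel <- function(x, fs_out) {
  stopifnot(inherits(x, "channel_signal"))
  assert_scalar_number(fs_out, "fs_out", lower = 0, closed_lower = FALSE)
  n <- length(x$samples)
  dur <- n / x$fs
  t_in <- (seq_len(n) - 1) / x$fs
  n_out <- max(1L, floor(dur * fs_out))
  t_out <- (seq_len(n_out) - 1) / fs_out
  y <- stats::approx(t_in, x$samples, xout = t_out, rule = 2)$y
  channel_signal(x$name, y, fs_out, x$units)
}
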