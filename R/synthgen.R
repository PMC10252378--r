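#' Drive protocol: ordered phases with durations
#'
#' The default plan mimics a real-drive stress protocol: a 15-minute rest,
#' a city segment, an uninterrupted highway stretch, a second city segment
#' and a closing 15-minute rest. Rest, highway and city phases are taken to
#' induce low, medium and high stress. `scale` shrinks every duration so a
#' full synthetic drive generates in seconds (desk scale 0.1 by default
#' elsewhere in the package).
#'
#' @param phases Character vector of phases (`"rest"`, `"city"`,
#'   `"highway"`); must start and end with rest.
#' @param durations_s Matching durations in seconds (full scale).
#' @param scale Multiplier applied to all durations (> 0).
#' @return An object of class `drive_protocol`.
#' @examples
#' drive_protocol(scale = 0.1) # 90 s rests, 39 s-per-minute drive phases
#' @export
drive_protocol <- function(phases = c("rest", "city", "highway", "city", "rest"),
                           durations_s = c(900, 600, 900, 600, 900),
                           scale = 1) {
  stopifnot(length(phases) == length(durations_s))
  phases <- match.arg(phases, c("rest", "city", "highway"), several.ok = TRUE)
  if (phases[1] != "rest" || phases[length(phases)] != "rest") {
    stopf("protocol must start and end with a rest phase")
  }
  if (any(durations_s <= 0)) stopf("durations must be positive")
  assert_scalar_number(scale, "scale", lower = 0, closed_lower = FALSE)
  structure(list(phases = phases, durations_s = durations_s * scale,
                 scale = scale),
            class = "drive_protocol")
}

#' Phase annotation implied by a protocol
#'
#' Lays the protocol's phases end to end from time zero and labels them
#' under the requested scheme.
#'
#' @param protocol A [drive_protocol()].
#' @param label_scheme `"three"` (rest/highway/city -> low/medium/high) or
#'   `"two"` (rest -> relaxed, driving -> stressed).
#' @return A [phase_annotation()] covering the full drive.
#' @export
phase_schedule <- function(protocol, label_scheme = c("three", "two")) {
  stopifnot(inherits(protocol, "drive_protocol"))
  ends <- cumsum(protocol$durations_s)
  starts <- c(0, ends[-length(ends)])
  phase_annotation(starts, ends, protocol$phases, match.arg(label_scheme))
}

#' Total duration of a protocol in seconds
#' @param protocol A [drive_protocol()].
#' @return Numeric scalar.
#' @export
protocol_duration <- function(protocol) sum(protocol$durations_s)

#' Parametric model of one synthetic channel
#'
#' Declares how a channel is synthesised: a baseline level plus a
#' per-stress-level offset, an oscillatory component, event-like transients
#' whose rate depends on the stress level (phasic skin-conductance
#' responses, muscle bursts), and the classic noise taxonomy the cleaning
#' recipes target — white noise, slow baseline wander and mains (powerline)
#' interference. These are synthetic stand-ins: the contract is realistic
#' sampling rates, removable noise and controllable class separation, not
#' physiological waveform realism.
#'
#' @param kind Channel kind; one of `"ecg"`, `"hr"`, `"gsr"`, `"emg"`,
#'   `"resp"`, `"scalar"` (generic slow channel, e.g. temperature or
#'   breathing rate).
#' @param name Channel name (defaults to `kind`).
#' @param fs Sampling rate in Hz.
#' @param baseline Baseline level in channel units.
#' @param offsets Numeric length-3 vector: additive offset at low, medium
#'   and high stress.
#' @param osc_hz,osc_amp Frequency (Hz) and amplitude of the oscillatory
#'   component (0 disables it).
#' @param white_sd White-noise standard deviation (>= 0).
#' @param wander_amp,wander_hz Baseline-wander amplitude and frequency.
#' @param powerline_amp 60 Hz mains-interference amplitude.
#' @param event_rate Length-3 nonnegative vector: transient events per
#'   second at low/medium/high stress.
#' @param event_amp,event_tau_s Event amplitude and exponential decay time.
#' @param units Unit label.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(kind, name = kind, fs, baseline = 0,
                          offsets = c(0, 0, 0), osc_hz = 0, osc_amp = 0,
                          white_sd = 0, wander_amp = 0, wander_hz = 0.1,
                          powerline_amp = 0, event_rate = c(0, 0, 0),
                          event_amp = 0, event_tau_s = 1, units = "") {
  kind <- match.arg(kind, c("ecg", "hr", "gsr", "emg", "resp", "scalar"))
  assert_scalar_number(fs, "fs", lower = 0, closed_lower = FALSE)
  if (white_sd < 0 || any(event_rate < 0)) stopf("sigma and rates must be >= 0")
  stopifnot(length(offsets) == 3L, length(event_rate) == 3L)
  structure(list(kind = kind, name = name, fs = fs, baseline = baseline,
                 offsets = as.numeric(offsets), osc_hz = osc_hz,
                 osc_amp = osc_amp, white_sd = white_sd,
                 wander_amp = wander_amp, wander_hz = wander_hz,
                 powerline_amp = powerline_amp,
                 event_rate = as.numeric(event_rate), event_amp = event_amp,
                 event_tau_s = event_tau_s, units = units),
            class = "channel_model")
}

#' Default channel models per recording device
#'
#' `"srad"` emulates the in-car physiological montage (ECG, heart rate,
#' foot/hand skin conductance, trapezius EMG, respiration); `"bh"` a chest
#' strap (heart rate, breathing rate, posture, activity); `"e4"` a wrist
#' device (skin conductance, blood-volume pulse, heart rate, skin
#' temperature, acceleration). Stress offsets default to five white-noise
#' standard deviations per stress step on the stress-sensitive channels, so
#' adjacent classes are separated by 5 sigma; `noise_scale` multiplies all
#' noise amplitudes (an SNR dial), and `sep_scale` multiplies the offsets.
#'
#' @param device `"srad"`, `"bh"` or `"e4"`.
#' @param noise_scale,sep_scale Positive multipliers.
#' @param prefix Optional channel-name prefix (used when pooling devices).
#' @return Named list of [channel_model()] objects.
#' @export
default_channel_models <- function(device = c("srad", "bh", "e4"),
                                   noise_scale = 1, sep_scale = 1,
                                   prefix = "") {
  device <- match.arg(device)
  ns <- noise_scale; ss <- sep_scale
  mods <- switch(device,
    srad = list(
      channel_model("ecg", "ecg", fs = 496, baseline = 0,
                    offsets = ss * c(0, 10, 20), white_sd = 0.05 * ns,
                    wander_amp = 0.3 * ns, wander_hz = 0.2,
                    powerline_amp = 0.2 * ns, units = "mV"),
      channel_model("hr", "hr", fs = 15.5, baseline = 70,
                    offsets = ss * c(0, 10, 20), osc_hz = 0.01, osc_amp = 1,
                    white_sd = 2 * ns, units = "bpm"),
      channel_model("gsr", "foot_gsr", fs = 31, baseline = 2,
                    offsets = ss * c(0, 1, 2), white_sd = 0.2 * ns,
                    event_rate = c(0.01, 0.05, 0.1), event_amp = 0.8,
                    event_tau_s = 3, units = "uS"),
      channel_model("gsr", "hand_gsr", fs = 31, baseline = 3,
                    offsets = ss * c(0, 1, 2), white_sd = 0.2 * ns,
                    event_rate = c(0.01, 0.05, 0.1), event_amp = 0.8,
                    event_tau_s = 3, units = "uS"),
      channel_model("emg", "emg", fs = 495, baseline = 0,
                    offsets = ss * c(0, 0.25, 0.5), white_sd = 0.05 * ns,
                    powerline_amp = 0.1 * ns,
                    event_rate = c(0.02, 0.1, 0.2), event_amp = 0.5,
                    event_tau_s = 0.2, units = "mV"),
      channel_model("resp", "resp", fs = 31, baseline = 0,
                    offsets = c(0, 0, 0), osc_hz = 0.25, osc_amp = 1,
                    white_sd = 0.1 * ns, wander_amp = 0.2 * ns,
                    wander_hz = 0.03, units = "au")),
    bh = list(
      channel_model("hr", "bh_hr", fs = 1, baseline = 70,
                    offsets = ss * c(0, 10, 20), white_sd = 2 * ns,
                    units = "bpm"),
      channel_model("scalar", "bh_br", fs = 1, baseline = 15,
                    offsets = ss * c(0, 2.5, 5), white_sd = 0.5 * ns,
                    units = "breaths/min"),
      channel_model("scalar", "bh_posture", fs = 1, baseline = 0,
                    offsets = c(0, 0, 0), white_sd = 5 * ns, units = "deg"),
      channel_model("scalar", "bh_activity", fs = 1, baseline = 0.1,
                    offsets = ss * c(0, 0.1, 0.2), white_sd = 0.05 * ns,
                    units = "g")),
    e4 = list(
      channel_model("gsr", "e4_gsr", fs = 4, baseline = 1,
                    offsets = ss * c(0, 0.75, 1.5), white_sd = 0.15 * ns,
                    event_rate = c(0.01, 0.05, 0.1), event_amp = 0.6,
                    event_tau_s = 3, units = "uS"),
      channel_model("scalar", "e4_bvp", fs = 64, baseline = 0,
                    offsets = c(0, 0, 0), osc_hz = 1.2, osc_amp = 1,
                    white_sd = 0.2 * ns, units = "au"),
      channel_model("hr", "e4_hr", fs = 1, baseline = 70,
                    offsets = ss * c(0, 10, 20), white_sd = 2 * ns,
                    units = "bpm"),
      channel_model("scalar", "e4_temp", fs = 4, baseline = 33,
                    offsets = ss * c(0, -0.5, -1), white_sd = 0.1 * ns,
                    units = "degC"),
      channel_model("scalar", "e4_accel", fs = 32, baseline = 0.05,
                    offsets = ss * c(0, 0.05, 0.1), white_sd = 0.05 * ns,
                    units = "g")))
  names(mods) <- paste0(prefix, vapply(mods, `[[`, character(1), "name"))
  for (nm in names(mods)) mods[[nm]]$name <- nm
  mods
}

# stress level (1/2/3) of each sample midpoint given the protocol
sample_levels <- function(protocol, fs, n) {
  t_mid <- (seq_len(n) - 0.5) / fs
  ends <- cumsum(protocol$durations_s)
  starts <- c(0, ends[-length(ends)])
  lev_map <- c(rest = 1L, highway = 2L, city = 3L)
  lev <- integer(n)
  for (i in seq_along(starts)) {
    lev[t_mid >= starts[i] & t_mid < ends[i]] <- lev_map[[protocol$phases[i]]]
  }
  lev[lev == 0L] <- lev_map[[protocol$phases[length(starts)]]]
  lev
}

synth_channel <- function(model, protocol) {
  fs <- model$fs
  n <- max(1L, floor(protocol_duration(protocol) * fs))
  t <- (seq_len(n) - 0.5) / fs
  lev <- sample_levels(protocol, fs, n)
  drive <- model$baseline + model$offsets[lev]
  if (model$kind == "ecg") {
    # periodic pulse train whose instantaneous rate follows the stress
    # level (baseline interpreted as resting bpm offsetted per level);
    # no morphological realism claimed
    bpm <- 60 + model$offsets[lev]
    phase <- cumsum(bpm / 60 / fs)
    beat <- floor(phase)
    pulse_pos <- which(diff(c(0, beat)) > 0)
    x <- numeric(n)
    width <- max(1L, round(0.02 * fs))
    for (p in pulse_pos) {
      idx <- p:min(n, p + 3L * width)
      x[idx] <- x[idx] + exp(-0.5 * ((idx - p) / width)^2)
    }
    x <- x + model$baseline
  } else {
    x <- drive
  }
  if (model$osc_amp > 0) {
    x <- x + model$osc_amp * sin(2 * pi * model$osc_hz * t +
                                   stats::runif(1, 0, 2 * pi))
  }
  if (model$event_amp != 0 && any(model$event_rate > 0)) {
    p_evt <- pmin(1, model$event_rate[lev] / fs)
    impulses <- as.numeric(stats::runif(n) < p_evt) * model$event_amp
    decay <- exp(-1 / (model$event_tau_s * fs))
    x <- x + as.numeric(stats::filter(impulses, decay, method = "recursive"))
  }
  if (model$wander_amp > 0) {
    x <- x + model$wander_amp * sin(2 * pi * model$wander_hz * t +
                                      stats::runif(1, 0, 2 * pi))
  }
  if (model$powerline_amp > 0) {
    x <- x + model$powerline_amp * sin(2 * pi * 60 * t +
                                         stats::runif(1, 0, 2 * pi))
  }
  if (model$white_sd > 0) x <- x + stats::rnorm(n, 0, model$white_sd)
  # fixed-precision storage keeps recordings platform-independent
  channel_signal(model$name, round(x, 6), fs, model$units)
}

#' Generate one synthetic drive
#'
#' Synthesises every channel of `models` over the protocol, attaching the
#' phase annotation. Reproducible: the same seed yields bitwise-identical
#' recordings.
#'
#' @param protocol A [drive_protocol()].
#' @param models Named list of [channel_model()] objects (default: the
#'   in-car montage of [default_channel_models()]).
#' @param seed Integer seed.
#' @param label_scheme `"three"` or `"two"`.
#' @param id Recording identifier.
#' @return A [multi_channel_recording()].
#' @examples
#' rec <- generate_drive(drive_protocol(scale = 0.02), seed = 1)
#' recording_duration(rec)
#' @export
generate_drive <- function(protocol, models = default_channel_models("srad"),
                           seed = 1L, label_scheme = c("three", "two"),
                           id = "synthetic_drive") {
  stopifnot(inherits(protocol, "drive_protocol"),
            all(vapply(models, inherits, logical(1), "channel_model")))
  label_scheme <- match.arg(label_scheme)
  channels <- local_seed(seed, lapply(models, synth_channel, protocol = protocol))
  multi_channel_recording(channels, phase_schedule(protocol, label_scheme), id)
}

#' Generate a cohort of synthetic drives
#'
#' Per-drive seeds are derived deterministically from the master seed, and
#' each drive gets a mild baseline jitter so drives differ the way sessions
#' and subjects do.
#'
#' @inheritParams generate_drive
#' @param n_drives Number of drives (>= 1).
#' @param jitter_sd Standard deviation of the per-drive baseline jitter,
#'   as a fraction of each channel's white-noise sigma (default 1).
#' @return List of [multi_channel_recording()] objects.
#' @export
generate_cohort <- function(n_drives, protocol,
                            models = default_channel_models("srad"),
                            seed = 1L, label_scheme = c("three", "two"),
                            jitter_sd = 1) {
  stopifnot(n_drives >= 1L)
  label_scheme <- match.arg(label_scheme)
  drive_seeds <- (as.integer(seed) + 7919L * seq_len(n_drives)) %% 2147483647L
  lapply(seq_len(n_drives), function(i) {
    mods_i <- local_seed(drive_seeds[i] + 1L, lapply(models, function(m) {
      m$baseline <- m$baseline + stats::rnorm(1, 0, jitter_sd * max(m$white_sd, 1e-12))
      m
    }))
    generate_drive(protocol, mods_i, seed = drive_seeds[i],
                   label_scheme = label_scheme,
                   id = sprintf("synthetic_drive_%02d", i))
  })
}
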