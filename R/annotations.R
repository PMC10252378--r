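#' Phase annotation of a drive
#'
#' Ordered, non-overlapping intervals marking the driving phase. Phases map
#' to stress labels under the active scheme: the three-level scheme labels
#' rest, highway and city phases as low, medium and high stress; the
#' two-level scheme labels rest as relaxed and both driving phases as
#' stressed.
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @param phase Character vector with values in `"rest"`, `"city"`,
#'   `"highway"`.
#' @param label_scheme `"two"` or `"three"`.
#' @return An object of class `phase_annotation` (a data frame of intervals
#'   plus the scheme).
#' @examples
#' phase_annotation(c(0, 90), c(90, 150), c("rest", "city"), "three")
#' @export
phase_annotation <- function(start_s, end_s, phase, label_scheme = c("three", "two")) {
  label_scheme <- match.arg(label_scheme)
  if (length(start_s) == 0L) stopf("empty annotation")
  stopifnot(length(start_s) == length(end_s), length(start_s) == length(phase))
  phase <- match.arg(as.character(phase), c("rest", "city", "highway"),
                     several.ok = TRUE)
  if (any(end_s <= start_s)) stopf("intervals must have positive length")
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]; phase <- phase[o]
  if (length(start_s) > 1L && any(start_s[-1] < end_s[-length(end_s)] - 1e-9)) {
    stopf("intervals overlap")
  }
  structure(
    data.frame(start_s = start_s, end_s = end_s, phase = phase,
               stringsAsFactors = FALSE),
    label_scheme = label_scheme, class = c("phase_annotation", "data.frame"))
}

#' Stress labels of a labelling scheme
#'
#' @param scheme `"two"` or `"three"`.
#' @return Character vector of ordered class labels.
#' @export
scheme_labels <- function(scheme = c("three", "two")) {
  scheme <- match.arg(scheme)
  if (scheme == "two") c("relaxed", "stressed") else c("low", "medium", "high")
}

# phase -> label under a scheme
phase_to_label <- function(phase, scheme) {
  if (scheme == "two") {
    ifelse(phase == "rest", "relaxed", "stressed")
  } else {
    c(rest = "low", highway = "medium", city = "high")[phase]
  }
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat(sprintf("<phase_annotation> %d interval(s), scheme '%s'\n",
              nrow(x), attr(x, "label_scheme")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Bundle channels and an annotation into a recording
#'
#' @param channels Named list of [channel_signal()] objects. Channels may
#'   have different sampling rates.
#' @param annotation A [phase_annotation()].
#' @param id Recording identifier.
#' @return An object of class `multi_channel_recording`.
#' @export
multi_channel_recording <- function(channels, annotation, id = "drive") {
  if (length(channels) == 0L) stopf("a recording needs at least one channel")
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_signal")),
            inherits(annotation, "phase_annotation"))
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- vapply(channels, `[[`, character(1), "name")
  }
  dur <- recording_duration_ch(channels)
  if (max(annotation$end_s) > dur + 1e-6) {
    stopf("annotation extends beyond recording duration (%.1f s > %.1f s)",
          max(annotation$end_s), dur)
  }
  structure(list(channels = channels, annotation = annotation, id = id),
            class = "multi_channel_recording")
}

recording_duration_ch <- function(channels) {
  max(vapply(channels, function(ch) length(ch$samples) / ch$fs, numeric(1)))
}

#' Duration of a recording in seconds
#' @param rec A [multi_channel_recording()].
#' @return Length of the longest channel, in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "multi_channel_recording"))
  recording_duration_ch(rec$channels)
}

#' @export
print.multi_channel_recording <- function(x, ...) {
  cat(sprintf("<multi_channel_recording> '%s': %d channel(s), %.1f s\n",
              x$id, length(x$channels), recording_duration(x)))
  for (ch in x$channels) {
    cat(sprintf("  %-10s %8d samples @ %6g Hz\n",
                ch$name, length(ch$samples), ch$fs))
  }
  invisible(x)
}
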