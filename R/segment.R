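#' Construct a segment set directly
#'
#' Container for equal-length labelled windows ready for model training.
#' Usually produced by [segment_record()]; this constructor is for building
#' one from arrays (e.g. simulated features).
#'
#' @param x Numeric array of shape `n_windows x window_len x n_channels`.
#' @param labels Factor (or character) of one stress label per window.
#' @param window_s Window length in seconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param fs Common sampling rate of the windows, in Hz.
#' @param scheme `"two"` or `"three"`.
#' @param channels Optional channel names (length `n_channels`).
#' @return An object of class `segment_set`.
#' @export
segment_set <- function(x, labels, window_s, overlap, fs,
                        scheme = c("three", "two"), channels = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  lv <- scheme_labels(scheme)
  labels <- factor(as.character(labels), levels = lv)
  if (anyNA(labels)) stopf("labels outside the '%s' scheme", scheme)
  if (length(labels) != dim(x)[1]) stopf("one label per window required")
  assert_scalar_number(overlap, "overlap", lower = 0, upper = 1,
                       closed_upper = FALSE)
  channels <- channels %||% dimnames(x)[[3]] %||%
    paste0("ch", seq_len(dim(x)[3]))
  structure(list(x = x, labels = labels, window_s = window_s,
                 overlap = overlap, fs = fs, scheme = scheme,
                 channels = channels),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d window(s) of %g s (%d samples @ %g Hz), %d channel(s), scheme '%s'\n",
              dim(x$x)[1], x$window_s, dim(x$x)[2], x$fs, dim(x$x)[3], x$scheme))
  print(table(x$labels))
  invisible(x)
}

#' Number of windows in a segment set
#' @param ss A [segment_set()].
#' @return Integer count.
#' @export
n_windows <- function(ss) dim(ss$x)[1]

#' Cut a recording into labelled sliding windows
#'
#' All channels are linearly resampled to a common rate, stacked, and cut
#' into equal-length windows with the given overlap. Each window is labelled
#' by the stress label of the phase covering the majority of its samples
#' (windows straddling a phase boundary take the majority side); windows
#' not covered by any annotated phase are dropped.
#'
#' @param rec A [multi_channel_recording()].
#' @param window_s Window length in seconds (default 10).
#' @param overlap Overlap fraction in `[0, 1)` (default 0.5).
#' @param ann A [phase_annotation()]; defaults to the recording's own.
#' @param common_fs Common sampling rate all channels are resampled to
#'   before stacking, in Hz (default 8).
#' @return A [segment_set()].
#' @examples
#' ann <- phase_annotation(0, 100, "rest", "three")
#' rec <- multi_channel_recording(
#'   list(hr = channel_signal("hr", rnorm(800, 70), fs = 8)), ann)
#' seg <- segment_record(rec, window_s = 10, overlap = 0)
#' n_windows(seg) # 10
#' @export
segment_record <- function(rec, window_s = 10, overlap = 0.5,
                           ann = rec$annotation, common_fs = 8) {
  stopifnot(inherits(rec, "multi_channel_recording"),
            inherits(ann, "phase_annotation"))
  assert_scalar_number(window_s, "window_s", lower = 0, closed_lower = FALSE)
  assert_scalar_number(overlap, "overlap", lower = 0, upper = 1,
                       closed_upper = FALSE)
  scheme <- attr(ann, "label_scheme")
  res <- lapply(rec$channels, resample_channel, fs_out = common_fs)
  n_common <- min(vapply(res, function(ch) length(ch$samples), integer(1)))
  mat <- vapply(res, function(ch) ch$samples[seq_len(n_common)],
                numeric(n_common))          # time x channel
  w <- max(1L, round(window_s * common_fs))
  if (w > n_common) {
    stopf("window (%g s = %d samples) longer than recording (%d samples at %g Hz)",
          window_s, w, n_common, common_fs)
  }
  stride <- max(1L, round(w * (1 - overlap)))
  starts <- seq.int(1L, n_common - w + 1L, by = stride)
  # per-sample stress label from the annotation (sample midpoints)
  t_mid <- (seq_len(n_common) - 0.5) / common_fs
  samp_lab <- rep(NA_character_, n_common)
  for (i in seq_len(nrow(ann))) {
    inside <- t_mid >= ann$start_s[i] & t_mid < ann$end_s[i]
    samp_lab[inside] <- phase_to_label(ann$phase[i], scheme)
  }
  lv <- scheme_labels(scheme)
  win_lab <- vapply(starts, function(s) {
    labs <- samp_lab[s:(s + w - 1L)]
    labs <- labs[!is.na(labs)]
    if (length(labs) == 0L) return(NA_character_)
    tab <- table(factor(labs, levels = lv))
    lv[which.max(tab)]          # ties go to the lower stress level
  }, character(1))
  keep <- !is.na(win_lab)
  if (!any(keep)) stopf("no window overlaps the annotated phases")
  starts <- starts[keep]; win_lab <- win_lab[keep]
  x <- array(NA_real_, dim = c(length(starts), w, ncol(mat)),
             dimnames = list(NULL, NULL, colnames(mat)))
  for (j in seq_along(starts)) {
    x[j, , ] <- mat[starts[j]:(starts[j] + w - 1L), , drop = FALSE]
  }
  segment_set(x, win_lab, window_s = window_s, overlap = overlap,
              fs = common_fs, scheme = scheme, channels = colnames(mat))
}

#' Subset the windows of a segment set
#'
#' @param ss A [segment_set()].
#' @param idx Integer (or logical) window indices.
#' @return A [segment_set()] with the selected windows.
#' @export
subset_segments <- function(ss, idx) {
  stopifnot(inherits(ss, "segment_set"))
  segment_set(ss$x[idx, , , drop = FALSE], ss$labels[idx], ss$window_s,
              ss$overlap, ss$fs, ss$scheme, ss$channels)
}

#' Pool several segment sets into one
#'
#' @param ... [segment_set()] objects with identical window shape and scheme.
#' @return A single [segment_set()].
#' @export
bind_segments <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "segment_set")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "segment_set")))
  d1 <- dim(parts[[1]]$x)[-1]
  ok <- vapply(parts, function(p) identical(dim(p$x)[-1], d1) &&
                 identical(p$scheme, parts[[1]]$scheme), logical(1))
  if (!all(ok)) stopf("segment sets differ in window shape or scheme")
  x <- do.call(abind1, lapply(parts, `[[`, "x"))
  labels <- unlist(lapply(parts, function(p) as.character(p$labels)))
  segment_set(x, labels, parts[[1]]$window_s, parts[[1]]$overlap,
              parts[[1]]$fs, parts[[1]]$scheme, parts[[1]]$channels)
}

# bind 3D arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, dim = c(n, d[2], d[3]),
               dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
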