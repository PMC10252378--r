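# Delimited-text readers and writers: one TSV per channel (time_s, value),
# a TSV annotation (start_s, end_s, phase), a JSON metadata sidecar, and
# decision-matrix / metrics tables.

#' Write a recording to a directory of delimited text files
#'
#' Each channel becomes `<name>.channel.tsv` with columns `time_s` and
#' `value`; the phase annotation becomes `annotation.tsv` with columns
#' `start_s`, `end_s`, `phase`; sampling rates, units, the labelling scheme
#' and the recording id go to `recording.json`.
#'
#' @param rec A [multi_channel_recording()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "multi_channel_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in rec$channels) {
    df <- data.frame(time_s = round((seq_along(ch$samples) - 1) / ch$fs, 6),
                     value = ch$samples)
    utils::write.table(df, file.path(dir, paste0(ch$name, ".channel.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  ann <- rec$annotation
  utils::write.table(as.data.frame(ann),
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(id = rec$id, label_scheme = attr(ann, "label_scheme"),
               channels = lapply(rec$channels, function(ch)
                 list(name = ch$name, fs = ch$fs, units = ch$units)))
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_delim_checked <- function(path, expected_cols) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("%s: %s", path, conditionMessage(e)))
  if (!all(expected_cols %in% names(df))) {
    stopf("%s: expected columns %s", path, paste(expected_cols, collapse = ", "))
  }
  num_cols <- setdiff(expected_cols, "phase")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0L) {
      stopf("%s: malformed value in column '%s' at data line %d",
            path, cc, bad[1])
    }
    if (anyNA(v)) stopf("%s: missing value in column '%s' at data line %d",
                        path, cc, which(is.na(v))[1])
    df[[cc]] <- v
  }
  df
}

#' Read an annotation file
#'
#' @param path TSV with columns `start_s`, `end_s`, `phase`.
#' @param label_scheme `"three"` or `"two"`.
#' @return A [phase_annotation()].
#' @export
read_annotation <- function(path, label_scheme = c("three", "two")) {
  df <- read_delim_checked(path, c("start_s", "end_s", "phase"))
  phase_annotation(df$start_s, df$end_s, df$phase, match.arg(label_scheme))
}

#' Read a recording from a directory of channel files
#'
#' Reads every `*.channel.tsv` file plus `annotation.tsv`. Sampling rates
#' and units come from `recording.json` when present, otherwise each
#' channel's rate is inferred from its time column. Channels keep their own
#' (possibly different) rates.
#'
#' @param dir Directory written by [write_recording()] (or hand-assembled
#'   in the same layout).
#' @param label_scheme Scheme override; default from the metadata sidecar,
#'   falling back to `"three"`.
#' @return A [multi_channel_recording()].
#' @export
read_recording <- function(dir, label_scheme = NULL) {
  files <- list.files(dir, pattern = "\\.channel\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stopf("no channel files (*.channel.tsv) in %s", dir)
  ann_path <- file.path(dir, "annotation.tsv")
  if (!file.exists(ann_path)) stopf("missing annotation file: %s", ann_path)
  meta_path <- file.path(dir, "recording.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = FALSE)
  } else NULL
  scheme <- label_scheme %||% meta$label_scheme %||% "three"
  meta_ch <- list()
  for (m in (meta$channels %||% list())) meta_ch[[m$name]] <- m
  channels <- lapply(files, function(f) {
    nm <- sub("\\.channel\\.tsv$", "", basename(f))
    df <- read_delim_checked(f, c("time_s", "value"))
    m <- meta_ch[[nm]]
    fs <- if (!is.null(m)) m$fs else {
      if (nrow(df) < 2L) stopf("%s: cannot infer sampling rate from one sample", f)
      (nrow(df) - 1) / (df$time_s[nrow(df)] - df$time_s[1])
    }
    channel_signal(nm, df$value, fs, units = (m$units %||% ""))
  })
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  multi_channel_recording(channels, read_annotation(ann_path, scheme),
                          id = meta$id %||% basename(dir))
}

#' Guess the cleaning recipe for a channel name
#'
#' Maps conventional channel names to the modality kinds understood by
#' [clean_channel()]: names containing `gsr`/`eda` map to `gsr`, `ecg` to
#' `ecg`, `emg` to `emg`, `resp`/`br` to `resp`, `hr` to `hr`; anything
#' else returns `NA` (left unfiltered, min-max normalised only).
#'
#' @param name Channel name.
#' @return A kind string or `NA`.
#' @export
infer_channel_kind <- function(name) {
  n <- tolower(name)
  if (grepl("gsr|eda", n)) return("gsr")
  if (grepl("ecg", n)) return("ecg")
  if (grepl("emg", n)) return("emg")
  if (grepl("resp|(^|_)br($|_)", n)) return("resp")
  if (grepl("(^|_)hr($|_)|heart", n)) return("hr")
  NA_character_
}

#' Clean every channel of a recording
#'
#' Applies [clean_channel()] with the per-modality recipe inferred from the
#' channel names (see [infer_channel_kind()]); channels with no recognised
#' modality are min-max normalised only.
#'
#' @param rec A [multi_channel_recording()].
#' @param kinds Optional named character vector overriding the inferred
#'   kinds.
#' @return The cleaned [multi_channel_recording()].
#' @export
clean_recording <- function(rec, kinds = NULL) {
  stopifnot(inherits(rec, "multi_channel_recording"))
  channels <- lapply(rec$channels, function(ch) {
    kind <- if (!is.null(kinds) && ch$name %in% names(kinds)) {
      kinds[[ch$name]]
    } else {
      infer_channel_kind(ch$name)
    }
    if (is.na(kind)) {
      channel_signal(ch$name, minmax_normalize(ch$samples), ch$fs, ch$units)
    } else {
      # channels sampled too slowly for their modality's filter chain
      # (e.g. a 1 Hz heart-rate stream and the 59-61 Hz notch) fall back
      # to plain min-max normalisation
      tryCatch(clean_channel(ch, kind), error = function(e) {
        if (!grepl("^stage ", conditionMessage(e))) stop(e)
        warnf("channel '%s': %s; min-max normalised only",
              ch$name, conditionMessage(e))
        channel_signal(ch$name, minmax_normalize(ch$samples), ch$fs, ch$units)
      })
    }
  })
  multi_channel_recording(channels, rec$annotation, rec$id)
}

#' Read / write a decision matrix as delimited text
#'
#' The file is a TSV whose header names the criteria, whose first data row
#' (alternative `.weights`) carries the criterion weights, and whose
#' remaining rows are the alternatives.
#'
#' @param dm A [decision_matrix()].
#' @param path File path.
#' @return `read_decision_matrix()` returns a [decision_matrix()];
#'   `write_decision_matrix()` returns `path` invisibly.
#' @export
write_decision_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "decision_matrix"))
  df <- data.frame(alternative = c(".weights", rownames(dm$X)),
                   rbind(dm$weights, dm$X), check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decision_matrix
#' @export
read_decision_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "alternative") {
    stopf("%s: first column must be 'alternative'", path)
  }
  wrow <- which(df$alternative == ".weights")
  if (length(wrow) != 1L) stopf("%s: expected one '.weights' row", path)
  vals <- as.matrix(df[-wrow, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  suppressWarnings(
    decision_matrix(vals, weights = as.numeric(df[wrow, -1]),
                    names = df$alternative[-wrow],
                    criteria = names(df)[-1]))
}

#' Write the audit trail of an EDAS run
#'
#' Emits delimited tables mirroring the step-by-step worked analysis
#' (average solution, distance matrices, weighted and normalised sums with
#' appraisal scores and ranks) plus a JSON audit record with every
#' intermediate at full precision.
#'
#' @param res An `edas_result` from [run_edas()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_edas_tables <- function(res, dir) {
  stopifnot(inherits(res, "edas_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, col.names = NA)
  wt(t(as.matrix(res$psi)), "average_solution.tsv")
  wt(res$PI, "positive_distance.tsv")
  wt(res$NI, "negative_distance.tsv")
  utils::write.table(summary(res), file.path(dir, "edas_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- list(psi = as.list(res$psi), PI = res$PI, NI = res$NI,
                SPI = as.list(res$SPI), SNI = as.list(res$SNI),
                NSPI = as.list(res$NSPI), NSNI = as.list(res$NSNI),
                lambda = as.list(res$lambda), ranks = as.list(res$ranks),
                weights = res$dm$weights)
  jsonlite::write_json(audit, file.path(dir, "edas_audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a per-class metrics table
#' @param tab Data frame from [metrics_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a confusion matrix as a delimited integer grid
#' @param cm A [confusion_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_confusion_matrix <- function(cm, path) {
  utils::write.table(unclass(cm), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Path to a bundled example decision matrix
#'
#' The package ships the published per-class metrics of six competing
#' convolutional stress classifiers (two-class task, one table per class
#' state) as ready-made decision matrices for the ranking worked example.
#'
#' @param which `"cnn_two_class_relaxed"` or `"cnn_two_class_stressed"`.
#' @return File path inside the installed package.
#' @export
example_decision_matrix <- function(which = c("cnn_two_class_relaxed",
                                              "cnn_two_class_stressed")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".tsv"), package = "drivestress",
              mustWork = TRUE)
}
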