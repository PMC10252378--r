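#' Validated pipeline configuration
#'
#' Plain key-value configuration for [run_pipeline()]. Unknown keys are
#' errors (silent typos being the classic failure mode of pipeline
#' configs); every omitted key takes the documented default, and the
#' resolved value of every defaulted parameter is recorded in the run
#' manifest.
#'
#' @param ... Named configuration values. Recognised keys:
#'   `out_dir` (required), `seed` (default 1), `scheme` ("three"/"two",
#'   default "two"), `n_drives` (default 3), `scale` (protocol desk-scale
#'   factor, default 0.1), `device` ("srad"/"bh"/"e4", default "srad"),
#'   `noise_scale` (default 1), `window_s` (default 10), `overlap`
#'   (default 0.5), `common_fs` (default 8), `architecture`
#'   ("cnn"/"cnn_lstm", default "cnn"), `profile` (default "srad"),
#'   `epochs`, `minibatch` (profile defaults when `NULL`), `split`
#'   (default 0.8), `learning_rate` (default 1e-3), `weights` (EDAS
#'   criterion weights, default [edas_default_weights()]),
#'   `rank_metrics_file` (optional decision-matrix TSV to rank instead of
#'   the freshly computed per-class rows).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    out_dir = NULL, seed = 1L, scheme = "two", n_drives = 3L, scale = 0.1,
    device = "srad", noise_scale = 1, window_s = 10, overlap = 0.5,
    common_fs = 8, architecture = "cnn", profile = "srad", epochs = NULL,
    minibatch = NULL, split = 0.8, learning_rate = 1e-3,
    weights = edas_default_weights(), rank_metrics_file = NULL)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  if (is.null(cfg$out_dir)) stopf("configuration key 'out_dir' is required")
  cfg$scheme <- match.arg(cfg$scheme, c("two", "three"))
  cfg$architecture <- match.arg(cfg$architecture, c("cnn", "cnn_lstm"))
  cfg$device <- match.arg(cfg$device, c("srad", "bh", "e4"))
  cfg$profile <- match.arg(cfg$profile, network_profiles())
  structure(cfg, class = "pipeline_config")
}

md5_of <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full synthetic pipeline
#'
#' Executes, in order: synthesis of a drive cohort, per-channel cleaning,
#' windowed segmentation, classifier training, evaluation on a held-out
#' synthetic drive, and ranking. Writes the metrics table, confusion
#' matrix, ranking tables and a JSON run manifest (config snapshot,
#' package version, per-stage output digests and timings) under
#' `config$out_dir`. Any stage failure aborts with the stage named.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly (also written to
#'   `run_manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("drivestress")),
                   config = unclass(config), stages = list())
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = md5_of(out$files %||% character(0)))
    out$value
  }

  protocol <- drive_protocol(scale = config$scale)
  models <- default_channel_models(config$device,
                                   noise_scale = config$noise_scale)

  cohort <- run_stage("synth", function() {
    drives <- generate_cohort(config$n_drives, protocol, models,
                              seed = config$seed, label_scheme = config$scheme)
    list(value = drives)
  })

  segs <- run_stage("preprocess", function() {
    parts <- lapply(cohort, function(rec) {
      segment_record(clean_recording(rec), window_s = config$window_s,
                     overlap = config$overlap, common_fs = config$common_fs)
    })
    list(value = bind_segments(parts))
  })

  model <- run_stage("train", function() {
    spec <- if (config$architecture == "cnn") {
      build_cnn(config$profile, n_classes = length(scheme_labels(config$scheme)))
    } else {
      build_cnn_lstm(config$profile, n_classes = length(scheme_labels(config$scheme)))
    }
    opts <- training_options(epochs = config$epochs,
                             minibatch = config$minibatch,
                             split = config$split,
                             learning_rate = config$learning_rate,
                             seed = config$seed)
    list(value = train(spec, segs, opts))
  })

  eval_out <- run_stage("evaluate", function() {
    holdout <- generate_drive(protocol, models,
                              seed = (config$seed + 104729L) %% 2147483647L,
                              label_scheme = config$scheme, id = "holdout")
    seg_h <- segment_record(clean_recording(holdout), window_s = config$window_s,
                            overlap = config$overlap, common_fs = config$common_fs)
    pred <- predict(model, seg_h)
    cm <- confusion_matrix(seg_h$labels, pred, classes = model$classes)
    tab <- metrics_table(cm)
    f_cm <- file.path(config$out_dir, "confusion_matrix.tsv")
    f_tab <- file.path(config$out_dir, "metrics_table.tsv")
    write_confusion_matrix(cm, f_cm)
    write_metrics_table(cbind(tab, overall_acc = overall_accuracy(cm)), f_tab)
    list(value = list(cm = cm, tab = tab), files = c(f_cm, f_tab))
  })

  rank_res <- run_stage("rank", function() {
    dm <- if (!is.null(config$rank_metrics_file)) {
      read_decision_matrix(config$rank_metrics_file)
    } else {
      # one alternative per class: rank which stress class the model
      # recognises best
      rows <- lapply(seq_len(nrow(eval_out$tab)), function(i)
        unlist(eval_out$tab[i, c("acc", "rcl", "prc", "f1", "spc")]))
      names(rows) <- eval_out$tab$class
      decision_matrix_from_metrics(rows, weights = config$weights)
    }
    res <- run_edas(dm)
    write_edas_tables(res, file.path(config$out_dir, "edas"))
    list(value = res,
         files = list.files(file.path(config$out_dir, "edas"),
                            full.names = TRUE))
  })

  manifest$rank_1 <- names(rank_res$ranks)[rank_res$ranks == 1L]
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
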