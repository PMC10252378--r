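#' Train a stress classifier on labelled windows
#'
#' Performs a stratified train/validation split, initialises the network
#' with Glorot-uniform weights, and minimises the cross-entropy loss with
#' Adam over shuffled minibatches. Validation loss and accuracy are
#' recorded every `validation_frequency` iterations and once more at the
#' end. The whole procedure is deterministic given `opts$seed`: rerunning
#' with the same data and options reproduces the history bitwise.
#'
#' @param spec A `network_spec` from [build_cnn()] or [build_cnn_lstm()].
#' @param data A [segment_set()] whose scheme has `spec$n_classes` labels.
#' @param opts A [training_options()]; epoch/minibatch defaults come from
#'   the network's profile.
#' @return An object of class `fitted_stress_model` carrying the spec, the
#'   trained weights, the class labels, the train/validation window indices
#'   (`train_idx`, `val_idx`) and a history data frame with columns
#'   `iteration, epoch, train_loss, val_loss, val_acc`.
#' @export
train <- function(spec, data, opts = training_options()) {
  stopifnot(inherits(spec, "network_spec"), inherits(data, "segment_set"),
            inherits(opts, "training_options"))
  opts <- resolve_options(spec, opts)
  classes <- scheme_labels(data$scheme)
  if (length(classes) != spec$n_classes) {
    stopf("scheme '%s' has %d labels but the network expects %d classes",
          data$scheme, length(classes), spec$n_classes)
  }
  y_all <- as.integer(data$labels)
  n <- n_windows(data)
  if (n < 2L) stopf("need at least 2 windows to split and train")
  if (length(unique(y_all)) < spec$n_classes) {
    warnf("training data covers %d of %d classes",
          length(unique(y_all)), spec$n_classes)
  }
  in_channels <- dim(data$x)[3]
  layers <- build_layer_plan(spec, in_channels)

  local_seed(opts$seed, {
    # stratified split before training
    idx_train <- integer(0)
    for (cl in sort(unique(y_all))) {
      members <- which(y_all == cl)
      k <- max(1L, round(opts$split * length(members)))
      idx_train <- c(idx_train, sort(sample(members, k)))
    }
    idx_train <- sort(idx_train)
    idx_val <- setdiff(seq_len(n), idx_train)
    if (length(idx_val) == 0L) idx_val <- idx_train  # degenerate tiny data
    if (opts$minibatch > length(idx_train)) {
      stopf("minibatch (%d) exceeds training-set size (%d)",
            opts$minibatch, length(idx_train))
    }
    Xtr <- data$x[idx_train, , , drop = FALSE]
    ytr <- y_all[idx_train]
    Xva <- data$x[idx_val, , , drop = FALSE]
    yva <- y_all[idx_val]

    par <- init_params(layers, spec$kernel)
    state <- adam_init(par)
    history <- list()
    it <- 0L
    evaluate_val <- function(train_loss, epoch) {
      fwd <- forward_net(layers, par, spec$kernel, Xva, training = FALSE)
      P <- softmax_rows(fwd$logits)
      vloss <- -mean(log(pmax(P[cbind(seq_along(yva), yva)], 1e-12)))
      vacc <- mean(max.col(P, ties.method = "first") == yva)
      history[[length(history) + 1L]] <<-
        data.frame(iteration = it, epoch = epoch, train_loss = train_loss,
                   val_loss = vloss, val_acc = vacc)
    }
    for (epoch in seq_len(opts$epochs)) {
      ord <- sample(length(ytr))
      batches <- split(ord, ceiling(seq_along(ord) / opts$minibatch))
      for (b in batches) {
        it <- it + 1L
        fwd <- forward_net(layers, par, spec$kernel,
                           Xtr[b, , , drop = FALSE], training = TRUE)
        bk <- backward_net(layers, par, spec$kernel, fwd, ytr[b])
        upd <- adam_step(par, bk$grads, state, opts$learning_rate)
        par <- upd$par; state <- upd$state
        if (it %% opts$validation_frequency == 0L) evaluate_val(bk$loss, epoch)
      }
    }
    if (length(history) == 0L || history[[length(history)]]$iteration < it) {
      evaluate_val(NA_real_, opts$epochs)
    }
    structure(list(spec = spec, par = par, layers = layers,
                   classes = classes, scheme = data$scheme,
                   in_channels = in_channels, opts = opts,
                   train_idx = idx_train, val_idx = idx_val,
                   history = do.call(rbind, history)),
              class = "fitted_stress_model")
  })
}

#' @export
print.fitted_stress_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<fitted_stress_model> %s, %d classes, %d parameter(s)\n",
              if (is.null(x$spec$lstm_hidden)) "1D CNN" else "1D CNN-LSTM",
              x$spec$n_classes, count_parameters(x$spec, x$in_channels)))
  cat(sprintf("  final validation: loss %.4f, accuracy %.4f (iteration %d)\n",
              last$val_loss, last$val_acc, last$iteration))
  invisible(x)
}

#' Predict stress labels (and probabilities) for windows
#'
#' @param object A `fitted_stress_model`.
#' @param data A [segment_set()] with the same channel count the model was
#'   trained on.
#' @param type `"class"` for a factor of labels, `"prob"` for the per-class
#'   probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Factor of predicted labels, or a probability matrix.
#' @export
predict.fitted_stress_model <- function(object, data, type = c("class", "prob"),
                                        ...) {
  type <- match.arg(type)
  stopifnot(inherits(data, "segment_set"))
  if (dim(data$x)[3] != object$in_channels) {
    stopf("window shape mismatch: model expects %d channel(s), data has %d",
          object$in_channels, dim(data$x)[3])
  }
  if (n_windows(data) == 0L) {
    return(if (type == "class") factor(character(0), levels = object$classes)
           else matrix(numeric(0), 0, length(object$classes)))
  }
  fwd <- forward_net(object$layers, object$par, object$spec$kernel, data$x,
                     training = FALSE)
  P <- softmax_rows(fwd$logits)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Final validation accuracy of a fitted model
#' @param model A `fitted_stress_model`.
#' @return The last recorded validation accuracy.
#' @export
validation_accuracy <- function(model) {
  stopifnot(inherits(model, "fitted_stress_model"))
  model$history$val_acc[nrow(model$history)]
}

#' Save / load a fitted model as portable JSON
#'
#' Weights and the architecture description are written as a single JSON
#' document, so checkpoints are plain text and platform independent.
#'
#' @param model A `fitted_stress_model`.
#' @param path Output / input file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `fitted_stress_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_stress_model"))
  payload <- list(
    spec = model$spec[c("profile", "blocks", "trailing", "kernel",
                        "lstm_hidden", "dropout", "n_classes")],
    classes = model$classes, scheme = model$scheme,
    in_channels = model$in_channels,
    opts = unclass(model$opts),
    history = model$history,
    par = lapply(model$par, function(p) list(dim = dim(p) %||% length(p),
                                             data = as.numeric(p))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- new_network_spec(pl$spec$profile, pl$spec$blocks, pl$spec$trailing,
                           pl$spec$kernel,
                           if (is.null(pl$spec$lstm_hidden)) NULL else as.integer(pl$spec$lstm_hidden),
                           pl$spec$dropout, pl$spec$n_classes)
  par <- lapply(pl$par, function(p) {
    d <- as.integer(p$dim)
    if (length(d) > 1L) array(p$data, dim = d) else as.numeric(p$data)
  })
  opts <- do.call(training_options, pl$opts[c("epochs", "minibatch",
                                              "validation_frequency", "split",
                                              "learning_rate", "seed")])
  structure(list(spec = spec, par = par,
                 layers = build_layer_plan(spec, as.integer(pl$in_channels)),
                 classes = pl$classes, scheme = pl$scheme,
                 in_channels = as.integer(pl$in_channels), opts = opts,
                 history = as.data.frame(pl$history)),
            class = "fitted_stress_model")
}
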