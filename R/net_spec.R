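# Device profiles and their convolutional stacks.
#
# Wrist/chest device groups share two stack shapes: the wearable profiles
# (srad, e4l, e4r, e4lr, bh_e4lr) use four blocks of 8/32/64/128 filters
# plus a trailing 8-filter conv; the chest-strap profile (bh) uses three
# blocks of 128/64/32 filters and no trailing conv. Fusion profiles (e4lr,
# bh_e4lr) use early fusion: constituent-device channels are stacked as
# input channels of the deeper stack.
profile_table <- function() {
  list(
    srad    = list(blocks = c(8L, 32L, 64L, 128L), trailing = 8L,
                   lstm = 250L, dropout = 0.4, epochs = 20L, minibatch = 30L),
    e4l     = list(blocks = c(8L, 32L, 64L, 128L), trailing = 8L,
                   lstm = 300L, dropout = 0.5, epochs = 30L, minibatch = 20L),
    e4r     = list(blocks = c(8L, 32L, 64L, 128L), trailing = 8L,
                   lstm = 200L, dropout = 0.5, epochs = 30L, minibatch = 20L),
    e4lr    = list(blocks = c(8L, 32L, 64L, 128L), trailing = 8L,
                   lstm = 200L, dropout = 0.5, epochs = 30L, minibatch = 20L),
    bh      = list(blocks = c(128L, 64L, 32L), trailing = NULL,
                   lstm = 200L, dropout = 0.5, epochs = 30L, minibatch = 20L),
    bh_e4lr = list(blocks = c(8L, 32L, 64L, 128L), trailing = 8L,
                   lstm = 200L, dropout = 0.5, epochs = 30L, minibatch = 20L))
}

#' Device profiles available for the stress classifiers
#' @return Character vector of profile names.
#' @export
network_profiles <- function() names(profile_table())

new_network_spec <- function(profile, blocks, trailing, kernel, lstm_hidden,
                             dropout, n_classes) {
  if (!n_classes %in% c(2L, 3L)) stopf("n_classes must be 2 or 3")
  if (xor(is.null(lstm_hidden), is.null(dropout))) {
    stopf("lstm_hidden and dropout must be given together (hybrid) or both absent")
  }
  structure(list(profile = profile, blocks = as.integer(blocks),
                 trailing = if (is.null(trailing)) NULL else as.integer(trailing),
                 kernel = as.integer(kernel),
                 lstm_hidden = lstm_hidden, dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' Declare a 1D CNN stress classifier
#'
#' Builds the declarative architecture for a device profile: a stack of
#' Conv1D blocks (kernel 3, causal padding, each followed by ReLU and layer
#' normalisation), an optional trailing conv, global average pooling, a
#' fully connected layer of width `n_classes`, softmax and a cross-entropy
#' classification head. Filter counts per profile: the wearable profiles
#' use blocks of 8, 32, 64 and 128 filters with a trailing 8-filter conv;
#' the `bh` chest-strap profile uses 128, 64 and 32 filters with no
#' trailing conv.
#'
#' @param profile One of `"srad"`, `"e4l"`, `"e4r"`, `"e4lr"`, `"bh"`,
#'   `"bh_e4lr"`.
#' @param n_classes 2 or 3 stress levels.
#' @param kernel Convolution kernel length (default 3).
#' @return An object of class `network_spec`.
#' @examples
#' build_cnn("srad", 3)$blocks # 8 32 64 128
#' @export
build_cnn <- function(profile, n_classes = 2L, kernel = 3L) {
  p <- profile_table()[[match.arg(profile, network_profiles())]]
  new_network_spec(profile, p$blocks, p$trailing, kernel,
                   lstm_hidden = NULL, dropout = NULL, n_classes = n_classes)
}

#' Declare a hybrid 1D CNN-LSTM stress classifier
#'
#' Same convolutional front end as [build_cnn()], followed by an LSTM layer
#' whose final hidden state feeds a dropout layer and the fully connected /
#' softmax / classification head. Hidden sizes per profile: 250 (`srad`),
#' 300 (`e4l`), 200 otherwise; dropout 0.4 for `srad` and 0.5 otherwise.
#'
#' @inheritParams build_cnn
#' @param lstm_hidden,dropout Optional overrides of the profile defaults.
#' @return An object of class `network_spec` with LSTM fields set.
#' @examples
#' s <- build_cnn_lstm("srad", 2)
#' c(s$lstm_hidden, s$dropout) # 250 0.4
#' @export
build_cnn_lstm <- function(profile, n_classes = 2L, kernel = 3L,
                           lstm_hidden = NULL, dropout = NULL) {
  p <- profile_table()[[match.arg(profile, network_profiles())]]
  new_network_spec(profile, p$blocks, p$trailing, kernel,
                   lstm_hidden = as.integer(lstm_hidden %||% p$lstm),
                   dropout = dropout %||% p$dropout, n_classes = n_classes)
}

#' @export
print.network_spec <- function(x, ...) {
  kind <- if (is.null(x$lstm_hidden)) "1D CNN" else "1D CNN-LSTM"
  cat(sprintf("<network_spec> %s (profile '%s', %d classes)\n",
              kind, x$profile, x$n_classes))
  cat(sprintf("  conv blocks: %s (kernel %d, causal, ReLU + LN)\n",
              paste(x$blocks, collapse = "-"), x$kernel))
  if (!is.null(x$trailing)) cat(sprintf("  trailing conv: %d filters\n", x$trailing))
  if (is.null(x$lstm_hidden)) {
    cat("  head: GAP -> FC -> softmax\n")
  } else {
    cat(sprintf("  head: LSTM(%d) -> dropout(%.1f) -> FC -> softmax\n",
                x$lstm_hidden, x$dropout))
  }
  invisible(x)
}

#' Training options
#'
#' @param epochs Maximum passes over the training split.
#' @param minibatch Windows per optimisation step.
#' @param validation_frequency Iterations between validation evaluations
#'   (default 10).
#' @param split Training fraction of the data (stratified), in (0, 1).
#' @param learning_rate Initial Adam learning rate.
#' @param seed Integer seed controlling the split, weight initialisation
#'   and minibatch shuffling.
#' @return An object of class `training_options`.
#' @export
training_options <- function(epochs = NULL, minibatch = NULL,
                             validation_frequency = 10L, split = 0.8,
                             learning_rate = 1e-3, seed = 1L) {
  assert_scalar_number(split, "split", lower = 0, upper = 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  structure(list(epochs = epochs, minibatch = minibatch,
                 validation_frequency = as.integer(validation_frequency),
                 split = split, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "training_options")
}

# Fill epoch/minibatch defaults from the network's profile.
resolve_options <- function(spec, opts) {
  p <- profile_table()[[spec$profile]]
  opts$epochs <- as.integer(opts$epochs %||% p$epochs)
  opts$minibatch <- as.integer(opts$minibatch %||% p$minibatch)
  if (opts$epochs < 1L || opts$minibatch < 1L) stopf("epochs and minibatch must be >= 1")
  opts
}

#' Exact trainable-parameter count of a network
#'
#' A conv layer with kernel `k`, `c_in` input channels and `c_out` filters
#' contributes `k * c_in * c_out + c_out` parameters; each layer norm
#' contributes `2 * c_out`; the LSTM contributes `4 * h * (c_in + h + 1)`;
#' the fully connected layer `c_in * n_classes + n_classes`.
#'
#' @param spec A `network_spec`.
#' @param in_channels Number of input channels.
#' @param layer_norm Count the per-block layer-norm gain/bias pairs?
#'   Default `TRUE`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, in_channels, layer_norm = TRUE) {
  stopifnot(inherits(spec, "network_spec"))
  total <- 0L
  c_in <- as.integer(in_channels)
  for (f in c(spec$blocks, spec$trailing)) {
    total <- total + spec$kernel * c_in * f + f
    c_in <- f
  }
  if (layer_norm) total <- total + sum(2L * spec$blocks)
  if (!is.null(spec$lstm_hidden)) {
    h <- spec$lstm_hidden
    total <- total + 4L * h * (c_in + h + 1L)
    c_in <- h
  }
  total + c_in * spec$n_classes + spec$n_classes
}
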