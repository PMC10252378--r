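test_that("CNN profiles carry the published filter stacks", {
  s <- build_cnn("srad", 3)
  expect_equal(s$blocks, c(8L, 32L, 64L, 128L))
  expect_equal(s$trailing, 8L)
  expect_equal(s$n_classes, 3L)
  expect_null(s$lstm_hidden)
  b <- build_cnn("bh", 2)
  expect_equal(b$blocks, c(128L, 64L, 32L))
  expect_null(b$trailing)
  expect_equal(b$n_classes, 2L)
  expect_error(build_cnn("phone", 2))
  expect_error(build_cnn("srad", 4), "n_classes")
})

test_that("hybrid profiles carry the published hidden sizes and dropout", {
  expect_equal(build_cnn_lstm("srad", 2)$lstm_hidden, 250L)
  expect_equal(build_cnn_lstm("srad", 2)$dropout, 0.4)
  expect_equal(build_cnn_lstm("e4l", 3)$lstm_hidden, 300L)
  expect_equal(build_cnn_lstm("e4l", 3)$dropout, 0.5)
  expect_equal(build_cnn_lstm("bh_e4lr", 2)$lstm_hidden, 200L)
  expect_equal(build_cnn_lstm("bh_e4lr", 2)$dropout, 0.5)
  expect_equal(build_cnn_lstm("e4r", 2)$lstm_hidden, 200L)
})

test_that("parameter count matches an independent per-layer hand sum", {
  # single conv block: 3*1*8 + 8 = 32 (plus its layer norm 2*8)
  one <- build_cnn("bh", 2)
  # hand sum for (bh, 2) with 4 input channels, written layer by layer
  conv <- function(k, cin, cout) k * cin * cout + cout
  hand <- conv(3, 4, 128) + conv(3, 128, 64) + conv(3, 64, 32) +
    2 * (128 + 64 + 32) +            # layer norms
    (32 * 2 + 2)                     # fully connected
  expect_equal(count_parameters(one, 4), hand)
  # (srad, 3) with 6 channels, including trailing conv
  srad <- build_cnn("srad", 3)
  hand2 <- conv(3, 6, 8) + conv(3, 8, 32) + conv(3, 32, 64) +
    conv(3, 64, 128) + conv(3, 128, 8) + 2 * (8 + 32 + 64 + 128) +
    (8 * 3 + 3)
  expect_equal(count_parameters(srad, 6), hand2)
  # hybrid adds 4*h*(c_in + h + 1)
  hy <- build_cnn_lstm("bh", 2, lstm_hidden = 10, dropout = 0.5)
  hand3 <- conv(3, 4, 128) + conv(3, 128, 64) + conv(3, 64, 32) +
    2 * (128 + 64 + 32) + 4 * 10 * (32 + 10 + 1) + (10 * 2 + 2)
  expect_equal(count_parameters(hy, 4), hand3)
})

test_that("causal convolutions preserve length for any input length", {
  spec <- build_cnn("bh", 2)
  layers <- drivestress:::build_layer_plan(spec, 2L)
  set.seed(1)
  par <- drivestress:::init_params(layers, spec$kernel)
  for (L in c(16L, 50L, 333L)) {
    X <- array(rnorm(2 * L * 2), dim = c(2, L, 2))
    fwd <- drivestress:::forward_net(layers, par, spec$kernel, X)
    for (i in seq_along(layers)) {
      if (layers[[i]]$type == "conv") {
        expect_equal(nrow(fwd$caches[[i]]$Zin), 2L * L)
      }
    }
    expect_equal(dim(fwd$logits), c(2L, 2L))
  }
})

test_that("causal padding uses only past samples", {
  # perturbing the final time step must not change any earlier conv output
  spec <- build_cnn("bh", 2)
  layers <- drivestress:::build_layer_plan(spec, 1L)[1]  # first conv only
  set.seed(2)
  par <- drivestress:::init_params(layers, spec$kernel)
  X1 <- array(rnorm(30), dim = c(1, 30, 1))
  X2 <- X1; X2[1, 30, 1] <- X2[1, 30, 1] + 5
  f1 <- drivestress:::forward_net(layers, par, spec$kernel, X1)
  f2 <- drivestress:::forward_net(layers, par, spec$kernel, X2)
  expect_equal(f1$logits[1:29, ], f2$logits[1:29, ])
  expect_false(isTRUE(all.equal(f1$logits[30, ], f2$logits[30, ])))
})

test_that("softmax outputs are a probability simplex per window", {
  segs <- make_segments(n_drives = 2, seed = 8)
  m <- train(build_cnn("srad", 2), segs,
             training_options(seed = 1, epochs = 1))
  P <- predict(m, segs, type = "prob")
  expect_true(all(P >= 0))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
})

test_that("training is deterministic under a fixed seed", {
  segs <- make_segments(n_drives = 2, seed = 8)
  opts <- training_options(seed = 13, epochs = 2)
  m1 <- train(build_cnn("srad", 2), segs, opts)
  m2 <- train(build_cnn("srad", 2), segs, opts)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
})

test_that("the CNN separates a well-separated synthetic cohort across seeds", {
  segs <- make_segments(n_drives = 3, seed = 42)
  expect_gte(nearest_centroid_acc(segs), 0.95)   # separability oracle
  for (s in c(1, 2, 3)) {
    m <- train(build_cnn("srad", 2), segs,
               training_options(seed = s, epochs = 6))
    expect_gte(validation_accuracy(m), 0.9)
  }
})

test_that("the hybrid CNN-LSTM trains and predicts on the same cohort", {
  segs <- make_segments(n_drives = 2, seed = 5)
  m <- train(build_cnn_lstm("srad", 2, lstm_hidden = 24), segs,
             training_options(seed = 11, epochs = 4, minibatch = 20))
  expect_gte(validation_accuracy(m), 0.85)
  expect_s3_class(predict(m, segs), "factor")
})

test_that("single-class data trains with a warning and predicts that class", {
  segs <- make_segments(n_drives = 2, seed = 8)
  only <- subset_segments(segs, segs$labels == "relaxed")
  expect_warning(
    m <- train(build_cnn("srad", 2), only,
               training_options(seed = 1, epochs = 1, minibatch = 10)),
    "classes")
  expect_true(all(predict(m, only) == "relaxed"))
})

test_that("training rejects a minibatch larger than the training split", {
  segs <- make_segments(n_drives = 2, seed = 8)
  expect_error(train(build_cnn("srad", 2), segs,
                     training_options(seed = 1, epochs = 1,
                                      minibatch = 10000)),
               "minibatch")
})

test_that("prediction is pure and validates input shape", {
  segs <- make_segments(n_drives = 2, seed = 8)
  m <- train(build_cnn("srad", 2), segs, training_options(seed = 1, epochs = 2))
  one <- subset_segments(segs, rep(1L, 5))
  expect_equal(length(unique(predict(m, one))), 1L)
  empty <- subset_segments(segs, integer(0))
  expect_equal(length(predict(m, empty)), 0L)
  bad <- segment_set(array(0, c(2, dim(segs$x)[2], 9)),
                     rep("relaxed", 2), 10, 0.5, 8, "two")
  expect_error(predict(m, bad), "mismatch")
})

test_that("held-out predictions reproduce the recorded validation accuracy", {
  segs <- make_segments(n_drives = 2, seed = 8)
  m <- train(build_cnn("srad", 2), segs, training_options(seed = 4, epochs = 3))
  val <- subset_segments(segs, m$val_idx)
  cm <- confusion_matrix(val$labels, predict(m, val), classes = m$classes)
  expect_equal(overall_accuracy(cm), validation_accuracy(m), tolerance = 1e-12)
})

test_that("relabelling classes permutes the confusion matrix accordingly", {
  # low-noise cohort so both runs solve the task exactly; the permutation
  # property is only exact when the two fits classify the probe identically
  segs <- make_segments(n_drives = 3, seed = 42, noise_scale = 0.5)
  flipped <- segment_set(segs$x,
                         ifelse(segs$labels == "relaxed", "stressed", "relaxed"),
                         segs$window_s, segs$overlap, segs$fs, "two",
                         segs$channels)
  opts <- training_options(seed = 2, epochs = 8)
  m1 <- train(build_cnn("srad", 2), segs, opts)
  m2 <- train(build_cnn("srad", 2), flipped, opts)
  probe <- subset_segments(segs, seq_len(min(60, n_windows(segs))))
  p1 <- predict(m1, probe)
  p2 <- predict(m2, subset_segments(flipped, seq_len(n_windows(probe))))
  # both runs solve the task, so predictions agree up to the relabelling
  # and the confusion matrices are permutations of each other
  cm1 <- confusion_matrix(probe$labels, p1, classes = c("relaxed", "stressed"))
  cm2 <- confusion_matrix(
    factor(ifelse(probe$labels == "relaxed", "stressed", "relaxed"),
           levels = c("relaxed", "stressed")),
    p2, classes = c("relaxed", "stressed"))
  expect_equal(unclass(cm1), unclass(cm2)[2:1, 2:1], ignore_attr = TRUE)
})

test_that("model checkpoints survive a JSON round trip", {
  segs <- make_segments(n_drives = 2, seed = 8)
  m <- train(build_cnn("srad", 2), segs, training_options(seed = 1, epochs = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict(m2, segs), predict(m, segs))
  expect_equal(m2$history$val_acc, m$history$val_acc)
})
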