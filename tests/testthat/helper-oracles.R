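# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# power of x in a narrow band around f (FFT oracle, independent of the
# filtering code under test)
band_power <- function(x, fs, f, bw = 0.1) {
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) * fs / length(x)
  sum(sp[fr >= f - bw & fr <= f + bw])
}

rms <- function(x) sqrt(mean(x^2))

# attenuation (dB) of band f relative to reference band f_ref, before vs
# after processing; insensitive to overall rescaling (min-max etc.)
rel_band_change_db <- function(before, after, fs, f, f_ref) {
  r0 <- band_power(before, fs, f) / band_power(before, fs, f_ref)
  r1 <- band_power(after, fs, f) / band_power(after, fs, f_ref)
  10 * log10(r1 / r0)
}

# nearest-centroid classifier on per-window channel means: the
# separability oracle for the synthetic cohorts
nearest_centroid_acc <- function(segs) {
  X <- t(apply(segs$x, 1, colMeans))
  y <- segs$labels
  cent <- sapply(levels(y), function(l) colMeans(X[y == l, , drop = FALSE]))
  pred <- levels(y)[apply(X, 1, function(r) which.min(colSums((cent - r)^2)))]
  mean(pred == y)
}

# compact three-channel montage (heart rate, skin conductance,
# respiration) used wherever a full montage would only cost time
small_montage <- function(noise_scale = 1) {
  default_channel_models("srad", noise_scale = noise_scale)[
    c("hr", "foot_gsr", "resp")]
}

# desk-scale protocol shared across tests
desk_protocol <- function() drive_protocol(scale = 0.1)

# cleaned, pooled windows from a small synthetic cohort
make_segments <- function(n_drives = 3, seed = 42, scheme = "two",
                          noise_scale = 1, window_s = 10, overlap = 0.5) {
  coh <- generate_cohort(n_drives, desk_protocol(),
                         small_montage(noise_scale), seed = seed,
                         label_scheme = scheme)
  suppressWarnings(bind_segments(lapply(coh, function(r)
    segment_record(clean_recording(r), window_s, overlap, common_fs = 8))))
}

# step-by-step scalar-loop recomputation of the whole ranking chain,
# written deliberately without matrix code so it is independent of the
# package's vectorised implementation
edas_loop_oracle <- function(X, w, beneficial = rep(TRUE, ncol(X))) {
  n <- nrow(X); m <- ncol(X)
  psi <- numeric(m)
  for (b in seq_len(m)) {
    s <- 0
    for (a in seq_len(n)) s <- s + X[a, b]
    psi[b] <- s / n
  }
  PI <- matrix(0, n, m); NI <- matrix(0, n, m)
  for (a in seq_len(n)) for (b in seq_len(m)) {
    below <- max(0, psi[b] - X[a, b]) / psi[b]
    above <- max(0, X[a, b] - psi[b]) / psi[b]
    if (beneficial[b]) { PI[a, b] <- below; NI[a, b] <- above }
    else { PI[a, b] <- above; NI[a, b] <- below }
  }
  SPI <- numeric(n); SNI <- numeric(n)
  for (a in seq_len(n)) for (b in seq_len(m)) {
    SPI[a] <- SPI[a] + w[b] * PI[a, b]
    SNI[a] <- SNI[a] + w[b] * NI[a, b]
  }
  mx_p <- max(SPI); mx_n <- max(SNI)
  NSPI <- if (mx_p == 0) rep(0, n) else SPI / mx_p
  NSNI <- if (mx_n == 0) rep(1, n) else 1 - SNI / mx_n
  lam <- (NSPI + NSNI) / 2
  list(psi = psi, PI = PI, NI = NI, SPI = SPI, SNI = SNI,
       NSPI = NSPI, NSNI = NSNI, lambda = lam)
}

# per-instance counting oracle for one-vs-rest metrics
metrics_count_oracle <- function(truth, pred, cls) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(truth)) {
    is_t <- truth[i] == cls; is_p <- pred[i] == cls
    if (is_t && is_p) tp <- tp + 1L
    else if (is_t && !is_p) fn <- fn + 1L
    else if (!is_t && is_p) fp <- fp + 1L
    else tn <- tn + 1L
  }
  n <- tp + fn + fp + tn
  c(acc = (tp + tn) / n, rcl = tp / (tp + fn), prc = tp / (tp + fp),
    spc = tn / (tn + fp))
}

# the six published relaxed-state convolutional-model metric rows used in
# the ranking worked example
relaxed_cnn_matrix <- function() {
  read_decision_matrix(example_decision_matrix("cnn_two_class_relaxed"))
}

stressed_cnn_matrix <- function() {
  read_decision_matrix(example_decision_matrix("cnn_two_class_stressed"))
}

# absolute-tolerance comparison for values printed at 4 decimals (the
# default testthat tolerance is relative, which is meaningless for
# 1e-3-scale distance cells)
expect_abs_equal <- function(object, expected, tol = 1.5e-4) {
  expect_lt(max(abs(object - expected)), tol)
}
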