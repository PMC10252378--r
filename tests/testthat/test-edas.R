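# The worked-example expectations below are the published step-by-step
# tables of the two-class convolutional comparison; only cells that are
# internally consistent with the stated formulas are asserted (the source
# tables contain a handful of transcription inconsistencies, documented in
# the vignette).

test_that("the average solution reproduces the published column means", {
  dm <- relaxed_cnn_matrix()
  expect_abs_equal(unname(average_solution(dm$X)),
                   c(0.9076, 0.9051, 0.8886, 0.8947, 0.9130))
  expect_equal(average_solution(matrix(2.5, 3, 4)), rep(2.5, 4))
  expect_error(average_solution(matrix(numeric(0), 0, 0)), "empty")
})

test_that("column means match a loop-summed oracle on random matrices", {
  set.seed(7)
  X <- matrix(runif(12), 4, 3)
  expect_equal(unname(average_solution(X)), edas_loop_oracle(X, rep(1, 3))$psi,
               tolerance = 1e-12)
})

test_that("distance matrices reproduce the published shortfall/surplus cells", {
  dm <- relaxed_cnn_matrix()
  d <- distance_matrices(dm$X, average_solution(dm$X), dm$beneficial)
  # positive distance: recall shortfall of the in-car montage
  expect_abs_equal(d$PI["SRAD", "RCL"], 0.0306)
  expect_abs_equal(d$PI["SRAD", "F1"], 0.0006)
  expect_abs_equal(unname(d$PI["BH", ]),
                   c(0.0184, 0, 0.0696, 0.0228, 0.0522))
  # negative distance: recall surplus of the fused chest+wrist model
  expect_abs_equal(d$NI["BH+E4-(L+R)", "RCL"], 0.0796)
  expect_abs_equal(unname(d$NI["BH+E4-(L+R)", c("ACC", "F1", "SPC")]),
                   c(0.0537, 0.0607, 0.0314))
  # X equal to the average gives all-zero distances
  Xc <- matrix(rep(average_solution(dm$X), each = 4), 4, 5)
  dc <- distance_matrices(Xc, average_solution(Xc), rep(TRUE, 5))
  expect_equal(max(abs(dc$PI)), 0)
  expect_equal(max(abs(dc$NI)), 0)
  expect_error(distance_matrices(matrix(0, 2, 2), c(0, 1), c(TRUE, TRUE)),
               "zero")
})

test_that("weighted sums reproduce the published consistent aggregate cells", {
  dm <- relaxed_cnn_matrix()
  d <- distance_matrices(dm$X, average_solution(dm$X), dm$beneficial)
  s <- weighted_sums(d$PI, d$NI, dm$weights)
  names(s$SPI) <- names(s$SNI) <- rownames(dm$X)
  expect_abs_equal(s$SPI[["SRAD"]], 0.0088)
  expect_abs_equal(s$SPI[["BH"]], 0.0233)
  expect_abs_equal(s$SPI[["E4-(L+R)"]], 0.0066)
  expect_abs_equal(unname(s$SNI),
                   c(0.0158, 0.0071, 0.0100, 0.0000, 0.0321, 0.0579))
  zero <- weighted_sums(matrix(0, 2, 3), matrix(0, 2, 3), c(0.2, 0.3, 0.5))
  expect_equal(zero$SPI, c(0, 0))
  expect_error(weighted_sums(d$PI, d$NI, c(1, 2)), "length")
})

test_that("normalised sums follow the zero-max convention", {
  dm <- relaxed_cnn_matrix()
  res <- run_edas(dm)
  expect_equal(res$NSNI[["SRAD"]], 0.7270, tolerance = 1.5e-4)
  expect_equal(res$NSPI[[which.max(res$SPI)]], 1)
  ns <- normalize_sums(c(0, 0, 0), c(0, 0, 0))
  expect_equal(ns$NSPI, c(0, 0, 0))
  expect_equal(ns$NSNI, c(1, 1, 1))
})

test_that("appraisal scores bound and combine the normalised sums", {
  expect_equal(appraisal(0, 0), 0)
  expect_equal(appraisal(1, 1), 1)
  dm <- relaxed_cnn_matrix()
  res <- run_edas(dm)
  oracle <- edas_loop_oracle(dm$X, dm$weights)
  expect_equal(unname(res$lambda), oracle$lambda, tolerance = 1e-12)
  expect_equal(res$lambda[["SRAD"]],
               (res$SPI[["SRAD"]] / max(res$SPI) + res$NSNI[["SRAD"]]) / 2)
})

test_that("dense ranks break ties within tolerance", {
  expect_equal(edas_ranks(c(0.3, 0.1, 0.2)), c(3L, 1L, 2L))
  expect_equal(edas_ranks(c(0.5, 0.5, 0.9), tol = 1e-4), c(1L, 1L, 2L))
  expect_equal(edas_ranks(c(0.10003, 0.10001, 0.4)), c(1L, 1L, 2L))
})

test_that("the full chain ranks the fused model first in both class states", {
  relaxed <- run_edas(relaxed_cnn_matrix())
  expect_equal(names(relaxed$ranks)[relaxed$ranks == 1L], "BH+E4-(L+R)")
  stressed <- run_edas(stressed_cnn_matrix())
  expect_equal(round(stressed$SNI[["BH+E4-(L+R)"]], 4), 0.0505)
  expect_equal(unname(which.max(stressed$SNI)), 6L)
  expect_equal(names(stressed$ranks)[stressed$ranks == 1L], "BH+E4-(L+R)")
})

test_that("a single-alternative matrix gets rank 1 under the zero-max convention", {
  dm <- suppressWarnings(decision_matrix(matrix(c(0.9, 0.8), 1, 2),
                                         weights = c(0.5, 0.5)))
  res <- run_edas(dm)
  expect_equal(max(abs(res$PI)), 0)
  expect_equal(max(abs(res$NI)), 0)
  expect_equal(unname(res$ranks), 1L)
  expect_equal(unname(res$lambda), 0.5)  # NSPI 0, NSNI 1
})

test_that("every intermediate matches the loop oracle on random matrices", {
  set.seed(17)
  for (i in 1:10) {
    X <- matrix(runif(20, 0.2, 1), 5, 4)
    w <- runif(4); w <- w / sum(w)
    benef <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    res <- run_edas(decision_matrix(X, w, benef))
    want <- edas_loop_oracle(X, w, benef)
    expect_equal(unname(res$psi), want$psi, tolerance = 1e-10)
    expect_equal(unname(res$PI), want$PI, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(unname(res$NI), want$NI, ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(unname(res$SPI), want$SPI, tolerance = 1e-10)
    expect_equal(unname(res$SNI), want$SNI, tolerance = 1e-10)
    expect_equal(unname(res$lambda), want$lambda, tolerance = 1e-10)
  }
})

test_that("rescaling a criterion column leaves the whole chain unchanged", {
  set.seed(23)
  X <- matrix(runif(15, 0.1, 1), 5, 3)
  w <- c(0.5, 0.3, 0.2)
  base <- run_edas(decision_matrix(X, w))
  for (c_ in c(0.01, 3, 1000)) {
    X2 <- X; X2[, 2] <- X2[, 2] * c_
    scaled <- run_edas(decision_matrix(X2, w))
    expect_equal(unname(scaled$PI), unname(base$PI), tolerance = 1e-9)
    expect_equal(unname(scaled$NI), unname(base$NI), tolerance = 1e-9)
    expect_equal(unname(scaled$lambda), unname(base$lambda), tolerance = 1e-9)
    expect_equal(scaled$ranks, base$ranks)
  }
})

test_that("positive and negative distances are never jointly nonzero", {
  set.seed(29)
  for (i in 1:15) {
    X <- matrix(runif(24, 0.1, 2), 6, 4)
    benef <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    res <- run_edas(decision_matrix(X, rep(0.25, 4), benef))
    expect_equal(max(abs(res$PI * res$NI)), 0)
    expect_true(all(res$PI >= 0) && all(res$NI >= 0))
    expect_true(all(res$lambda >= 0 & res$lambda <= 1))
  }
})

test_that("a dominating alternative has zero shortfall and rank 1", {
  set.seed(31)
  X <- matrix(runif(20, 0.2, 0.8), 5, 4)
  X[3, ] <- apply(X, 2, max) + c(0.1, 0, 0, 0)  # weakly best, strictly on C1
  res <- run_edas(decision_matrix(X, rep(0.25, 4)))
  expect_equal(unname(res$SPI[3]), 0)
  expect_equal(unname(res$ranks[3]), 1L)
})

test_that("duplicating an alternative never reorders the originals", {
  set.seed(37)
  X <- matrix(runif(20, 0.2, 1), 5, 4)
  w <- rep(0.25, 4)
  base <- run_edas(decision_matrix(X, w))
  dup <- run_edas(decision_matrix(rbind(X, X[2, ]), w))
  ord_base <- order(base$lambda[1:5])
  ord_dup <- order(dup$lambda[1:5])
  expect_equal(ord_base, ord_dup)
})

test_that("decision matrices validate weights and shape", {
  expect_warning(decision_matrix(matrix(1, 2, 2), weights = c(0.9, 0.3)),
                 "sum")
  expect_error(decision_matrix(matrix(1, 2, 2), weights = c(1)), "weight")
  expect_error(decision_matrix(matrix(1, 2, 2), weights = c(-0.5, 1.5)),
               "positive")
  expect_equal(sum(edas_default_weights()), 0.9999)
  expect_equal(sum(edas_default_weights(renormalize = TRUE)), 1)
})
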