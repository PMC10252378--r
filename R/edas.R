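#' Default criterion weights for the five classification metrics
#'
#' Weights attached to the (ACC, RCL, PRC, F1, SPC) criteria when ranking
#' competing classifiers. They sum to 0.99993; pass `renormalize = TRUE` to
#' rescale them to exactly 1.
#'
#' @param renormalize Rescale to sum exactly 1?
#' @return Named numeric vector of length 5.
#' @export
edas_default_weights <- function(renormalize = FALSE) {
  w <- c(ACC = 0.4176, RCL = 0.2850, PRC = 0.1453, F1 = 0.0844, SPC = 0.0676)
  if (renormalize) w <- w / sum(w)
  w
}

#' Construct a decision matrix
#'
#' Alternatives-by-criteria value matrix with positive criterion weights and
#' benefit/cost flags, the input to [run_edas()].
#'
#' @param X Numeric matrix, rows = alternatives, columns = criteria.
#' @param weights Positive weights, one per criterion. Warns if they do not
#'   sum to 1 within 1e-3.
#' @param beneficial Logical flags, one per criterion (`TRUE` = larger is
#'   better). Default all beneficial.
#' @param names Alternative labels (default from rownames).
#' @param criteria Criterion labels (default from colnames).
#' @return An object of class `decision_matrix`.
#' @export
decision_matrix <- function(X, weights, beneficial = NULL, names = NULL,
                            criteria = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 1L || ncol(X) < 1L) stopf("decision matrix must be non-empty")
  if (length(weights) != ncol(X)) stopf("one weight per criterion required")
  if (any(weights <= 0)) stopf("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-3) {
    warnf("criterion weights sum to %.5f, not 1", sum(weights))
  }
  beneficial <- beneficial %||% rep(TRUE, ncol(X))
  stopifnot(length(beneficial) == ncol(X), is.logical(beneficial))
  rownames(X) <- names %||% rownames(X) %||% paste0("A", seq_len(nrow(X)))
  colnames(X) <- criteria %||% colnames(X) %||% paste0("C", seq_len(ncol(X)))
  structure(list(X = X, weights = unname(weights), beneficial = beneficial),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf("<decision_matrix> %d alternative(s) x %d criteria\n",
              nrow(x$X), ncol(x$X)))
  print(round(x$X, 4))
  cat("weights:   ", paste(format(x$weights), collapse = " "), "\n")
  cat("beneficial:", paste(ifelse(x$beneficial, "+", "-"), collapse = " "), "\n")
  invisible(x)
}

#' Average solution (column means) of a decision matrix
#'
#' Step 1 of the ranking procedure: the per-criterion average over all
#' alternatives.
#'
#' @param X Numeric matrix (alternatives x criteria).
#' @return Numeric vector of column means.
#' @export
average_solution <- function(X) {
  X <- as.matrix(X)
  if (length(X) == 0L) stopf("empty decision matrix")
  colMeans(X)
}

#' Positive and negative distances from the average solution
#'
#' Steps 2-3. For a beneficial criterion the positive distance is the
#' relative shortfall below the column average,
#' `PI = max(0, psi - x) / psi`, and the negative distance is the relative
#' surplus above it, `NI = max(0, x - psi) / psi`; a non-beneficial
#' criterion swaps the two. (This orientation measures shortfall as the
#' penalised distance; combined with the lowest-score-wins ranking of
#' [edas_ranks()], the best alternative still comes first.) Exactly one of
#' the pair is nonzero in every cell.
#'
#' @param X Numeric matrix (alternatives x criteria).
#' @param psi Column averages, as from [average_solution()]; all nonzero.
#' @param beneficial Logical flags per criterion.
#' @return List with matrices `PI` and `NI`.
#' @export
distance_matrices <- function(X, psi = average_solution(X),
                              beneficial = rep(TRUE, ncol(X))) {
  X <- as.matrix(X)
  stopifnot(length(psi) == ncol(X), length(beneficial) == ncol(X))
  if (any(psi == 0)) stopf("average solution contains a zero; distances undefined")
  below <- sweep(pmax(sweep(X, 2, psi, function(x, p) p - x), 0), 2, psi, "/")
  above <- sweep(pmax(sweep(X, 2, psi, "-"), 0), 2, psi, "/")
  PI <- below; NI <- above
  if (any(!beneficial)) {
    PI[, !beneficial] <- above[, !beneficial]
    NI[, !beneficial] <- below[, !beneficial]
  }
  list(PI = PI, NI = NI)
}

#' Weighted distance sums per alternative
#'
#' Steps 4-5: `SPI = PI %*% w`, `SNI = NI %*% w`.
#'
#' @param PI,NI Distance matrices from [distance_matrices()].
#' @param weights Criterion weights.
#' @return List with vectors `SPI` and `SNI`.
#' @export
weighted_sums <- function(PI, NI, weights) {
  if (length(weights) != ncol(PI) || length(weights) != ncol(NI)) {
    stopf("weight length (%d) does not match criteria count", length(weights))
  }
  list(SPI = as.numeric(PI %*% weights), SNI = as.numeric(NI %*% weights))
}

#' Normalised weighted sums
#'
#' Step 6: `NSPI = SPI / max(SPI)` and `NSNI = 1 - SNI / max(SNI)`. When a
#' maximum is zero the ratio is defined as 0, so an all-zero SPI vector
#' yields all-zero NSPI and an all-zero SNI vector yields all-one NSNI.
#'
#' @param SPI,SNI Vectors from [weighted_sums()].
#' @return List with vectors `NSPI` and `NSNI`.
#' @export
normalize_sums <- function(SPI, SNI) {
  ratio0 <- function(v) {
    m <- max(v)
    if (m == 0) rep(0, length(v)) else v / m
  }
  list(NSPI = ratio0(SPI), NSNI = 1 - ratio0(SNI))
}

#' Appraisal score
#'
#' Step 7: the mean of the two normalised sums,
#' `lambda = (NSPI + NSNI) / 2`, which lies in `[0, 1]`.
#'
#' @param NSPI,NSNI Vectors from [normalize_sums()].
#' @return Numeric vector of appraisal scores.
#' @export
appraisal <- function(NSPI, NSNI) {
  stopifnot(length(NSPI) == length(NSNI))
  (NSPI + NSNI) / 2
}

#' Dense ranks of appraisal scores (lowest score = rank 1)
#'
#' Step 8: the alternative with the lowest appraisal score performs best.
#' Scores within `tol` of each other share a rank (dense ranking: the next
#' distinct score takes the next integer).
#'
#' @param lam Appraisal scores.
#' @param tol Tie tolerance (default `5e-5`, half a unit in the fourth
#'   decimal place).
#' @return Integer vector of ranks.
#' @examples
#' edas_ranks(c(0.3, 0.1, 0.2))             # 3 1 2
#' edas_ranks(c(0.5, 0.5, 0.9), tol = 1e-4) # 1 1 2
#' @export
edas_ranks <- function(lam, tol = 5e-5) {
  o <- order(lam)
  ranks <- integer(length(lam))
  r <- 0L
  prev <- -Inf
  for (i in o) {
    if (lam[i] - prev > tol) {
      r <- r + 1L
      prev <- lam[i]
    }
    ranks[i] <- r
  }
  ranks
}

#' Run the full eight-step distance-from-average ranking
#'
#' Composes [average_solution()], [distance_matrices()], [weighted_sums()],
#' [normalize_sums()], [appraisal()] and [edas_ranks()] and keeps every
#' intermediate for audit.
#'
#' @param dm A [decision_matrix()].
#' @param tie_tol Tie tolerance passed to [edas_ranks()].
#' @return An object of class `edas_result`: list with `psi`, `PI`, `NI`,
#'   `SPI`, `SNI`, `NSPI`, `NSNI`, `lambda`, `ranks` and the input `dm`.
#' @examples
#' dm <- decision_matrix(rbind(a = c(0.9, 0.8), b = c(0.7, 0.95)),
#'                       weights = c(0.6, 0.4))
#' run_edas(dm)$ranks
#' @export
run_edas <- function(dm, tie_tol = 5e-5) {
  stopifnot(inherits(dm, "decision_matrix"))
  psi <- average_solution(dm$X)
  d <- distance_matrices(dm$X, psi, dm$beneficial)
  s <- weighted_sums(d$PI, d$NI, dm$weights)
  ns <- normalize_sums(s$SPI, s$SNI)
  lam <- appraisal(ns$NSPI, ns$NSNI)
  nm <- rownames(dm$X)
  named <- function(v) stats::setNames(v, nm)
  structure(list(psi = psi, PI = d$PI, NI = d$NI,
                 SPI = named(s$SPI), SNI = named(s$SNI),
                 NSPI = named(ns$NSPI), NSNI = named(ns$NSNI),
                 lambda = named(lam),
                 ranks = named(edas_ranks(lam, tie_tol)),
                 dm = dm),
            class = "edas_result")
}

#' @export
print.edas_result <- function(x, digits = 4, ...) {
  cat("<edas_result>\n")
  tab <- cbind(SPI = x$SPI, SNI = x$SNI, NSPI = x$NSPI, NSNI = x$NSNI,
               lambda = x$lambda, rank = x$ranks)
  print(round(tab, digits))
  invisible(x)
}

#' Summarise an EDAS run as a data frame
#' @param object An `edas_result`.
#' @param ... Unused.
#' @return Data frame mirroring the final analysis table: one row per
#'   alternative with SPI, SNI, NSPI, NSNI, appraisal score and rank.
#' @export
summary.edas_result <- function(object, ...) {
  data.frame(alternative = names(object$SPI),
             SPI = unname(object$SPI), SNI = unname(object$SNI),
             NSPI = unname(object$NSPI), NSNI = unname(object$NSNI),
             lambda = unname(object$lambda), rank = unname(object$ranks),
             row.names = NULL, stringsAsFactors = FALSE)
}
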