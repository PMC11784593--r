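#' Row-structured matrix norms
#'
#' `linf1Norm` is the l-infinity,1 norm: the sum over rows of the largest
#' absolute entry per row. Penalizing it selects whole SNP rows jointly
#' across tasks — a row survives only if it is worth a nonzero budget in at
#' least one task. `l21Norm` is the classical group-sparse l2,1 norm, the
#' sum of row Euclidean norms, used by the comparison methods.
#'
#' @param x numeric matrix.
#' @return scalar norm value.
#' @examples
#' linf1Norm(rbind(c(3, -4), c(1, 0.5)))  # 4 + 1 = 5
#' l21Norm(rbind(c(3, 4), c(0, 0)))       # 5
#' @export
linf1Norm <- function(x) {
  x <- abs(as.matrix(x))
  if (!all(is.finite(x))) stop("non-finite entries")
  sum(do.call(pmax, c(asplit(x, 2L), list(0))))
}

#' @rdname linf1Norm
#' @export
l21Norm <- function(x) {
  x <- as.matrix(x)
  sum(sqrt(rowSums(x^2)))
}

## fast row statistics used throughout the solver
.rowMaxAbs <- function(x) {
  x <- abs(x)
  out <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) out <- pmax.int(out, x[, j])
  out
}
.rowL2 <- function(x) sqrt(rowSums(x^2))

#' Reweighting diagonal for the row-sparsity penalties
#'
#' The alternating solver replaces each row-structured penalty by a
#' quadratic form with diagonal weights refreshed from the current iterate:
#' entry i is 1 / (2 max(r_i, delta)), where r_i is the row's max-abs entry
#' (l-infinity,1 penalty) or its Euclidean norm (l2,1 penalty). The floor
#' `delta` keeps weights finite on rows that have shrunk to zero.
#'
#' @param P numeric matrix whose rows are being penalized.
#' @param delta positive smoothing floor (default 1e-8).
#' @param norm `"linf"` (row max) or `"l2"` (row Euclidean norm).
#' @return numeric vector of strictly positive diagonal entries.
#' @export
reweightDiag <- function(P, delta = 1e-8, norm = c("linf", "l2")) {
  norm <- match.arg(norm)
  if (delta <= 0) stop("'delta' must be positive")
  r <- if (norm == "linf") .rowMaxAbs(P) else .rowL2(P)
  1 / (2 * pmax.int(r, delta))
}
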