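#' Column-standardize a matrix
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n-1 denominator). Marginal GWAS effect sizes and the
#' reference-panel LD matrix are defined on this scale, so every genotype
#' and QT matrix entering the solver passes through here first.
#'
#' @param x numeric matrix with at least 2 rows.
#' @param center,scale logical.
#' @param dropConstant drop zero-variance columns (with a warning) instead
#'   of failing.
#' @param means,scales optional pre-computed statistics (e.g. from a
#'   training fold) to apply instead of estimating from `x`.
#'
#' @return list with `x` (transformed matrix), `means`, `scales`, and
#'   `kept` (column indices retained).
#' @examples
#' s <- standardizeColumns(cbind(a = c(2, 4, 6)))
#' s$x  # -1, 0, 1
#' @export
standardizeColumns <- function(x, center = TRUE, scale = TRUE,
                               dropConstant = FALSE,
                               means = NULL, scales = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  estimated <- is.null(means)
  if (estimated) {
    means <- if (center) colMeans(x) else rep(0, ncol(x))
    scales <- if (scale) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  }
  kept <- seq_len(ncol(x))
  zero <- which(scales <= 0 | !is.finite(scales))
  if (length(zero) && estimated) {
    nm <- colnames(x)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    if (!dropConstant)
      stop("zero-variance column(s): ", paste(nm, collapse = ", "),
           " (set dropConstant = TRUE to drop)")
    warning("dropping zero-variance column(s): ", paste(nm, collapse = ", "))
    kept <- setdiff(kept, zero)
    x <- x[, kept, drop = FALSE]
    means <- means[kept]; scales <- scales[kept]
  }
  out <- sweep(x, 2L, means, "-")
  out <- sweep(out, 2L, scales, "/")
  list(x = out, means = means, scales = scales, kept = kept)
}

#' Invert a column standardization
#'
#' @param x standardized matrix.
#' @param means,scales the statistics returned by [standardizeColumns()].
#' @return matrix on the original scale.
#' @export
unstandardizeColumns <- function(x, means, scales) {
  sweep(sweep(as.matrix(x), 2L, scales, "*"), 2L, means, "+")
}

#' Regress nuisance covariates out of QT columns
#'
#' Replaces each quantitative-trait column by the residuals of an ordinary
#' least-squares fit on the named covariates plus an intercept. Used to
#' remove influences such as gender, education and handedness from imaging
#' QTs before any genetic modeling, so those demographic effects cannot
#' masquerade as genetic signal.
#'
#' @param qts data.frame or matrix of QT values (rows = observations).
#' @param covariates data.frame aligned with `qts` rows.
#' @param names character, covariate columns to remove. Factors/characters
#'   are expanded to dummies via the usual model matrix.
#'
#' @return object of the same shape as `qts` holding residuals; residuals
#'   are orthogonal to every covariate column.
#' @export
residualizeCovariates <- function(qts, covariates, names) {
  qtm <- as.matrix(qts)
  if (!all(names %in% colnames(covariates)))
    stop("missing covariate column(s): ",
         paste(setdiff(names, colnames(covariates)), collapse = ", "))
  if (nrow(covariates) != nrow(qtm))
    stop("covariates must be aligned with the QT rows")
  mm <- if (length(names)) {
    stats::model.matrix(
      stats::reformulate(names),
      data = as.data.frame(covariates)[, names, drop = FALSE])
  } else {
    matrix(1, nrow(qtm), 1L)  # intercept only: residuals = centered QTs
  }
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient covariate matrix")
  fit <- stats::lm.fit(mm, qtm)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(qtm)
  if (is.data.frame(qts)) as.data.frame(res) else res
}
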