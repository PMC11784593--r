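## Comparison methods fitted under the same data model and solver core:
##   smtr  - per-timepoint sparse multi-task regression (no trajectory model)
##   smml  - one-stage mixed-effects longitudinal model, l2,1 penalties
##   msmml - the multi-stage model without the GWAS collaboration term

.commonSubjects <- function(data) {
  Reduce(intersect, lapply(data@stages, function(st) st@subjectIds))
}

## One-stage pooled view: subjects present in every stage, observed at the
## absolute times of all (stage, visit) pairs. Duplicated absolute times
## (stage windows sharing a boundary visit) stay as separate observations.
.pooledView <- function(data, standardize = TRUE, qtStats = NULL,
                        genoStats = NULL) {
  ids <- .commonSubjects(data)
  if (length(ids) < 2L)
    stop("the one-stage view needs at least 2 subjects present in every stage")
  st1 <- data@stages[[1L]]
  X <- st1@genotype[match(ids, st1@subjectIds), , drop = FALSE]
  Z <- list(); tt <- numeric(0); layout <- NULL
  for (s in seq_along(data@stages)) {
    st <- data@stages[[s]]
    pos <- match(ids, st@subjectIds)
    for (k in seq_along(st@times)) {
      zk <- st@qts[k, pos, , drop = FALSE]
      dim(zk) <- c(length(ids), length(st@qtNames))
      Z[[length(Z) + 1L]] <- zk
      tt <- c(tt, st@timeOffset + st@times[k])
      layout <- rbind(layout, data.frame(stage = s, visit = k))
    }
  }
  if (standardize) {
    if (is.null(qtStats)) {
      all <- do.call(rbind, Z)
      qtStats <- list(means = colMeans(all), scales = apply(all, 2L, stats::sd))
    }
    Z <- lapply(Z, function(zk)
      sweep(sweep(zk, 2L, qtStats$means, "-"), 2L, qtStats$scales, "/"))
    gs <- .genoStandardize(X, genoStats)
    X <- gs$x; genoStats <- gs$stats
  }
  tt <- tt - tt[1L]
  ZS <- Reduce(`+`, Z)
  ZT <- Reduce(`+`, Map(`*`, Z, tt))
  stage <- list(X = X, Z = Z, t = tt, m = length(tt),
                stm = sum(tt), st2 = sum(tt^2),
                idx = seq_along(ids), XtX = crossprod(X),
                SZ = crossprod(X, ZS), TZ = crossprod(X, ZT),
                ZS = ZS, ZT = ZT)
  list(registry = ids, L = 1L, d = ncol(X), cc = ncol(Z[[1L]]),
       qtStats = qtStats, genoStats = list(genoStats),
       snpIds = st1@snpIds, qtNames = st1@qtNames,
       stageSubjects = list(ids), stages = list(stage), layout = layout)
}

#' Fit the one-stage mixed-effects longitudinal baseline
#'
#' Models the whole trajectory with a single stage: per pooled visit k,
#' \eqn{Z_k = A + X W + (B + X V) t_k + E}, with subject aging effects A, B
#' and genetic effects W (intercept) and V (slope) under l2,1 (row
#' Euclidean norm) penalties `lambda1`, `lambda2`. A multi-stage dataset is
#' pooled to the subjects present in every stage, observed at the absolute
#' visit times of all stages; a one-stage dataset is used as is.
#'
#' @param data a [LongitudinalDataset-class].
#' @param lambda1,lambda2 nonnegative l2,1 penalty weights on W and V.
#' @param maxIter,tol,delta,standardize,bootstrap as in [fitMSColoR()].
#' @return A [BaselineFit-class] with method `"smml"`.
#' @export
fitSMML <- function(data, lambda1 = 1, lambda2 = 1, maxIter = 200L,
                    tol = 1e-5, delta = 1e-8, standardize = TRUE,
                    bootstrap = TRUE) {
  stopifnot(is(data, "LongitudinalDataset"))
  prep <- .pooledView(data, standardize)
  hyper <- .makeHyper(gG = 1, gA = 1, lambdaP = lambda1, lambdaQ = lambda2,
                      tau = 0, delta = delta, ridge = 0, penalty = "l2")
  res <- .mscolorEngine(prep, hyper, share = FALSE,
                        maxIter = as.integer(maxIter), tol = tol,
                        bootstrap = bootstrap)
  new("BaselineFit", method = "smml",
      params = list(A = res$par$Astage[[1L]], B = res$par$Bstage[[1L]],
                    W = res$par$W[[1L]], V = res$par$V[[1L]]),
      objectiveTrace = res$objectiveTrace,
      surrogateTrace = res$surrogateTrace,
      converged = res$converged, nIter = res$nIter,
      subjectRegistry = prep$registry,
      snpIds = prep$snpIds, qtNames = prep$qtNames,
      prepared = list(prep = prep, hyper = hyper),
      control = list(lambda1 = lambda1, lambda2 = lambda2,
                     maxIter = maxIter, tol = tol, delta = delta,
                     standardize = standardize))
}

#' Fit the multi-stage baseline without GWAS collaboration
#'
#' The multi-stage mixed-effects model with per-stage aging effects and
#' l-infinity,1 penalties on the genetic blocks, but no summary-statistic
#' term: the control that isolates the contribution of the GWAS
#' collaboration. Identical to [fitMSColoR()] with `tau = 0` and
#' per-stage aging.
#'
#' @param data a [LongitudinalDataset-class].
#' @param lambda1,lambda2 nonnegative penalty weights on the intercept and
#'   slope blocks.
#' @param gamma genetic-versus-aging weight in \[0, 1\].
#' @inheritParams fitSMML
#' @return A [BaselineFit-class] with method `"msmml"`.
#' @export
fitMSMML <- function(data, lambda1 = 1, lambda2 = 1, gamma = 0.5,
                     maxIter = 200L, tol = 1e-5, delta = 1e-8,
                     standardize = TRUE, qtStats = NULL, genoStats = NULL,
                     bootstrap = TRUE) {
  stopifnot(is(data, "LongitudinalDataset"))
  prep <- .prepareStages(data, standardize, qtStats, genoStats)
  hyper <- .makeHyper(gG = gamma, gA = 1 - gamma, lambdaP = lambda1,
                      lambdaQ = lambda2, tau = 0, delta = delta, ridge = 0,
                      penalty = "linf")
  res <- .mscolorEngine(prep, hyper, share = FALSE,
                        maxIter = as.integer(maxIter), tol = tol,
                        bootstrap = bootstrap)
  new("BaselineFit", method = "msmml",
      params = list(Astage = res$par$Astage, Bstage = res$par$Bstage,
                    W = res$par$W, V = res$par$V),
      objectiveTrace = res$objectiveTrace,
      surrogateTrace = res$surrogateTrace,
      converged = res$converged, nIter = res$nIter,
      subjectRegistry = prep$registry,
      snpIds = prep$snpIds, qtNames = prep$qtNames,
      prepared = list(prep = prep, hyper = hyper),
      control = list(lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
                     maxIter = maxIter, tol = tol, delta = delta,
                     standardize = standardize))
}

#' Fit the per-timepoint sparse multi-task regression baseline
#'
#' Regresses every (stage, visit) QT matrix on the genotypes with one
#' coefficient matrix per task and a joint l2,1 row penalty:
#' min_W sum_k ||Y_k - X W_k||_F^2 + lambda ||W||_2,1 with rows taken
#' across all tasks. No trajectory structure: this method selects variants
#' but cannot model progression. Solved by iteratively reweighted ridge.
#'
#' @param data a [LongitudinalDataset-class]; pooled to the subjects
#'   present in every stage.
#' @param lambda nonnegative penalty weight.
#' @inheritParams fitSMML
#' @return A [BaselineFit-class] with method `"smtr"`; `params$W` is a list
#'   of per-task coefficient matrices aligned with `params$layout`.
#' @export
fitSMTR <- function(data, lambda = 1, maxIter = 200L, tol = 1e-5,
                    delta = 1e-8, standardize = TRUE) {
  stopifnot(is(data, "LongitudinalDataset"))
  prep <- .pooledView(data, standardize)
  sg <- prep$stages[[1L]]
  Y <- do.call(cbind, sg$Z)
  X <- sg$X
  XtY <- crossprod(X, Y)
  d <- ncol(X)
  W <- matrix(0, d, ncol(Y))
  objTrace <- numeric(0); surTrace <- numeric(0)
  converged <- FALSE; it <- 0L
  step <- function(Dw) .cholSolve(sg$XtX + diag(lambda * Dw, d),
                                  XtY, "W", "lambda")
  scoreOf <- function(Wcur) {
    r <- pmax.int(.rowL2(Wcur), delta)
    R <- Y - X %*% Wcur
    c(obj = sum(R * R) + lambda * sum(r),
      sur = sum(R * R) + lambda * sum((rowSums(Wcur^2) + r^2) / (2 * r)))
  }
  while (it < maxIter) {
    it <- it + 1L
    Wold <- W
    # iteration 1 bootstraps with identity weights, as in the main engine
    W <- step(if (it == 1L) rep(1, d) else reweightDiag(W, delta, "l2"))
    sc <- scoreOf(W)
    objTrace[it] <- sc[["obj"]]
    surTrace[it] <- sc[["sur"]]
    if (it > 1L && surTrace[it] - surTrace[it - 1L] >
          1e-3 * max(abs(surTrace[1L]), 1))
      stop("surrogate objective increased: solver divergence")
    if (max(abs(W - Wold)) <= tol) { converged <- TRUE; break }
  }
  cc <- prep$cc
  Wtasks <- lapply(seq_len(sg$m), function(k)
    W[, (k - 1L) * cc + seq_len(cc), drop = FALSE])
  new("BaselineFit", method = "smtr",
      params = list(W = Wtasks, Wflat = W, layout = prep$layout),
      objectiveTrace = objTrace, surrogateTrace = surTrace,
      converged = converged, nIter = it,
      subjectRegistry = prep$registry,
      snpIds = prep$snpIds, qtNames = prep$qtNames,
      prepared = list(prep = prep),
      control = list(lambda = lambda, maxIter = maxIter, tol = tol,
                     delta = delta, standardize = standardize))
}

#' Fitted values of a baseline
#'
#' For `"smml"`: \eqn{A + X W + (B + X V) t} at a pooled visit time t.
#' For `"msmml"`: the per-stage analogue of [predict][MscolorFit-class]
#' with stage-specific aging effects. For `"smtr"`: \eqn{X W_k} for pooled
#' task k (`t` is then the task index).
#'
#' @param object a [BaselineFit-class].
#' @param stage stage index (`"msmml"`), ignored otherwise.
#' @param t within-stage time (`"msmml"`), pooled time (`"smml"`), or task
#'   index (`"smtr"`).
#' @param ... unused.
#' @export
setMethod("predict", "BaselineFit", function(object, stage = 1L, t = 0, ...) {
  prep <- object@prepared$prep
  p <- object@params
  switch(object@method,
    smml = {
      X <- prep$stages[[1L]]$X
      p$A + X %*% p$W + (p$B + X %*% p$V) * t
    },
    msmml = {
      sg <- prep$stages[[stage]]
      g <- object@control$gamma
      g * (sg$X %*% p$W[[stage]] + sg$X %*% p$V[[stage]] * t) +
        (1 - g) * (p$Astage[[stage]] + p$Bstage[[stage]] * t)
    },
    smtr = {
      k <- as.integer(t)
      prep$stages[[1L]]$X %*% p$W[[k]]
    })
})
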