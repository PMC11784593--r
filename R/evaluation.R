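## Model-fit scoring, nested cross-validation, SNP-selection scoring, and
## the post-fit statistical validation procedures (stage-contrast t tests,
## covariate-adjusted ANOVA of top SNPs, trajectory-cognition correlations).

#' Root mean square error
#'
#' sqrt of the mean squared residual over all entries. Aggregate model
#' reports average this quantity over subjects and QTs, each scored across
#' its time points.
#'
#' @param observed,fitted numeric vectors/matrices of equal shape.
#' @return scalar.
#' @export
rmse <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("'observed' and 'fitted' must have the same length")
  sqrt(mean((observed - fitted)^2))
}

#' Deterministic cross-validation folds
#'
#' Fold labels are a pure function of the *set* of ids and the seed: ids
#' are sorted before the seeded assignment, so any row order of the data
#' yields identical folds.
#'
#' @param ids character vector of subject ids.
#' @param k number of folds.
#' @param seed integer.
#' @return named integer vector of fold labels (1..k).
#' @export
makeFolds <- function(ids, k, seed) {
  ids <- sort(unique(as.character(ids)))
  if (length(ids) < k) stop("fewer subjects than folds")
  set.seed(seed)
  f <- sample(rep_len(seq_len(k), length(ids)))
  names(f) <- ids
  f
}

## restrict a dataset to a set of subjects (per-stage intersection)
.subsetDataset <- function(data, ids) {
  stages <- lapply(data@stages, function(st) {
    keep <- st@subjectIds %in% ids
    if (sum(keep) < 2L)
      stop("a stage retains fewer than 2 subjects after subsetting")
    StageData(stageIndex = st@stageIndex,
              subjectIds = st@subjectIds[keep],
              genotype = st@genotype[keep, , drop = FALSE],
              qts = st@qts[, keep, , drop = FALSE],
              times = st@times + st@timeOffset,
              qtNames = st@qtNames, snpIds = st@snpIds)
  })
  cov <- data@covariates
  if (nrow(cov)) cov <- cov[cov$subject_id %in% ids, , drop = FALSE]
  LongitudinalDataset(stages, cov)
}

## --- internal: fitting and scoring one method on one train/test split ---

.fitOne <- function(method, trainData, summary, lambda, gamma, tau,
                    maxIter, tol) {
  switch(method,
    mscolor = fitMSColoR(trainData, summary, gamma = gamma,
                         lambdaP = lambda, lambdaQ = lambda, tau = tau,
                         maxIter = maxIter, tol = tol),
    msmml = fitMSMML(trainData, lambda1 = lambda, lambda2 = lambda,
                     gamma = gamma, maxIter = maxIter, tol = tol),
    smml = fitSMML(trainData, lambda1 = lambda, lambda2 = lambda,
                   maxIter = maxIter, tol = tol),
    smtr = fitSMTR(trainData, lambda = lambda, maxIter = maxIter,
                   tol = tol))
}

## Warm-started fits along an ascending lambda path on one training subset:
## the design is prepared once and each fit starts from the previous
## lambda's solution (ascending, so rows shrink along the path rather than
## having to re-grow through the reweighting floor). Returns light fit
## records carrying just enough state for validation RMSE.
.pathFits <- function(method, trainData, summary, lambdas, gamma, tau,
                      maxIter, tol, delta = 1e-8, ridge = 1e-3) {
  lambdas <- sort(lambdas)
  out <- vector("list", length(lambdas))
  if (method %in% c("mscolor", "msmml", "smml")) {
    prep <- if (method == "smml") .pooledView(trainData, TRUE)
      else .prepareStages(trainData, TRUE)
    share <- method == "mscolor"
    par0 <- NULL
    for (i in seq_along(lambdas)) {
      lam <- lambdas[i]
      hyper <- switch(method,
        mscolor = .makeHyper(gamma, 1 - gamma, lam, lam, tau, delta, ridge,
                             "linf", summary),
        msmml = .makeHyper(gamma, 1 - gamma, lam, lam, 0, delta, 0, "linf"),
        smml = .makeHyper(1, 1, lam, lam, 0, delta, 0, "l2"))
      res <- .mscolorEngine(prep, hyper, share = share, maxIter = maxIter,
                            tol = tol, par0 = par0)
      par0 <- res$par
      out[[i]] <- list(method = method, gG = hyper$gG, gA = hyper$gA,
                       prep = prep, par = res$par)
    }
  } else {
    prep <- .pooledView(trainData, TRUE)
    sg <- prep$stages[[1L]]
    Y <- do.call(cbind, sg$Z)
    XtY <- crossprod(sg$X, Y)
    d <- ncol(sg$X)
    W <- matrix(0, d, ncol(Y))
    for (i in seq_along(lambdas)) {
      for (it in seq_len(maxIter)) {
        Wold <- W
        Dw <- if (i == 1L && it == 1L) rep(1, d)
          else reweightDiag(W, delta, "l2")
        W <- .cholSolve(sg$XtX + diag(lambdas[i] * Dw, d), XtY, "W", "lambda")
        if (it > 1L && max(abs(W - Wold)) <= tol) break
      }
      out[[i]] <- list(method = "smtr", prep = prep, W = W)
    }
  }
  names(out) <- as.character(lambdas)
  out
}

## Held-out RMSE: model-based prediction of unseen subjects. The genetic
## part is fully predictable from the held-out genotypes; the aging part of
## an unseen subject is unknowable, so the population column means of the
## fitted aging effects stand in (the fixed-effects prediction of a mixed
## model). RMSE is over all visits, subjects and QTs of each stage.
.lightRmse <- function(light, newData) {
  prep <- light$prep
  qstd <- function(zk, n, cc) {
    dim(zk) <- c(n, cc)
    sweep(sweep(zk, 2L, prep$qtStats$means, "-"),
          2L, prep$qtStats$scales, "/")
  }
  if (light$method %in% c("mscolor", "msmml", "smml")) {
    par <- light$par; gG <- light$gG; gA <- light$gA
    out <- numeric(length(newData@stages))
    ids <- if (light$method == "smml") .commonSubjects(newData) else NULL
    for (s in seq_along(newData@stages)) {
      st <- newData@stages[[s]]
      pos <- if (is.null(ids)) seq_along(st@subjectIds)
        else match(ids, st@subjectIds)
      n <- length(pos); cc <- length(st@qtNames)
      if (n == 0L) { out[s] <- NA_real_; next }
      gi <- if (light$method == "smml") 1L else s
      Xt <- .genoStandardize(st@genotype[pos, , drop = FALSE],
                             prep$genoStats[[gi]])$x
      if (par$share) {
        Abar <- colMeans(par$A); Bbar <- colMeans(par$B)
      } else {
        Abar <- colMeans(par$Astage[[gi]]); Bbar <- colMeans(par$Bstage[[gi]])
      }
      GW <- Xt %*% par$W[[gi]]; HV <- Xt %*% par$V[[gi]]
      ## the one-stage model lives on the pooled absolute time axis
      toff <- if (light$method == "smml") st@timeOffset else 0
      se <- 0
      for (k in seq_along(st@times)) {
        zk <- qstd(st@qts[k, pos, , drop = FALSE], n, cc)
        tk <- st@times[k] + toff
        pred <- gG * (GW + HV * tk) +
          gA * rep(1, n) %o% (Abar + Bbar * tk)
        se <- se + sum((zk - pred)^2)
      }
      out[s] <- sqrt(se / (n * cc * length(st@times)))
    }
    return(c(out, avg = mean(out, na.rm = TRUE)))
  }
  ## smtr: direct per-task genotype prediction
  ids <- .commonSubjects(newData)
  if (length(ids) < 1L) return(c(pooled = NA_real_, avg = NA_real_))
  st1 <- newData@stages[[1L]]
  Xt <- .genoStandardize(st1@genotype[match(ids, st1@subjectIds), ,
                                      drop = FALSE],
                         prep$genoStats[[1L]])$x
  cc <- length(st1@qtNames)
  se <- 0; cnt <- 0L; pooledIdx <- 0L
  for (s in seq_along(newData@stages)) {
    st <- newData@stages[[s]]
    pos <- match(ids, st@subjectIds)
    for (k in seq_along(st@times)) {
      pooledIdx <- pooledIdx + 1L
      zk <- qstd(st@qts[k, pos, , drop = FALSE], length(ids), cc)
      wk <- light$W[, (pooledIdx - 1L) * cc + seq_len(cc), drop = FALSE]
      se <- se + sum((zk - Xt %*% wk)^2)
      cnt <- cnt + length(zk)
    }
  }
  r <- sqrt(se / cnt)
  c(pooled = r, avg = r)
}

## light view of a fitted S4 object, so the same scoring code serves both
.asLight <- function(fit) {
  if (is(fit, "MscolorFit")) {
    list(method = "mscolor", gG = fit@gamma, gA = 1 - fit@gamma,
         prep = fit@prepared$prep,
         par = list(share = fit@control$shareAging, A = fit@A, B = fit@B,
                    Astage = fit@Astage, Bstage = fit@Bstage,
                    W = fit@W, V = fit@V, u = fit@u))
  } else if (fit@method == "smtr") {
    list(method = "smtr", prep = fit@prepared$prep, W = fit@params$Wflat)
  } else if (fit@method == "smml") {
    list(method = "smml", gG = 1, gA = 1, prep = fit@prepared$prep,
         par = list(share = FALSE, Astage = list(fit@params$A),
                    Bstage = list(fit@params$B), W = list(fit@params$W),
                    V = list(fit@params$V)))
  } else {
    list(method = "msmml", gG = fit@control$gamma,
         gA = 1 - fit@control$gamma, prep = fit@prepared$prep,
         par = list(share = FALSE, Astage = fit@params$Astage,
                    Bstage = fit@params$Bstage, W = fit@params$W,
                    V = fit@params$V))
  }
}

## in-sample RMSE of a light path fit (subject-level aging effects used)
.lightTrainRmse <- function(light) {
  prep <- light$prep
  if (light$method == "smtr") {
    sg <- prep$stages[[1L]]
    Y <- do.call(cbind, sg$Z)
    r <- sqrt(mean((Y - sg$X %*% light$W)^2))
    return(c(pooled = r, avg = r))
  }
  par <- light$par; gG <- light$gG; gA <- light$gA
  out <- numeric(prep$L)
  for (s in seq_len(prep$L)) {
    sg <- prep$stages[[s]]
    ag <- if (par$share)
      list(A = par$A[sg$idx, , drop = FALSE],
           B = par$B[sg$idx, , drop = FALSE])
    else list(A = par$Astage[[s]], B = par$Bstage[[s]])
    G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
    se <- 0
    for (k in seq_len(sg$m)) {
      R <- sg$Z[[k]] - gG * (G + H * sg$t[k]) -
        gA * (ag$A + ag$B * sg$t[k])
      se <- se + sum(R * R)
    }
    out[s] <- sqrt(se / (nrow(sg$X) * prep$cc * sg$m))
  }
  c(out, avg = mean(out))
}

.lightScores <- function(light) {
  nm <- light$prep$snpIds
  named <- function(x) { names(x) <- nm; x }
  if (light$method == "smtr")
    return(list(W = list(named(.rowMaxAbs(light$W))), V = list()))
  list(W = lapply(light$par$W, function(m) named(.rowMaxAbs(m))),
       V = lapply(light$par$V, function(m) named(.rowMaxAbs(m))))
}

.testRmse <- function(fit, testData) .lightRmse(.asLight(fit), testData)

.trainRmse <- function(fit) {
  prep <- fit@prepared$prep
  if (is(fit, "MscolorFit") || fit@method == "msmml") {
    out <- numeric(prep$L)
    for (s in seq_len(prep$L)) {
      sg <- prep$stages[[s]]
      se <- 0
      for (k in seq_len(sg$m)) {
        pred <- predict(fit, stage = s, t = sg$t[k])
        se <- se + sum((sg$Z[[k]] - pred)^2)
      }
      out[s] <- sqrt(se / (nrow(sg$X) * prep$cc * sg$m))
    }
    c(out, avg = mean(out))
  } else {
    sg <- prep$stages[[1L]]
    se <- 0; cnt <- 0L
    for (k in seq_len(sg$m)) {
      pred <- predict(fit, t = if (fit@method == "smml") sg$t[k] else k)
      se <- se + sum((sg$Z[[k]] - pred)^2)
      cnt <- cnt + length(sg$Z[[k]])
    }
    r <- sqrt(se / cnt)
    c(pooled = r, avg = r)
  }
}

.fitScores <- function(fit) {
  nm <- fit@snpIds
  named <- function(x) { names(x) <- nm; x }
  if (is(fit, "MscolorFit")) {
    list(W = lapply(fit@W, function(m) named(.rowMaxAbs(m))),
         V = lapply(fit@V, function(m) named(.rowMaxAbs(m))))
  } else if (fit@method == "msmml") {
    list(W = lapply(fit@params$W, function(m) named(.rowMaxAbs(m))),
         V = lapply(fit@params$V, function(m) named(.rowMaxAbs(m))))
  } else if (fit@method == "smml") {
    list(W = list(named(.rowMaxAbs(fit@params$W))),
         V = list(named(.rowMaxAbs(fit@params$V))))
  } else {
    list(W = list(named(.rowMaxAbs(fit@params$Wflat))), V = list())
  }
}

#' Nested cross-validation of a method
#'
#' Outer folds estimate generalization error; inner folds select the
#' sparsity level from `grid` by mean validation RMSE, ties broken toward
#' the larger (sparser) value. Folds partition the subject registry
#' deterministically from the seed; all standardization statistics are
#' estimated on the training side of each split only.
#'
#' @param data a [LongitudinalDataset-class].
#' @param summary a [HarmonizedSummary-class] (required for
#'   `method = "mscolor"`).
#' @param method one of `"mscolor"`, `"msmml"`, `"smml"`, `"smtr"`.
#' @param grid candidate penalty values (default powers of ten, 1e-3..1e3);
#'   applied to both penalty blocks.
#' @param kOuter,kInner fold counts.
#' @param gamma,tau passed to the fitters where relevant.
#' @param maxIter,tol solver settings for the CV fits.
#' @param seed integer; folds and everything downstream derive from it.
#'
#' @return A [CvReport-class].
#' @export
nestedCV <- function(data, summary = NULL,
                     method = c("mscolor", "msmml", "smml", "smtr"),
                     grid = 10^(-3:3), kOuter = 5L, kInner = 5L,
                     gamma = 0.5, tau = 1, maxIter = 100L, tol = 1e-5,
                     seed = 1L) {
  method <- match.arg(method)
  if (!length(grid)) stop("'grid' must be nonempty")
  if (method == "mscolor" && is.null(summary))
    stop("method 'mscolor' needs harmonized summary statistics")
  registry <- data@subjectRegistry
  if (length(registry) < kOuter) stop("fewer subjects than outer folds")
  grid <- sort(grid)
  outer <- makeFolds(registry, kOuter, seed)
  foldRows <- NULL; chosen <- NULL; snpScores <- list()
  for (o in seq_len(kOuter)) {
    testIds <- names(outer)[outer == o]
    trainIds <- names(outer)[outer != o]
    trainData <- .subsetDataset(data, trainIds)
    inner <- makeFolds(trainIds, kInner, seed * 131L + o)
    valErr <- matrix(NA_real_, kInner, length(grid))
    for (j in seq_len(kInner)) {
      subTrain <- .subsetDataset(trainData, names(inner)[inner != j])
      subVal <- .subsetDataset(trainData, names(inner)[inner == j])
      lights <- .pathFits(method, subTrain, summary, grid, gamma, tau,
                          maxIter, tol)
      for (gidx in seq_along(grid))
        valErr[j, gidx] <- .lightRmse(lights[[gidx]], subVal)[["avg"]]
    }
    mv <- colMeans(valErr)
    best <- max(which(mv <= min(mv) + 1e-12))  # tie -> larger lambda
    lamSel <- grid[best]
    # outer refit along the same warm-started path the inner folds used,
    # so the reported solution is the path solution at the chosen lambda
    outerLights <- .pathFits(method, trainData, summary, grid, gamma, tau,
                             maxIter, tol)
    light <- outerLights[[as.character(lamSel)]]
    testData <- .subsetDataset(data, testIds)
    tr <- .lightTrainRmse(light); te <- .lightRmse(light, testData)
    stageNames <- names(te)
    stageNames[stageNames == ""] <- as.character(seq_len(sum(stageNames == "")))
    foldRows <- rbind(foldRows, data.frame(
      fold = o, stage = stageNames, trainRmse = unname(tr),
      testRmse = unname(te)))
    chosen <- rbind(chosen, data.frame(fold = o, lambda = lamSel))
    snpScores[[o]] <- .lightScores(light)
  }
  avg <- foldRows[foldRows$stage == "avg", ]
  summaryDf <- data.frame(
    metric = c("trainRmse", "testRmse"),
    mean = c(mean(avg$trainRmse), mean(avg$testRmse)),
    sd = c(stats::sd(avg$trainRmse), stats::sd(avg$testRmse)))
  new("CvReport", method = method, folds = foldRows, chosen = chosen,
      grid = grid, snpScores = snpScores, summary = summaryDf,
      seed = as.integer(seed))
}

## Mann-Whitney AUC of a score against binary labels
.aucScore <- function(score, labels) {
  pos <- which(labels); neg <- which(!labels)
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' SNP-selection scoring and support recovery
#'
#' Aggregates per-SNP weights (mean absolute row-max across CV folds or
#' fits, separately for the intercept and slope blocks of each stage) into
#' a ranking, and scores it against a simulated causal support when one is
#' available.
#'
#' @param fits a [CvReport-class], a single fit, or a list of fits.
#' @param truth optional [SimTruth-class].
#' @param topK size of the reported top set (default 10).
#' @return A [SelectionReport-class].
#' @export
selectionMetrics <- function(fits, truth = NULL, topK = 10L) {
  scoreSets <- if (is(fits, "CvReport")) {
    fits@snpScores
  } else if (is.list(fits)) {
    # fits may be S4 fit objects or already-extracted score structures
    lapply(fits, function(f) if (isS4(f)) .fitScores(f) else f)
  } else {
    list(.fitScores(fits))
  }
  L <- length(scoreSets[[1L]]$W)
  d <- length(scoreSets[[1L]]$W[[1L]])
  ids <- names(scoreSets[[1L]]$W[[1L]])
  if (is.null(ids)) ids <- paste0("snp", seq_len(d))
  blockMean <- function(block, s) {
    vals <- vapply(scoreSets, function(sc)
      if (length(sc[[block]]) >= s) sc[[block]][[s]] else rep(0, d),
      numeric(d))
    rowMeans(vals)
  }
  scores <- data.frame(snp_id = ids)
  for (s in seq_len(L)) {
    scores[[paste0("intercept_stage", s)]] <- blockMean("W", s)
    if (length(scoreSets[[1L]]$V) >= s)
      scores[[paste0("slope_stage", s)]] <- blockMean("V", s)
  }
  blockCols <- setdiff(colnames(scores), "snp_id")
  scores$overall <- do.call(pmax, scores[blockCols])
  ranking <- scores$snp_id[order(scores$overall, decreasing = TRUE)]
  allZero <- all(scores$overall == 0)
  topK <- min(as.integer(topK), d)
  auc <- NA_real_; prec <- NA_real_
  if (!is.null(truth)) {
    lab <- causalSupport(truth)
    if (!allZero) auc <- .aucScore(scores$overall, lab)
    prec <- mean(lab[match(ranking[seq_len(topK)], ids)])
  }
  new("SelectionReport", scores = scores, ranking = ranking,
      auc = auc, precisionAtK = prec, topK = topK, allZero = allZero)
}

#' Significance bands for p values
#'
#' The conventional star banding: `ns` above 0.05, then `*` (<= 0.05),
#' `**` (<= 0.01), `***` (<= 0.001), `****` (<= 0.0001).
#'
#' @param p numeric vector of p values.
#' @return character vector of bands.
#' @export
significanceBand <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

## fitted per-subject stage slopes/intercepts on the standardized QT scale
.subjectEffects <- function(fit, stage) {
  stopifnot(is(fit, "MscolorFit") ||
              (is(fit, "BaselineFit") && fit@method == "msmml"))
  mscolor <- is(fit, "MscolorFit")
  prep <- fit@prepared$prep
  sg <- prep$stages[[stage]]
  g <- if (mscolor) fit@gamma else fit@control$gamma
  W <- if (mscolor) fit@W[[stage]] else fit@params$W[[stage]]
  V <- if (mscolor) fit@V[[stage]] else fit@params$V[[stage]]
  if (mscolor && fit@control$shareAging) {
    As <- fit@A[sg$idx, , drop = FALSE]; Bs <- fit@B[sg$idx, , drop = FALSE]
  } else if (mscolor) {
    As <- fit@Astage[[stage]]; Bs <- fit@Bstage[[stage]]
  } else {
    As <- fit@params$Astage[[stage]]; Bs <- fit@params$Bstage[[stage]]
  }
  list(subjects = prep$stageSubjects[[stage]],
       intercept = g * (sg$X %*% W) + (1 - g) * As,
       slope = g * (sg$X %*% V) + (1 - g) * Bs)
}

#' Stage-contrast t tests of fitted progression rates
#'
#' Two-sample Welch t tests comparing the distributions of fitted
#' per-subject slopes (region-averaged across QTs) between every pair of
#' stages, and — when a grouping covariate is given — between diagnostic
#' groups within each stage. Significant stage contrasts indicate that the
#' staged model captured genuinely different progression rates.
#'
#' @param fit a [MscolorFit-class] (or an `"msmml"` [BaselineFit-class]).
#' @param covariates optional data.frame with `subject_id` and the
#'   grouping column.
#' @param groupBy optional name of the grouping column (e.g.
#'   `"diagnosis"`).
#' @param adjust add a Benjamini-Hochberg adjusted column `p_bh`
#'   (default off: raw p values match the harness's presentation).
#' @param measure `"slope"` (default) or `"intercept"`.
#' @return data.frame with one row per comparison: the compared units,
#'   t statistic, degrees of freedom, two-sided p and significance band.
#' @export
stageSlopeTests <- function(fit, covariates = NULL, groupBy = NULL,
                            measure = c("slope", "intercept"),
                            adjust = FALSE) {
  measure <- match.arg(measure)
  L <- nStages(fit)
  eff <- lapply(seq_len(L), function(s) .subjectEffects(fit, s))
  avg <- lapply(eff, function(e) rowMeans(e[[measure]]))
  rows <- NULL
  tt <- function(x, y) stats::t.test(x, y)
  if (L > 1L) for (s1 in seq_len(L - 1L)) for (s2 in (s1 + 1L):L) {
    ht <- tt(avg[[s1]], avg[[s2]])
    rows <- rbind(rows, data.frame(
      comparison = "between-stages", unit1 = paste0("stage", s1),
      unit2 = paste0("stage", s2), stage = NA_integer_,
      t = unname(ht$statistic), df = unname(ht$parameter),
      p = ht$p.value, band = significanceBand(ht$p.value)))
  }
  if (!is.null(groupBy)) {
    if (is.null(covariates) || !groupBy %in% colnames(covariates))
      stop("grouping column '", groupBy, "' not found in covariates")
    for (s in seq_len(L)) {
      grp <- covariates[[groupBy]][match(eff[[s]]$subjects,
                                         covariates$subject_id)]
      lv <- unique(stats::na.omit(grp))
      if (length(lv) < 2L) next
      for (i1 in seq_len(length(lv) - 1L)) for (i2 in (i1 + 1L):length(lv)) {
        x <- avg[[s]][grp == lv[i1]]; y <- avg[[s]][grp == lv[i2]]
        if (length(x) < 2L || length(y) < 2L) next
        ht <- tt(x, y)
        rows <- rbind(rows, data.frame(
          comparison = "between-groups", unit1 = as.character(lv[i1]),
          unit2 = as.character(lv[i2]), stage = s,
          t = unname(ht$statistic), df = unname(ht$parameter),
          p = ht$p.value, band = significanceBand(ht$p.value)))
      }
    }
  }
  if (adjust && !is.null(rows)) rows$p_bh <- stats::p.adjust(rows$p, "BH")
  rows
}

#' Correlations of fitted trajectories with cognition and diagnosis
#'
#' Pearson correlations (signed values, with p from [stats::cor.test()])
#' between the fitted per-subject stage slope and intercept — averaged
#' across QTs, i.e. across brain regions — and each named score. A
#' character/factor score (e.g. diagnosis) is numeric-coded by its sorted
#' levels.
#'
#' @param fit a [MscolorFit-class] (or `"msmml"` baseline fit).
#' @param covariates data.frame with `subject_id` and the score columns.
#' @param scoreNames character vector of covariate columns to correlate.
#' @param adjust add a Benjamini-Hochberg adjusted column `p_bh`.
#' @return data.frame: stage, measure, score, n, r, p, band.
#' @export
trajectoryCorrelations <- function(fit, covariates, scoreNames,
                                   adjust = FALSE) {
  miss <- setdiff(scoreNames, colnames(covariates))
  if (length(miss)) stop("missing score column(s): ",
                         paste(miss, collapse = ", "))
  L <- nStages(fit)
  rows <- NULL
  for (s in seq_len(L)) {
    eff <- .subjectEffects(fit, s)
    pos <- match(eff$subjects, covariates$subject_id)
    for (ms in c("slope", "intercept")) {
      x <- rowMeans(eff[[ms]])
      for (sc in scoreNames) {
        y <- covariates[[sc]][pos]
        if (!is.numeric(y)) y <- as.integer(factor(y, levels = sort(unique(y))))
        ok <- is.finite(x) & is.finite(y)
        ht <- stats::cor.test(x[ok], y[ok], method = "pearson")
        rows <- rbind(rows, data.frame(
          stage = s, measure = ms, score = sc, n = sum(ok),
          r = unname(ht$estimate), p = ht$p.value,
          band = significanceBand(ht$p.value)))
      }
    }
  }
  if (adjust) rows$p_bh <- stats::p.adjust(rows$p, "BH")
  rows
}

#' Covariate-adjusted ANOVA of one SNP on diagnostic status
#'
#' Tests whether a SNP's dosage (as a factor over its observed levels)
#' explains numeric-coded diagnostic status beyond age, gender, handedness
#' and education: an F test of the genotype term added last to the linear
#' model. A locus is called effective when p <= 0.05.
#'
#' @param genotype integer/numeric dosage vector (0/1/2).
#' @param diagnosis factor/character/numeric diagnostic status; non-numeric
#'   input is coded by its sorted levels.
#' @param covariates data.frame aligned with `genotype` holding the
#'   adjustment columns.
#' @param adjustFor character, adjustment columns (default the four
#'   demographics).
#' @return one-row data.frame with F, df1, df2, p and `effective`.
#' @export
anovaSnpEffect <- function(genotype, diagnosis, covariates,
                           adjustFor = c("age", "gender", "handedness",
                                         "education")) {
  if (length(unique(genotype)) < 2L)
    stop("genotype has no variation; ANOVA undefined")
  if (!is.numeric(diagnosis))
    diagnosis <- as.integer(factor(diagnosis,
                                   levels = sort(unique(diagnosis))))
  miss <- setdiff(adjustFor, colnames(covariates))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(.y = diagnosis, .g = factor(genotype),
                   covariates[, adjustFor, drop = FALSE])
  fit <- stats::lm(stats::reformulate(c(adjustFor, ".g"), response = ".y"),
                   data = df)
  at <- stats::anova(fit)
  row <- at[".g", ]
  data.frame(F = row[["F value"]], df1 = row[["Df"]],
             df2 = at["Residuals", "Df"], p = row[["Pr(>F)"]],
             effective = row[["Pr(>F)"]] <= 0.05)
}
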