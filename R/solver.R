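## Alternating closed-form solver for the multi-stage mixed-effects
## collaborative model and its reduced variants.
##
## The residual structure shared by all model variants is, per stage s and
## within-stage visit k,
##     Z_ks - gG (X_s W_s + X_s V_s t_ks) - gA (A_s + B_s t_ks)
## with gG the weight on the genetic terms and gA the weight on the
## population aging terms. The collaborative model uses gG = gamma,
## gA = 1 - gamma; the one-stage mixed-effects baseline fits the additive
## form gG = gA = 1. The GWAS collaboration term
##     tau (n_ref - 1) (u_s' Sigma u_s - 2 u_s' beta)
## is the expansion of ||y - X u_s||^2 with X'X and X'y replaced by their
## summary-statistic surrogates, up to the constant y'y that summary data
## cannot supply.

## ---- preparation -------------------------------------------------------

## Standardize genotype columns without changing the SNP panel: a column
## that is constant in some training fold is centered and left unscaled
## (it carries no signal there, and the panel must stay aligned with beta).
.genoStandardize <- function(x, stats = NULL) {
  if (is.null(stats)) {
    stats <- list(means = colMeans(x), scales = apply(x, 2L, stats::sd))
    stats$scales[stats$scales <= 0 | !is.finite(stats$scales)] <- 1
  }
  x <- sweep(x, 2L, stats$means, "-")
  x <- sweep(x, 2L, stats$scales, "/")
  list(x = x, stats = stats)
}

.qtGlobalStats <- function(data) {
  rows <- lapply(data@stages, function(st) {
    n <- length(st@subjectIds); cc <- length(st@qtNames)
    do.call(rbind, lapply(seq_along(st@times), function(k) {
      zk <- st@qts[k, , , drop = FALSE]; dim(zk) <- c(n, cc); zk
    }))
  })
  all <- do.call(rbind, rows)
  list(means = colMeans(all), scales = apply(all, 2L, stats::sd))
}

## Build the solver's per-stage design: standardized matrices plus the
## cross-products every update re-uses.
.prepareStages <- function(data, standardize = TRUE, qtStats = NULL,
                           genoStats = NULL) {
  registry <- data@subjectRegistry
  L <- nStages(data)
  cc <- nQts(data)
  d <- nSnps(data)
  if (standardize && is.null(qtStats)) qtStats <- .qtGlobalStats(data)
  if (is.null(genoStats)) genoStats <- vector("list", L)
  stages <- vector("list", L)
  for (s in seq_len(L)) {
    st <- data@stages[[s]]
    n <- length(st@subjectIds)
    gs <- if (standardize) .genoStandardize(st@genotype, genoStats[[s]])
          else list(x = st@genotype, stats = NULL)
    genoStats[[s]] <- gs$stats
    X <- gs$x
    t <- st@times
    m <- length(t)
    Z <- vector("list", m)
    for (k in seq_len(m)) {
      zk <- st@qts[k, , , drop = FALSE]; dim(zk) <- c(n, cc)
      if (standardize) {
        zk <- sweep(zk, 2L, qtStats$means, "-")
        zk <- sweep(zk, 2L, qtStats$scales, "/")
      }
      Z[[k]] <- zk
    }
    ZS <- Reduce(`+`, Z)
    ZT <- Reduce(`+`, Map(`*`, Z, t))
    stages[[s]] <- list(
      X = X, Z = Z, t = t, m = m,
      stm = sum(t), st2 = sum(t^2),
      idx = match(st@subjectIds, registry),
      XtX = crossprod(X),
      SZ = crossprod(X, ZS),
      TZ = crossprod(X, ZT),
      ZS = ZS, ZT = ZT)
  }
  list(registry = registry, L = L, d = d, cc = cc,
       qtStats = qtStats, genoStats = genoStats,
       snpIds = snpIds(data), qtNames = qtNames(data),
       stageSubjects = lapply(data@stages, function(st) st@subjectIds),
       stages = stages)
}

## ---- parameter state ---------------------------------------------------

.initParams <- function(prep, share, init = "zeros", seed = NULL) {
  L <- prep$L; d <- prep$d; cc <- prep$cc
  nreg <- length(prep$registry)
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.01), nr, nc)
  if (init == "random" && !is.null(seed)) set.seed(seed)
  mk <- function(nr, nc) if (init == "random") rnd(nr, nc) else matrix(0, nr, nc)
  par <- list(
    share = share,
    A = if (share) matrix(0, nreg, cc) else matrix(0, 0, 0),
    B = if (share) matrix(0, nreg, cc) else matrix(0, 0, 0),
    Astage = if (share) list() else lapply(prep$stages, function(sg)
      matrix(0, nrow(sg$X), cc)),
    Bstage = if (share) list() else lapply(prep$stages, function(sg)
      matrix(0, nrow(sg$X), cc)),
    W = lapply(seq_len(L), function(s) mk(d, cc)),
    V = lapply(seq_len(L), function(s) mk(d, cc)),
    u = lapply(seq_len(L), function(s) numeric(d)))
  par
}

.stageAging <- function(par, prep, s) {
  if (par$share) {
    idx <- prep$stages[[s]]$idx
    list(A = par$A[idx, , drop = FALSE], B = par$B[idx, , drop = FALSE])
  } else {
    list(A = par$Astage[[s]], B = par$Bstage[[s]])
  }
}

.penaltyBlocks <- function(par, hyper, s) {
  list(P = .penaltyP(par, hyper, s), Q = .penaltyQ(par, hyper, s))
}
.penaltyP <- function(par, hyper, s) {
  if (hyper$useGwas) cbind(par$u[[s]], par$W[[s]]) else par$W[[s]]
}
.penaltyQ <- function(par, hyper, s) {
  if (hyper$useGwas) cbind(par$u[[s]], par$V[[s]]) else par$V[[s]]
}

.rowStat <- function(M, hyper) {
  if (hyper$penalty == "linf") .rowMaxAbs(M) else .rowL2(M)
}

## ---- block updates -----------------------------------------------------

## Exact minimizer of the objective in the population aging effects: each
## registry subject's intercept row is the mean of its residuals over every
## (stage, visit) observation, and its slope row the time-weighted
## least-squares solution. Subjects whose visits are all at t = 0 keep
## their current slope.
.updateAging <- function(prep, par, hyper, which = c("both", "A", "B")) {
  which <- match.arg(which)
  gG <- hyper$gG; gA <- hyper$gA
  if (gA == 0) return(par)
  cc <- prep$cc
  doA <- which != "B"; doB <- which != "A"
  if (par$share) {
    nreg <- length(prep$registry)
    num <- matrix(0, nreg, cc); cnt <- numeric(nreg)
    if (doA) {
      for (s in seq_len(prep$L)) {
        sg <- prep$stages[[s]]
        G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
        Bs <- par$B[sg$idx, , drop = FALSE]
        num[sg$idx, ] <- num[sg$idx, ] + sg$ZS -
          gG * (sg$m * G + sg$stm * H) - gA * sg$stm * Bs
        cnt[sg$idx] <- cnt[sg$idx] + sg$m
      }
      ok <- cnt > 0
      par$A[ok, ] <- num[ok, , drop = FALSE] / (gA * cnt[ok])
    }
    if (doB) {
      num <- matrix(0, nreg, cc); den <- numeric(nreg)
      for (s in seq_len(prep$L)) {
        sg <- prep$stages[[s]]
        G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
        As <- par$A[sg$idx, , drop = FALSE]
        num[sg$idx, ] <- num[sg$idx, ] + sg$ZT -
          gG * (sg$stm * G + sg$st2 * H) - gA * sg$stm * As
        den[sg$idx] <- den[sg$idx] + sg$st2
      }
      ok <- den > 0
      par$B[ok, ] <- num[ok, , drop = FALSE] / (gA * den[ok])
    }
  } else {
    for (s in seq_len(prep$L)) {
      sg <- prep$stages[[s]]
      G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
      if (doA)
        par$Astage[[s]] <- (sg$ZS - gG * (sg$m * G + sg$stm * H) -
                              gA * sg$stm * par$Bstage[[s]]) / (gA * sg$m)
      if (doB && sg$st2 > 0)
        par$Bstage[[s]] <- (sg$ZT - gG * (sg$stm * G + sg$st2 * H) -
                              gA * sg$stm * par$Astage[[s]]) / (gA * sg$st2)
    }
  }
  par
}

.cholSolve <- function(M, rhs, what, lambdaName) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("singular system in the ", what,
         " update; set ", lambdaName, " > 0 (or increase it) ",
         "so the reweighted penalty regularizes the solve")
  backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
}

## Closed-form W_s given everything else: stationarity of the fixed-weight
## objective gives (gG^2 m X'X + lambda_p D_p) W_s = gG X' R with R the
## residual excluding the X W_s term; the time-point count m enters the
## normal matrix because the intercept effect appears in every visit.
.updateW <- function(prep, par, hyper, s) {
  sg <- prep$stages[[s]]
  ag <- .stageAging(par, prep, s)
  gG <- hyper$gG; gA <- hyper$gA
  Dp <- if (isTRUE(par$bootstrap)) rep(1, prep$d) else
    reweightDiag(.penaltyP(par, hyper, s), hyper$delta, hyper$penalty)
  rhs <- gG * (sg$SZ - gG * sg$stm * sg$XtX %*% par$V[[s]] -
                 crossprod(sg$X, gA * (sg$m * ag$A + sg$stm * ag$B)))
  M <- gG^2 * sg$m * sg$XtX
  diag(M) <- diag(M) + hyper$lambdaP * Dp
  .cholSolve(M, rhs, "W", "lambdaP")
}

.updateV <- function(prep, par, hyper, s) {
  sg <- prep$stages[[s]]
  ag <- .stageAging(par, prep, s)
  gG <- hyper$gG; gA <- hyper$gA
  Dq <- if (isTRUE(par$bootstrap)) rep(1, prep$d) else
    reweightDiag(.penaltyQ(par, hyper, s), hyper$delta, hyper$penalty)
  rhs <- gG * (sg$TZ - gG * sg$stm * sg$XtX %*% par$W[[s]] -
                 crossprod(sg$X, gA * (sg$stm * ag$A + sg$st2 * ag$B)))
  M <- gG^2 * sg$st2 * sg$XtX
  diag(M) <- diag(M) + hyper$lambdaQ * Dq
  .cholSolve(M, rhs, "V", "lambdaQ")
}

## Joint GWAS effects: (Sigma + lambda_p D~_p + lambda_q D~_q + ridge I) u
## = beta, the summary-statistic normal equations with both row-sparsity
## reweightings carried over, scaled by 1/(tau (n_ref - 1)).
.updateU <- function(prep, par, hyper, s) {
  if (isTRUE(par$bootstrap)) {
    Dp <- Dq <- rep(1, prep$d)
  } else {
    blocks <- .penaltyBlocks(par, hyper, s)
    Dp <- reweightDiag(blocks$P, hyper$delta, hyper$penalty)
    Dq <- reweightDiag(blocks$Q, hyper$delta, hyper$penalty)
  }
  dtilde <- (hyper$lambdaP * Dp + hyper$lambdaQ * Dq) /
    (hyper$tau * (hyper$nRef - 1))
  M <- hyper$sigma
  diag(M) <- diag(M) + dtilde + hyper$ridge
  u <- .cholSolve(M, hyper$beta, "u", "ridge")
  if (!all(is.finite(u))) stop("non-finite joint-effect solve; increase 'ridge'")
  drop(u)
}

## ---- objective ---------------------------------------------------------

.dataFit <- function(prep, par, hyper) {
  gG <- hyper$gG; gA <- hyper$gA
  val <- 0
  for (s in seq_len(prep$L)) {
    sg <- prep$stages[[s]]
    ag <- .stageAging(par, prep, s)
    G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
    for (k in seq_len(sg$m)) {
      R <- sg$Z[[k]] - gG * (G + H * sg$t[k]) - gA * (ag$A + ag$B * sg$t[k])
      val <- val + sum(R * R)
    }
  }
  val
}

.gwasFit <- function(prep, par, hyper) {
  if (!hyper$useGwas) return(0)
  val <- 0
  for (s in seq_len(prep$L)) {
    u <- par$u[[s]]
    val <- val + hyper$tau * (hyper$nRef - 1) *
      (drop(crossprod(u, hyper$sigma %*% u)) - 2 * sum(u * hyper$beta))
  }
  val
}

## both traces in one pass: the data-fit and GWAS terms are shared; only
## the penalty differs between the model objective (delta-floored
## row-structured norm) and the quadratic surrogate
.evalBothObjectives <- function(prep, par, hyper) {
  base <- .dataFit(prep, par, hyper) + .gwasFit(prep, par, hyper)
  penO <- 0; penS <- 0
  for (s in seq_len(prep$L)) {
    for (bl in list(list(M = .penaltyP(par, hyper, s), l = hyper$lambdaP),
                    list(M = .penaltyQ(par, hyper, s), l = hyper$lambdaQ))) {
      r <- pmax.int(.rowStat(bl$M, hyper), hyper$delta)
      penO <- penO + bl$l * sum(r)
      penS <- penS + bl$l * sum((rowSums(bl$M^2) + r^2) / (2 * r))
    }
  }
  c(objective = base + penO, surrogate = base + penS)
}

## type "objective": delta-floored row-structured penalty as the model
## states it. type "surrogate": the quadratic majorizer the closed-form
## updates minimize blockwise, evaluated self-consistently; descent is
## audited on this trace.
.evalObjective <- function(prep, par, hyper, type = c("objective", "surrogate")) {
  type <- match.arg(type)
  val <- .dataFit(prep, par, hyper) + .gwasFit(prep, par, hyper)
  for (s in seq_len(prep$L)) {
    blocks <- .penaltyBlocks(par, hyper, s)
    for (bl in list(list(M = blocks$P, l = hyper$lambdaP),
                    list(M = blocks$Q, l = hyper$lambdaQ))) {
      r <- pmax(.rowStat(bl$M, hyper), hyper$delta)
      val <- val + if (type == "objective") bl$l * sum(r)
        else bl$l * sum((rowSums(bl$M^2) + r^2) / (2 * r))
    }
  }
  val
}

## Fixed-weight smooth objective: the quadratic subproblem each closed-form
## update solves exactly, with the reweighting diagonals frozen at D. Used
## by the stationarity audits.
.fixedDObjective <- function(prep, par, hyper, Dfrozen) {
  val <- .dataFit(prep, par, hyper) + .gwasFit(prep, par, hyper)
  for (s in seq_len(prep$L)) {
    blocks <- .penaltyBlocks(par, hyper, s)
    val <- val +
      hyper$lambdaP * sum(Dfrozen[[s]]$Dp * rowSums(blocks$P^2)) +
      hyper$lambdaQ * sum(Dfrozen[[s]]$Dq * rowSums(blocks$Q^2))
  }
  val
}

## ---- engine ------------------------------------------------------------

## one full pass of Algorithm-style updates: aging effects, then per stage
## the joint GWAS effects and the genetic intercept/slope blocks
.oneIteration <- function(prep, par, hyper, bootstrap = FALSE) {
  par$bootstrap <- bootstrap
  par <- .updateAging(prep, par, hyper)
  for (s in seq_len(prep$L)) {
    if (hyper$useGwas) par$u[[s]] <- .updateU(prep, par, hyper, s)
    par$W[[s]] <- .updateW(prep, par, hyper, s)
    par$V[[s]] <- .updateV(prep, par, hyper, s)
  }
  par$bootstrap <- FALSE
  par
}

.mscolorEngine <- function(prep, hyper, share = TRUE, maxIter = 200L,
                           tol = 1e-5, init = "zeros", seed = NULL,
                           par0 = NULL, bootstrap = TRUE) {
  warm <- !is.null(par0)
  par <- if (warm) par0 else .initParams(prep, share, init, seed)
  L <- prep$L
  objTrace <- numeric(0)
  surTrace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Wold <- par$W; Vold <- par$V
    # a cold all-zero start with bootstrap = TRUE runs its first iteration
    # with identity reweighting (a ridge step): the delta-floored weights
    # of an all-zero block would otherwise pin the iterate at the spurious
    # zero fixed point. bootstrap = FALSE is the scheme exactly as printed.
    par <- .oneIteration(prep, par, hyper,
                         bootstrap = bootstrap && it == 1L && !warm &&
                           init == "zeros")
    both <- .evalBothObjectives(prep, par, hyper)
    objTrace[it] <- both[[1L]]
    surTrace[it] <- both[[2L]]
    if (it > 1L) {
      inc <- surTrace[it] - surTrace[it - 1L]
      if (inc > 1e-3 * max(abs(surTrace[1L]), 1))
        stop(sprintf(paste0(
          "surrogate objective increased at iteration %d ",
          "(%.10g -> %.10g, rise %.3e): solver divergence"),
          it, surTrace[it - 1L], surTrace[it], inc))
    }
    dW <- max(vapply(seq_len(L), function(s)
      max(abs(par$W[[s]] - Wold[[s]])), numeric(1)))
    dV <- max(vapply(seq_len(L), function(s)
      max(abs(par$V[[s]] - Vold[[s]])), numeric(1)))
    if (dW <= tol && dV <= tol) { converged <- TRUE; break }
  }
  par$bootstrap <- NULL
  list(par = par, objectiveTrace = objTrace, surrogateTrace = surTrace,
       converged = converged, nIter = it)
}

.makeHyper <- function(gG, gA, lambdaP, lambdaQ, tau, delta, ridge, penalty,
                       summary = NULL) {
  useGwas <- tau > 0 && !is.null(summary)
  list(gG = gG, gA = gA, lambdaP = lambdaP, lambdaQ = lambdaQ, tau = tau,
       delta = delta, ridge = ridge, penalty = penalty, useGwas = useGwas,
       beta = if (useGwas) summary@beta else NULL,
       sigma = if (useGwas) summary@sigma else NULL,
       nRef = if (useGwas) summary@nRef else NULL)
}

## ---- user-facing fits --------------------------------------------------

#' Fit the multi-stage collaborative longitudinal model
#'
#' Jointly models staged disease-progression trajectories and selects the
#' genetic variants underpinning them. Per stage s and visit k the model is
#' \deqn{Z_{ks} = \gamma (X_s W_s + X_s V_s t_{ks}) +
#'       (1-\gamma)(A_s + B_s t_{ks}) + E}
#' with shared population aging effects A, B over the subject registry,
#' per-stage genetic intercept and slope effect matrices W_s, V_s, and a
#' per-stage joint GWAS effect vector u_s tied to the external summary
#' statistics through \eqn{\tau (n_{ref}-1)(u' \Sigma u - 2 u' \beta)}.
#' Rows of the stacked blocks P_s = \[u_s W_s\] and Q_s = \[u_s V_s\] are
#' selected jointly through an l-infinity,1 penalty, solved by alternating
#' closed-form updates with iterative diagonal reweighting.
#'
#' Iteration stops when the largest absolute coefficient change of both W
#' and V falls below `tol`, or after `maxIter` iterations.
#'
#' @param data a [LongitudinalDataset-class].
#' @param summary a [HarmonizedSummary-class] aligned to `data`'s SNP panel
#'   (see [harmonizeSummary()]); may be NULL when `tau = 0`.
#' @param gamma weight of the genetic term versus the aging term, in
#'   \[0, 1\].
#' @param lambdaP,lambdaQ nonnegative sparsity weights for the intercept
#'   (P) and slope (Q) blocks.
#' @param tau weight of the GWAS collaboration term (0 disables it).
#' @param maxIter,tol iteration cap and coefficient-change stopping
#'   tolerance.
#' @param delta smoothing floor of the reweighting diagonals.
#' @param ridge diagonal loading of the summary-statistic solve.
#' @param shareAging share A and B across stages through the subject
#'   registry (the collaborative model's form); `FALSE` gives independent
#'   per-stage aging effects.
#' @param standardize standardize genotypes (per stage) and QTs (globally)
#'   before fitting.
#' @param init `"zeros"` (deterministic, default) or `"random"`.
#' @param seed integer seed used only for random initialization.
#' @param qtStats,genoStats optional pre-computed standardization
#'   statistics (training-fold statistics during cross-validation).
#' @param gwasN which cohort size supplies the (n - 1) scale of the GWAS
#'   collaboration term and its reweighting: the reference panel
#'   (`"ref"`, default — the panel is what sets the scale of the LD
#'   matrix) or the GWAS cohort (`"gwas"`).
#' @param bootstrap run the first iteration from a cold zero start with
#'   identity reweighting (a ridge step) so the iterate escapes the
#'   spurious all-zero fixed point of the delta-floored weights (default).
#'   `FALSE` runs the reweighted scheme exactly as printed, whose descent
#'   from a zero start is monotone but which cannot leave the zero state
#'   once the weights have collapsed; see the methods vignette.
#'
#' @return A [MscolorFit-class].
#' @export
fitMSColoR <- function(data, summary = NULL, gamma = 0.5,
                       lambdaP = 1, lambdaQ = 1, tau = 1,
                       maxIter = 200L, tol = 1e-5, delta = 1e-8,
                       ridge = 1e-3, shareAging = TRUE, standardize = TRUE,
                       init = c("zeros", "random"), seed = 1L,
                       qtStats = NULL, genoStats = NULL, bootstrap = TRUE,
                       gwasN = c("ref", "gwas")) {
  init <- match.arg(init)
  gwasN <- match.arg(gwasN)
  stopifnot(is(data, "LongitudinalDataset"))
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  if (lambdaP < 0 || lambdaQ < 0) stop("lambdas must be nonnegative")
  if (tol <= 0 || delta <= 0) stop("'tol' and 'delta' must be positive")
  if (tau > 0 && is.null(summary))
    stop("the collaborative GWAS term needs harmonized summary statistics: ",
         "supply 'summary' (see harmonizeSummary()) or set tau = 0")
  if (!is.null(summary) && !identical(summary@snpIds, snpIds(data)))
    stop("summary statistics are not aligned to the dataset's SNP panel; ",
         "run harmonizeSummary() against these genotypes first")
  prep <- .prepareStages(data, standardize, qtStats, genoStats)
  hyper <- .makeHyper(gG = gamma, gA = 1 - gamma, lambdaP, lambdaQ, tau,
                      delta, ridge, penalty = "linf", summary = summary)
  if (hyper$useGwas && gwasN == "gwas") hyper$nRef <- summary@nGwas
  res <- .mscolorEngine(prep, hyper, share = shareAging,
                        maxIter = as.integer(maxIter), tol = tol,
                        init = init, seed = seed, bootstrap = bootstrap)
  ctl <- list(gamma = gamma, lambdaP = lambdaP, lambdaQ = lambdaQ, tau = tau,
              maxIter = maxIter, tol = tol, delta = delta, ridge = ridge,
              shareAging = shareAging, standardize = standardize,
              init = init, seed = seed, bootstrap = bootstrap)
  new("MscolorFit",
      A = if (shareAging) res$par$A else matrix(0, 0, 0),
      B = if (shareAging) res$par$B else matrix(0, 0, 0),
      Astage = if (shareAging) list() else res$par$Astage,
      Bstage = if (shareAging) list() else res$par$Bstage,
      W = res$par$W, V = res$par$V, u = res$par$u,
      gamma = gamma, lambdaP = lambdaP, lambdaQ = lambdaQ, tau = tau,
      objectiveTrace = res$objectiveTrace,
      surrogateTrace = res$surrogateTrace,
      converged = res$converged, nIter = res$nIter,
      subjectRegistry = prep$registry,
      snpIds = prep$snpIds, qtNames = prep$qtNames,
      stageSubjects = prep$stageSubjects,
      prepared = list(prep = prep, hyper = hyper),
      control = ctl)
}

#' Evaluate the model objective of a fit
#'
#' Recomputes the fitted objective — stage-wise residual sums of squares,
#' the GWAS collaboration term (up to its unknown additive constant y'y),
#' and the row-sparsity penalties — either as stated by the model
#' (`surrogate = FALSE`, delta-floored l-infinity,1 penalty) or as the
#' quadratic surrogate the alternating updates minimize blockwise
#' (`surrogate = TRUE`).
#'
#' @param fit a [MscolorFit-class].
#' @param params optional list with elements among A, B, Astage, Bstage, W,
#'   V, u overriding the fitted values (used for audits of the solver).
#' @param surrogate logical.
#' @return scalar objective value.
#' @export
mscolorObjective <- function(fit, params = NULL, surrogate = FALSE) {
  stopifnot(is(fit, "MscolorFit"))
  prep <- fit@prepared$prep
  hyper <- fit@prepared$hyper
  par <- list(share = fit@control$shareAging,
              A = fit@A, B = fit@B, Astage = fit@Astage, Bstage = fit@Bstage,
              W = fit@W, V = fit@V, u = fit@u)
  if (!is.null(params)) par[names(params)] <- params
  .evalObjective(prep, par, hyper,
                 type = if (surrogate) "surrogate" else "objective")
}

#' Fitted stage trajectories
#'
#' Returns the model's fitted QT matrix for one stage at an arbitrary
#' within-stage time t (months since the stage's first visit):
#' \eqn{\gamma (X_s W_s + X_s V_s t) + (1-\gamma)(A_s + B_s t)}, on the
#' standardized QT scale the model was fitted on.
#'
#' @param object a [MscolorFit-class].
#' @param stage integer stage index.
#' @param t within-stage time in months (scalar).
#' @param ... unused.
#' @return numeric matrix, stage subjects x QTs.
#' @export
setMethod("predict", "MscolorFit", function(object, stage, t = 0, ...) {
  L <- length(object@W)
  if (stage < 1L || stage > L) stop("unknown stage: ", stage)
  prep <- object@prepared$prep
  sg <- prep$stages[[stage]]
  g <- object@gamma
  if (object@control$shareAging) {
    As <- object@A[sg$idx, , drop = FALSE]
    Bs <- object@B[sg$idx, , drop = FALSE]
  } else {
    As <- object@Astage[[stage]]; Bs <- object@Bstage[[stage]]
  }
  g * (sg$X %*% object@W[[stage]] + sg$X %*% object@V[[stage]] * t) +
    (1 - g) * (As + Bs * t)
})
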