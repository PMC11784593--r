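# Shared fixtures and independent oracles for the test suite.

# small study configurations used across tests; sizes chosen so a single
# fit runs in well under a second
tinyConfig <- function(seed = 1, ...) {
  defaults <- list(nPerStage = c(30L, 30L, 30L), d = 12L, nCausal = 3L,
                   c = 2L, nGwas = 3000L, nRef = 300L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

tinyStudy <- function(seed = 1, ...) simulateStudy(tinyConfig(seed, ...))

# single-stage dataset with exact linear structure Z = X W* + X V* t (+ A,B
# terms when gammaStar < 1); genotype pre-standardized so the model class
# reproduces it exactly
linearStage <- function(seed, n = 40, d = 6, cc = 3, times = c(0, 6, 12),
                        noise = 0, Wstar = NULL, Vstar = NULL) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * d), n, d))
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  if (is.null(Wstar)) Wstar <- matrix(rnorm(d * cc, sd = 0.5), d, cc)
  if (is.null(Vstar)) Vstar <- matrix(rnorm(d * cc, sd = 0.05), d, cc)
  qts <- array(0, c(length(times), n, cc))
  for (k in seq_along(times))
    qts[k, , ] <- X %*% Wstar + X %*% Vstar * times[k] +
      matrix(rnorm(n * cc, sd = noise), n, cc)
  sd <- StageData(stageIndex = 1L, subjectIds = sprintf("S%03d", seq_len(n)),
                  genotype = X, qts = qts, times = times)
  list(data = LongitudinalDataset(list(sd)), X = X, W = Wstar, V = Vstar)
}

# the engine-internal parameter list of a fitted collaborative model
parOf <- function(fit) {
  list(share = fit@control$shareAging, A = fit@A, B = fit@B,
       Astage = fit@Astage, Bstage = fit@Bstage,
       W = fit@W, V = fit@V, u = fit@u)
}

# loop-based oracles (deliberately naive)
loopLinf1 <- function(M) {
  tot <- 0
  for (i in seq_len(nrow(M))) {
    mx <- 0
    for (j in seq_len(ncol(M))) mx <- max(mx, abs(M[i, j]))
    tot <- tot + mx
  }
  tot
}

loopL21 <- function(M) {
  tot <- 0
  for (i in seq_len(nrow(M))) tot <- tot + sqrt(sum(M[i, ]^2))
  tot
}

loopAuc <- function(score, labels) {
  pos <- score[labels]; neg <- score[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# central finite differences of f at x
numGrad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# flatten/unflatten the full parameter set of a shared-aging collaborative
# fit, for the generic-minimizer oracle
flattenPar <- function(fit) {
  c(fit@A, fit@B, unlist(fit@W), unlist(fit@V), unlist(fit@u))
}

unflattenPar <- function(x, fit) {
  nreg <- length(fit@subjectRegistry)
  cc <- length(fit@qtNames); d <- length(fit@snpIds); L <- length(fit@W)
  i <- 0L
  take <- function(n) { out <- x[i + seq_len(n)]; i <<- i + n; out }
  A <- matrix(take(nreg * cc), nreg, cc)
  B <- matrix(take(nreg * cc), nreg, cc)
  W <- lapply(seq_len(L), function(s) matrix(take(d * cc), d, cc))
  V <- lapply(seq_len(L), function(s) matrix(take(d * cc), d, cc))
  u <- lapply(seq_len(L), function(s) take(d))
  list(A = A, B = B, W = W, V = V, u = u)
}

# analytic gradient of the quadratic-surrogate objective at a flattened
# parameter vector (piecewise-smooth: the row-max term contributes only
# through its achieving entry). Verified against numGrad in the tests.
surrogateGrad <- function(x, fit) {
  par <- unflattenPar(x, fit)
  prep <- fit@prepared$prep
  hyper <- fit@prepared$hyper
  gG <- hyper$gG; gA <- hyper$gA
  nreg <- length(fit@subjectRegistry)
  cc <- prep$cc; d <- prep$d; L <- prep$L
  gA_ <- matrix(0, nreg, cc); gB_ <- matrix(0, nreg, cc)
  gW <- lapply(seq_len(L), function(s) matrix(0, d, cc))
  gV <- lapply(seq_len(L), function(s) matrix(0, d, cc))
  gu <- lapply(seq_len(L), function(s) numeric(d))
  for (s in seq_len(L)) {
    sg <- prep$stages[[s]]
    As <- par$A[sg$idx, , drop = FALSE]; Bs <- par$B[sg$idx, , drop = FALSE]
    G <- sg$X %*% par$W[[s]]; H <- sg$X %*% par$V[[s]]
    for (k in seq_len(sg$m)) {
      tk <- sg$t[k]
      R <- sg$Z[[k]] - gG * (G + H * tk) - gA * (As + Bs * tk)
      gA_[sg$idx, ] <- gA_[sg$idx, ] - 2 * gA * R
      gB_[sg$idx, ] <- gB_[sg$idx, ] - 2 * gA * tk * R
      gW[[s]] <- gW[[s]] - 2 * gG * crossprod(sg$X, R)
      gV[[s]] <- gV[[s]] - 2 * gG * tk * crossprod(sg$X, R)
    }
    if (hyper$useGwas) {
      gu[[s]] <- gu[[s]] + 2 * hyper$tau * (hyper$nRef - 1) *
        drop(hyper$sigma %*% par$u[[s]] - hyper$beta)
    }
    # surrogate penalty gradient per row of P = [u W], Q = [u V]
    penGrad <- function(M, lam) {
      gM <- matrix(0, nrow(M), ncol(M))
      for (i in seq_len(nrow(M))) {
        p <- M[i, ]
        mraw <- max(abs(p))
        mt <- max(mraw, hyper$delta)
        gM[i, ] <- lam * p / mt
        if (mraw > hyper$delta) {
          jstar <- which.max(abs(p))[1L]
          a2 <- sum(p^2)
          gM[i, jstar] <- gM[i, jstar] +
            lam * sign(p[jstar]) * (mt^2 - a2) / (2 * mt^2)
        }
      }
      gM
    }
    P <- cbind(par$u[[s]], par$W[[s]]); Q <- cbind(par$u[[s]], par$V[[s]])
    gP <- penGrad(P, fit@lambdaP); gQ <- penGrad(Q, fit@lambdaQ)
    gu[[s]] <- gu[[s]] + gP[, 1L] + gQ[, 1L]
    gW[[s]] <- gW[[s]] + gP[, -1L, drop = FALSE]
    gV[[s]] <- gV[[s]] + gQ[, -1L, drop = FALSE]
  }
  c(gA_, gB_, unlist(gW), unlist(gV), unlist(gu))
}
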