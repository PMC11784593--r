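# Block-update correctness: each closed-form update must zero the gradient
# of the objective it minimizes (the full objective for the aging blocks,
# the fixed-reweighting quadratic for the penalized blocks), verified by
# central finite differences on seeded instances.

test_that("aging-effect updates zero the objective gradient", {
  for (seed in 1:3) {
    st <- tinyStudy(seed, d = 8L)
    fit <- fitMSColoR(st$data, st$harmonized, lambdaP = 0.5, lambdaQ = 0.5,
                      maxIter = 5, ridge = 0)
    prep <- fit@prepared$prep
    hyper <- fit@prepared$hyper
    # gradient is checked right after each block update, holding the rest
    parA <- mscolor:::.updateAging(prep, parOf(fit), hyper, which = "A")
    gradA <- numGrad(function(a) {
      p <- parA; p$A <- matrix(a, nrow(parA$A), ncol(parA$A))
      mscolor:::.evalObjective(prep, p, hyper, "objective")
    }, as.numeric(parA$A))
    expect_lt(max(abs(gradA)), 1e-6)
    parB <- mscolor:::.updateAging(prep, parA, hyper, which = "B")
    gradB <- numGrad(function(b) {
      p <- parB; p$B <- matrix(b, nrow(parB$B), ncol(parB$B))
      mscolor:::.evalObjective(prep, p, hyper, "objective")
    }, as.numeric(parB$B))
    expect_lt(max(abs(gradB)), 1e-6)
  }
})

test_that("penalized block updates zero the fixed-weight gradient", {
  for (seed in 1:3) {
    st <- tinyStudy(seed, d = 8L)
    fit <- fitMSColoR(st$data, st$harmonized, lambdaP = 1, lambdaQ = 1,
                      maxIter = 4, ridge = 0)
    prep <- fit@prepared$prep
    hyper <- fit@prepared$hyper
    par <- parOf(fit)
    for (s in seq_len(prep$L)) {
      frozen <- lapply(seq_len(prep$L), function(ss) {
        bl <- mscolor:::.penaltyBlocks(par, hyper, ss)
        list(Dp = reweightDiag(bl$P, hyper$delta, hyper$penalty),
             Dq = reweightDiag(bl$Q, hyper$delta, hyper$penalty))
      })
      Wnew <- mscolor:::.updateW(prep, par, hyper, s)
      pW <- par; pW$W[[s]] <- Wnew
      gW <- numGrad(function(w) {
        p <- pW; p$W[[s]] <- matrix(w, prep$d, prep$cc)
        mscolor:::.fixedDObjective(prep, p, hyper, frozen)
      }, as.numeric(Wnew))
      expect_lt(max(abs(gW)), 1e-6)

      Vnew <- mscolor:::.updateV(prep, par, hyper, s)
      pV <- par; pV$V[[s]] <- Vnew
      gV <- numGrad(function(v) {
        p <- pV; p$V[[s]] <- matrix(v, prep$d, prep$cc)
        mscolor:::.fixedDObjective(prep, p, hyper, frozen)
      }, as.numeric(Vnew))
      expect_lt(max(abs(gV)), 1e-6)

      unew <- mscolor:::.updateU(prep, par, hyper, s)
      pU <- par; pU$u[[s]] <- unew
      gU <- numGrad(function(u) {
        p <- pU; p$u[[s]] <- u
        mscolor:::.fixedDObjective(prep, p, hyper, frozen)
      }, unew)
      expect_lt(max(abs(gU)), 1e-6)
    }
  }
})

test_that("W update reduces to OLS without penalty or aging", {
  ls <- linearStage(21, n = 40, d = 6, cc = 3, times = 0, noise = 0.3)
  fit <- fitMSColoR(ls$data, NULL, gamma = 1, lambdaP = 0, lambdaQ = 1,
                    tau = 0, standardize = FALSE, maxIter = 10)
  Z <- ls$data@stages[[1]]@qts[1, , ]
  ols <- qr.solve(ls$X, Z)
  expect_lt(max(abs(geneticIntercepts(fit, 1) - ols)), 1e-10)
  expect_lt(max(abs(geneticSlopes(fit, 1))), 1e-12)  # t = 0: no slope info
})

test_that("overwhelming penalties drive coefficients to zero", {
  st <- tinyStudy(4)
  fit <- fitMSColoR(st$data, st$harmonized, lambdaP = 1e9, lambdaQ = 1e9,
                    maxIter = 50)
  for (s in 1:3) {
    expect_lt(max(abs(geneticIntercepts(fit, s))), 1e-6)
    expect_lt(max(abs(geneticSlopes(fit, s))), 1e-6)
    expect_lt(max(abs(jointSnpEffects(fit, s))), 1e-6)
  }
})

test_that("joint-effect update returns beta under identity LD", {
  st <- tinyStudy(5, d = 6L)
  hs <- st$harmonized
  hs@sigma <- diag(length(hs@snpIds))
  fit <- fitMSColoR(st$data, hs, lambdaP = 0, lambdaQ = 0, maxIter = 3,
                    ridge = 0)
  expect_equal(jointSnpEffects(fit, 1), hs@beta, tolerance = 1e-10)
})

test_that("penalized solves agree with a generic dense solver", {
  st <- tinyStudy(6, d = 10L)
  fit <- fitMSColoR(st$data, st$harmonized, lambdaP = 2, lambdaQ = 3,
                    maxIter = 6, ridge = 1e-3)
  prep <- fit@prepared$prep
  hyper <- fit@prepared$hyper
  par <- parOf(fit)
  s <- 2L
  sg <- prep$stages[[s]]
  ag <- mscolor:::.stageAging(par, prep, s)
  Dp <- reweightDiag(mscolor:::.penaltyP(par, hyper, s), hyper$delta, "linf")
  rhs <- hyper$gG * (sg$SZ - hyper$gG * sg$stm * sg$XtX %*% par$V[[s]] -
                       crossprod(sg$X, hyper$gA * (sg$m * ag$A +
                                                     sg$stm * ag$B)))
  M <- hyper$gG^2 * sg$m * sg$XtX + diag(hyper$lambdaP * Dp, prep$d)
  expect_lt(max(abs(mscolor:::.updateW(prep, par, hyper, s) -
                      solve(M, rhs))), 1e-10)

  Dq <- reweightDiag(mscolor:::.penaltyQ(par, hyper, s), hyper$delta, "linf")
  Mu <- hyper$sigma + diag((hyper$lambdaP * Dp + hyper$lambdaQ * Dq) /
                             (hyper$tau * (hyper$nRef - 1)) +
                             hyper$ridge, prep$d)
  expect_lt(max(abs(mscolor:::.updateU(prep, par, hyper, s) -
                      drop(solve(Mu, hyper$beta)))), 1e-10)
})

test_that("the GWAS-term scale can follow either cohort size", {
  st <- tinyStudy(8, d = 6L)
  fRef <- fitMSColoR(st$data, st$harmonized, lambdaP = 5, lambdaQ = 5,
                     maxIter = 20)
  fGwas <- fitMSColoR(st$data, st$harmonized, lambdaP = 5, lambdaQ = 5,
                      maxIter = 20, gwasN = "gwas")
  # a larger n shrinks the reweighting relative to the LD term, so the
  # joint effects are less penalized
  expect_gt(mean(abs(jointSnpEffects(fGwas, 1))),
            mean(abs(jointSnpEffects(fRef, 1))))
})

test_that("singular unpenalized systems fail with actionable advice", {
  # more SNPs than subjects and no penalty: the W solve must be singular
  st <- tinyStudy(7, nPerStage = c(8L, 8L, 8L), d = 20L, nCausal = 2L)
  expect_error(
    fitMSColoR(st$data, st$harmonized, lambdaP = 0, lambdaQ = 0,
               maxIter = 5),
    "lambdaP")
})
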