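test_that("noiseless linear data are interpolated at lambda = 0", {
  ls <- linearStage(11, n = 50, d = 6, cc = 3, times = c(0, 6, 12),
                    noise = 0)
  fit <- fitMSColoR(ls$data, NULL, gamma = 1, lambdaP = 0, lambdaQ = 0,
                    tau = 0, standardize = FALSE, maxIter = 200, tol = 1e-10)
  for (k in 1:3) {
    t <- c(0, 6, 12)[k]
    expect_lt(max(abs(predict(fit, 1, t) - ls$data@stages[[1]]@qts[k, , ])),
              1e-6)
  }
  expect_lt(max(abs(geneticIntercepts(fit, 1) - ls$W)), 1e-6)
  expect_lt(max(abs(geneticSlopes(fit, 1) - ls$V)), 1e-6)
})

test_that("the surrogate objective is non-increasing across iterations", {
  # the printed scheme (zeros init): strict descent; the bootstrapped
  # default may creep by ~1e-5 relative in collapse regimes (documented),
  # so for it only the divergence guard and net decrease are asserted
  lams <- c(0.01, 0.1, 1, 10, 100)
  for (seed in 1:10) {
    st <- tinyStudy(seed, nPerStage = c(50L, 50L, 50L), d = 20L,
                    nCausal = 4L, c = 3L)
    lam <- lams[(seed - 1L) %% length(lams) + 1L]
    fit <- fitMSColoR(st$data, st$harmonized, lambdaP = lam, lambdaQ = lam,
                      maxIter = 60, bootstrap = FALSE)
    tr <- surrogateTrace(fit)
    expect_lte(max(c(diff(tr), -Inf)), 1e-9 * abs(tr[1]))

    fitB <- fitMSColoR(st$data, st$harmonized, lambdaP = lam, lambdaQ = lam,
                       maxIter = 60)
    trB <- surrogateTrace(fitB)
    expect_lte(tail(trB, 1), trB[1] + 1e-9 * abs(trB[1]))
  }
})

test_that("predictions are affine in time", {
  st <- tinyStudy(12)
  fit <- fitMSColoR(st$data, st$harmonized, maxIter = 10)
  p0 <- predict(fit, 2, 0); p6 <- predict(fit, 2, 6); p3 <- predict(fit, 2, 3)
  expect_lt(max(abs(p0 + p6 - 2 * p3)), 1e-10)
  expect_error(predict(fit, 9, 0), "stage")
})

test_that("SNP permutation equivariance", {
  st <- tinyStudy(13, d = 10L)
  fit1 <- fitMSColoR(st$data, st$harmonized, maxIter = 25)
  set.seed(77)
  perm <- sample(10L)
  stagesP <- lapply(st$data@stages, function(sd)
    StageData(sd@stageIndex, sd@subjectIds,
              sd@genotype[, perm, drop = FALSE], sd@qts,
              times = sd@times + sd@timeOffset, qtNames = sd@qtNames,
              snpIds = sd@snpIds[perm]))
  dataP <- LongitudinalDataset(stagesP, covariates(st$data))
  hsP <- st$harmonized
  hsP@snpIds <- hsP@snpIds[perm]
  hsP@beta <- hsP@beta[perm]
  hsP@sigma <- hsP@sigma[perm, perm]
  fit2 <- fitMSColoR(dataP, hsP, maxIter = 25)
  expect_equal(objectiveTrace(fit1), objectiveTrace(fit2), tolerance = 1e-9)
  expect_equal(geneticIntercepts(fit1, 1)[perm, ],
               geneticIntercepts(fit2, 1), tolerance = 1e-9)
  expect_equal(jointSnpEffects(fit1, 3)[perm], jointSnpEffects(fit2, 3),
               tolerance = 1e-9)
})

test_that("row sparsity of the genetic blocks grows with lambda", {
  st <- tinyStudy(14, nPerStage = c(60L, 60L, 60L), d = 20L, nCausal = 4L)
  nActive <- sapply(10^(-2:4), function(lam) {
    fit <- fitMSColoR(st$data, st$harmonized, lambdaP = lam, lambdaQ = lam,
                      maxIter = 60)
    sum(sapply(1:3, function(s)
      sum(pmax(mscolor:::.rowMaxAbs(geneticIntercepts(fit, s)),
               mscolor:::.rowMaxAbs(geneticSlopes(fit, s))) > 1e-4)))
  })
  expect_true(all(diff(nActive) <= 0))
})

test_that("disabling the GWAS term reproduces the multi-stage baseline", {
  st <- tinyStudy(15)
  f1 <- fitMSColoR(st$data, NULL, tau = 0, shareAging = FALSE,
                   lambdaP = 1, lambdaQ = 1, maxIter = 40)
  f2 <- fitMSMML(st$data, 1, 1, gamma = 0.5, maxIter = 40)
  for (s in 1:3) {
    expect_lt(max(abs(geneticIntercepts(f1, s) - f2@params$W[[s]])), 1e-6)
    expect_lt(max(abs(geneticSlopes(f1, s) - f2@params$V[[s]])), 1e-6)
    expect_lt(max(abs(f1@Astage[[s]] - f2@params$Astage[[s]])), 1e-6)
  }
  expect_equal(objectiveTrace(f1), objectiveTrace(f2), tolerance = 1e-10)
})

test_that("with one stage and no penalty the mixed-effects fits coincide", {
  # both parameterizations span the same per-subject-line space, so the
  # unpenalized fitted values agree even though coefficients are scaled
  ls <- linearStage(16, n = 30, d = 4, cc = 2, times = c(0, 6, 12),
                    noise = 0.5)
  fc <- fitMSColoR(ls$data, NULL, gamma = 0.5, tau = 0, shareAging = FALSE,
                   lambdaP = 0, lambdaQ = 0, maxIter = 3000, tol = 1e-12)
  fs <- fitSMML(ls$data, 0, 0, maxIter = 3000, tol = 1e-12)
  for (k in 1:3) {
    t <- c(0, 6, 12)[k]
    pc <- predict(fc, 1, t)
    ps <- predict(fs, t = t)
    expect_lt(max(abs(pc - ps)), 1e-6)
  }
})

test_that("converged flag and stopping rule behave as documented", {
  st <- tinyStudy(18)
  fit <- fitMSColoR(st$data, st$harmonized, lambdaP = 100, lambdaQ = 100,
                    maxIter = 200)
  expect_true(isConverged(fit))
  expect_lt(fit@nIter, 200L)
  fit2 <- fitMSColoR(st$data, st$harmonized, lambdaP = 0.01, lambdaQ = 0.01,
                     maxIter = 3)
  expect_false(isConverged(fit2))
  expect_equal(fit2@nIter, 3L)
})

test_that("the fit refuses unusable inputs with clear messages", {
  st <- tinyStudy(19)
  expect_error(fitMSColoR(st$data, NULL), "summary")
  hsBad <- st$harmonized
  hsBad@snpIds <- rev(hsBad@snpIds)
  expect_error(fitMSColoR(st$data, hsBad), "aligned")
  expect_error(fitMSColoR(st$data, st$harmonized, gamma = 1.2), "gamma")
})
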