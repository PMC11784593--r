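test_that("column standardization centers, scales and inverts exactly", {
  s <- standardizeColumns(cbind(a = c(-1, 0, 1)))
  expect_equal(drop(s$x), c(-1, 0, 1))
  expect_equal(unname(s$means), 0)
  expect_equal(unname(s$scales), 1)

  s2 <- standardizeColumns(cbind(a = c(2, 4, 6)))
  expect_equal(drop(s2$x), c(-1, 0, 1))

  set.seed(7)
  m <- matrix(rnorm(500, mean = 3, sd = 2), 100, 5)
  s3 <- standardizeColumns(m)
  expect_lt(max(abs(colMeans(s3$x))), 1e-12)
  expect_lt(max(abs(apply(s3$x, 2, sd) - 1)), 1e-12)

  back <- unstandardizeColumns(s3$x, s3$means, s3$scales)
  expect_lt(max(abs(back - m)) / max(abs(m)), 1e-10)
})

test_that("zero-variance columns are rejected by name or dropped on request", {
  m <- cbind(ok = rnorm(10), flat = rep(2, 10))
  expect_error(standardizeColumns(m), "flat")
  expect_warning(s <- standardizeColumns(m, dropConstant = TRUE), "flat")
  expect_equal(colnames(s$x), "ok")
  expect_equal(s$kept, 1L)
})

test_that("covariate residualization removes exactly the named effects", {
  set.seed(42)
  n <- 80
  cov <- data.frame(age = rnorm(n, 75, 5),
                    gender = sample(c("M", "F"), n, TRUE))
  # QT identical to a covariate: residuals vanish
  r <- residualizeCovariates(cbind(q = cov$age), cov, "age")
  expect_lt(max(abs(r)), 1e-10)

  # intercept only: residuals are the centered QT
  q <- cbind(q = rnorm(n, mean = 5))
  r2 <- residualizeCovariates(q, cov, character(0))
  expect_equal(as.numeric(r2), as.numeric(scale(q, scale = FALSE)),
               tolerance = 1e-12)

  # QT = 2*age + noise: residual variance matches the generating noise
  eps <- rnorm(n, sd = 0.5)
  r3 <- residualizeCovariates(cbind(q = 2 * cov$age + eps), cov, "age")
  expect_equal(var(drop(r3)), var(eps), tolerance = 0.05)

  # residuals orthogonal to every covariate column (model matrix)
  r4 <- residualizeCovariates(cbind(q = rnorm(n)), cov, c("age", "gender"))
  mm <- model.matrix(~ age + gender, cov)
  expect_lt(max(abs(crossprod(mm, r4))), 1e-8)
})

test_that("residualization rejects rank-deficient covariates", {
  cov <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(residualizeCovariates(cbind(q = rnorm(10)), cov, c("a", "b")),
               "rank")
})

test_that("StageData validates its dimensions and ordering", {
  n <- 5; d <- 3; cc <- 2
  qts <- array(rnorm(2 * n * cc), c(2, n, cc))
  X <- matrix(rbinom(n * d, 2, .3), n, d)
  sd1 <- StageData(1L, sprintf("S%d", 1:n), X, qts, times = c(0, 6))
  expect_s4_class(sd1, "StageData")
  expect_equal(sd1@times, c(0, 6))

  # absolute times are re-coded to the stage window, offset retained
  sd2 <- StageData(2L, sprintf("S%d", 1:n), X, qts, times = c(12, 18))
  expect_equal(sd2@times, c(0, 6))
  expect_equal(sd2@timeOffset, 12)

  expect_error(StageData(1L, sprintf("S%d", 1:n), X, qts, times = c(6, 0)),
               "increasing")
  qtsNA <- qts; qtsNA[1, 1, 1] <- NA
  expect_error(StageData(1L, sprintf("S%d", 1:n), X, qtsNA, times = c(0, 6)),
               "missing")
})

test_that("LongitudinalDataset enforces a shared SNP panel and registry", {
  st <- tinyStudy(1)
  expect_s4_class(st$data, "LongitudinalDataset")
  expect_equal(nStages(st$data), 3L)
  expect_true(all(subjectIds(stageData(st$data, 2)) %in%
                    subjectIds(st$data)))

  bad <- stageData(st$data, 2)
  bad@snpIds <- rev(bad@snpIds)
  expect_error(LongitudinalDataset(list(stageData(st$data, 1), bad)),
               "identical")
})

test_that("fits are invariant to subject row order within stages", {
  st <- tinyStudy(3)
  f1 <- fitMSColoR(st$data, st$harmonized, lambdaP = 1, lambdaQ = 1,
                   maxIter = 30)
  # shuffle rows within every stage
  set.seed(99)
  shuffled <- lapply(st$data@stages, function(sd) {
    o <- sample(length(sd@subjectIds))
    StageData(sd@stageIndex, sd@subjectIds[o],
              sd@genotype[o, , drop = FALSE],
              sd@qts[, o, , drop = FALSE],
              times = sd@times + sd@timeOffset,
              qtNames = sd@qtNames, snpIds = sd@snpIds)
  })
  f2 <- fitMSColoR(LongitudinalDataset(shuffled, covariates(st$data)),
                   st$harmonized, lambdaP = 1, lambdaQ = 1, maxIter = 30)
  expect_equal(objectiveTrace(f1), objectiveTrace(f2), tolerance = 1e-10)
  expect_equal(geneticIntercepts(f1, 2), geneticIntercepts(f2, 2),
               tolerance = 1e-10)
})
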