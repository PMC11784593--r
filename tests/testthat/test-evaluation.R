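test_that("rmse matches its definition", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, 5, 7), c(1, 3, 5)), 2)
  set.seed(51)
  o <- rnorm(40); f <- rnorm(40)
  expect_equal(rmse(o, f), sqrt(sum((o - f)^2) / 40), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("fold assignment is a pure function of the id set and seed", {
  ids <- sprintf("S%03d", 1:40)
  f1 <- makeFolds(ids, 5, 9)
  f2 <- makeFolds(sample(ids), 5, 9)          # shuffled input order
  f3 <- makeFolds(c(ids, ids[1:10]), 5, 9)    # duplicated ids
  expect_identical(f1, f2)
  expect_identical(f1, f3)
  expect_equal(sort(unique(f1)), 1:5)
  expect_error(makeFolds(ids[1:3], 5, 1), "fewer")
})

test_that("selection metrics score support recovery correctly", {
  d <- 20
  ids <- paste0("snp", seq_len(d))
  mkScores <- function(w) {
    names(w) <- ids
    list(W = list(w), V = list(w))
  }
  # truth support exactly the top-k scored SNPs
  w <- c(rep(1, 5), rep(0, d - 5)) + seq(d, 1) * 1e-6
  truth <- new("SimTruth", trueA = matrix(0, 0, 0), trueB = matrix(0, 0, 0),
               trueW = list(), trueV = list(), trueU = numeric(0),
               causalSupport = c(rep(TRUE, 5), rep(FALSE, d - 5)),
               noiseSd = 0, configEcho = list())
  rep1 <- selectionMetrics(list(mkScores(w)), truth, topK = 5)
  expect_equal(rep1@auc, 1)
  expect_equal(rep1@precisionAtK, 1)
  expect_equal(rep1@ranking[1:5], ids[1:5])

  # all-zero fit: flag set, AUC undefined
  rep2 <- selectionMetrics(list(mkScores(rep(0, d))), truth)
  expect_true(rep2@allZero)
  expect_true(is.na(rep2@auc))

  # the rank-based AUC equals the brute-force pairwise count
  set.seed(52)
  sc <- runif(d)
  lab <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(mscolor:::.aucScore(sc, lab), loopAuc(sc, lab))

  # random scores at large d: AUC near 1/2
  set.seed(53)
  d2 <- 1000
  lab2 <- c(rep(TRUE, 100), rep(FALSE, 900))
  aucs <- replicate(20, mscolor:::.aucScore(runif(d2), lab2))
  se <- sqrt((100 + 900 + 1) / (12 * 100 * 900))
  expect_lt(max(abs(aucs - 0.5)), 4 * se)
})

test_that("significance banding uses the conventional thresholds", {
  expect_equal(significanceBand(c(0.049, 0.051, 0.009, 0.0009, 0.00009, 0.5)),
               c("*", "ns", "**", "***", "****", "ns"))
})

test_that("stage-contrast tests and correlations read fitted effects", {
  st <- tinyStudy(54, nPerStage = c(40L, 40L, 40L))
  fit <- fitMSColoR(st$data, st$harmonized, maxIter = 30)
  cov <- covariates(st$data)

  tests <- stageSlopeTests(fit, cov, groupBy = "diagnosis")
  expect_true(all(c("comparison", "t", "p", "band") %in% colnames(tests)))
  expect_equal(sum(tests$comparison == "between-stages"), 3L)
  expect_true(all(tests$p >= 0 & tests$p <= 1))

  # identical samples: t = 0, p = 1
  ht <- t.test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(significanceBand(ht$p.value), "ns")
  expect_equal(unname(ht$statistic), 0)

  # two seeded normals 5 sd apart at n = 100: deep in the strongest band
  set.seed(55)
  p <- t.test(rnorm(100), rnorm(100, mean = 5))$p.value
  expect_lt(p, 1e-4)

  # self-correlation: a score equal to the averaged slope gives r = 1
  eff <- mscolor:::.subjectEffects(fit, 1)
  cov2 <- data.frame(subject_id = eff$subjects,
                     self = rowMeans(eff$slope))
  tc <- trajectoryCorrelations(fit, cov2, "self")
  expect_equal(tc$r[tc$stage == 1 & tc$measure == "slope"], 1,
               tolerance = 1e-12)

  # the optional multiple-testing column is plain Benjamini-Hochberg
  tcAll <- trajectoryCorrelations(fit, covariates(st$data),
                                  c("mmse", "adas"), adjust = TRUE)
  expect_equal(tcAll$p_bh, p.adjust(tcAll$p, "BH"))

  # r agrees with the textbook formula
  set.seed(56)
  x <- rnorm(30); y <- rnorm(30)
  r <- cor.test(x, y)$estimate
  rManual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(r), rManual, tolerance = 1e-12)
})

test_that("independent scores stay within the null correlation bound", {
  st <- tinyStudy(57, nPerStage = c(100L, 100L, 100L), d = 10L)
  fit <- fitMSColoR(st$data, st$harmonized, maxIter = 15)
  eff <- mscolor:::.subjectEffects(fit, 2)
  n <- length(eff$subjects)
  ok <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    cov <- data.frame(subject_id = eff$subjects, noise = rnorm(n))
    tc <- trajectoryCorrelations(fit, cov, "noise")
    ok <- ok + all(abs(tc$r[tc$stage == 2]) < 2.5 / sqrt(n))
  }
  expect_gte(ok / 40, 0.95)
})

test_that("covariate-adjusted SNP ANOVA behaves at both extremes", {
  expect_error(anovaSnpEffect(rep(1, 30), rnorm(30),
                              data.frame(age = rnorm(30), gender = "M",
                                         handedness = "R", education = 16)),
               "variation")

  # diagnosis fully determined by genotype level
  set.seed(58)
  g <- rep(0:2, each = 20)
  cov <- data.frame(age = rnorm(60, 75, 5),
                    gender = sample(c("M", "F"), 60, TRUE),
                    handedness = sample(c("R", "L"), 60, TRUE, c(.9, .1)),
                    education = round(rnorm(60, 16, 3)))
  out <- suppressWarnings(anovaSnpEffect(g, g + 1L, cov))
  expect_lt(out$p, 1e-6)
  expect_true(out$effective)

  # null calibration: type-I rate within (0.03, 0.07) at alpha = 0.05
  set.seed(59)
  hits <- 0L
  n <- 120
  for (r in 1:1000) {
    g <- rbinom(n, 2, 0.3)
    if (length(unique(g)) < 2) next
    diag_ <- sample(1:3, n, TRUE)
    covN <- data.frame(age = rnorm(n, 75, 5),
                       gender = sample(c("M", "F"), n, TRUE),
                       handedness = sample(c("R", "L"), n, TRUE, c(.9, .1)),
                       education = round(rnorm(n, 16, 3)))
    hits <- hits + (anovaSnpEffect(g, diag_, covN)$p <= 0.05)
  }
  expect_gt(hits / 1000, 0.03)
  expect_lt(hits / 1000, 0.07)
})

test_that("nested CV is deterministic and selects from the grid", {
  st <- tinyStudy(60, nPerStage = c(40L, 40L, 40L), d = 8L, nGwas = 2000L)
  cv1 <- nestedCV(st$data, st$harmonized, method = "mscolor",
                  grid = c(0.1, 10), kOuter = 3, kInner = 2, maxIter = 25,
                  seed = 7)
  cv2 <- nestedCV(st$data, st$harmonized, method = "mscolor",
                  grid = c(0.1, 10), kOuter = 3, kInner = 2, maxIter = 25,
                  seed = 7)
  expect_identical(cv1@folds, cv2@folds)
  expect_identical(cv1@chosen, cv2@chosen)
  expect_true(all(cv1@chosen$lambda %in% c(0.1, 10)))
  expect_true(all(c("trainRmse", "testRmse") %in% colnames(cv1@folds)))

  # a one-point grid is selected trivially
  cv3 <- nestedCV(st$data, NULL, method = "msmml", grid = 1,
                  kOuter = 3, kInner = 2, maxIter = 20, seed = 7)
  expect_true(all(cv3@chosen$lambda == 1))
  expect_error(nestedCV(st$data, NULL, method = "mscolor"), "summary")
})
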