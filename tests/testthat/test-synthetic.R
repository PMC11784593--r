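test_that("simulated genotypes have binomial moments and valid values", {
  g <- simulateGenotypes(10000, 5, mafRange = c(0.5, 0.5), seed = 41)
  expect_true(all(g$genotype %in% 0:2))
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(max(abs(colMeans(g$genotype) - 1)), 3 * se * sqrt(5))

  # determinism under a fixed seed
  g1 <- simulateGenotypes(2, 1, seed = 42)
  g2 <- simulateGenotypes(2, 1, seed = 42)
  expect_identical(g1, g2)

  # no monomorphic columns even at tiny n
  g3 <- simulateGenotypes(4, 50, mafRange = c(0.05, 0.1), seed = 43)
  expect_true(all(apply(g3$genotype, 2, function(x) length(unique(x))) > 1))

  # non-ambiguous allele pairs by default
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  expect_true(all(g3$alleles$a2 != comp[g3$alleles$a1]))
})

test_that("the multi-stage generator is deterministic and consistent", {
  cfg <- tinyConfig(44)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(s1$data@stages[[2]]@qts, s2$data@stages[[2]]@qts)
  expect_identical(s1$summary@beta, s2$summary@beta)
  expect_identical(s1$truth@trueW, s2$truth@trueW)

  # causal support houses every nonzero effect row
  tr <- s1$truth
  expect_s4_class(tr, "SimTruth")
  nz <- rowSums(abs(tr@trueW[[1]])) > 0
  expect_true(all(which(nz) %in% which(causalSupport(tr))))
  expect_equal(sum(causalSupport(tr)), 3L)
})

test_that("full subject carry-over repeats the cohort across stages", {
  st <- simulateMultistage(tinyConfig(45, overlapFraction = 1,
                                      nPerStage = c(25L, 25L, 25L)))
  ids1 <- st$data@stages[[1]]@subjectIds
  expect_identical(sort(st$data@stages[[2]]@subjectIds), sort(ids1))
  expect_identical(sort(st$data@stages[[3]]@subjectIds), sort(ids1))
})

test_that("generated noise matches the configured residual sd", {
  cfg <- simConfig(nPerStage = c(200L, 200L, 200L), d = 30L, nCausal = 5L,
                   noiseSd = 0.7, seed = 46, nGwas = 1000L, nRef = 200L)
  ms <- simulateMultistage(cfg)
  tr <- ms$truth
  resid <- c()
  for (s in 1:3) {
    sd_ <- ms$data@stages[[s]]
    pos <- match(sd_@subjectIds, rownames(tr@trueA))
    Xs <- mscolor:::.genoStandardize(sd_@genotype)$x
    GW <- Xs %*% tr@trueW[[s]]; HV <- Xs %*% tr@trueV[[s]]
    Bs <- tr@trueB[pos, ] * cfg$stageSlopeProfile[s]
    for (k in seq_along(sd_@times)) {
      mu <- 0.5 * (GW + HV * sd_@times[k]) +
        0.5 * (tr@trueA[pos, ] + Bs * sd_@times[k])
      resid <- c(resid, as.numeric(sd_@qts[k, , ] - mu))
    }
  }
  expect_lt(abs(sd(resid) - 0.7) / 0.7, 0.05)
})

test_that("null-heritability GWAS yields null effect sizes", {
  cfg <- tinyConfig(47, gwasH2 = 0, d = 50L, nGwas = 5000L)
  ms <- simulateMultistage(cfg)
  gw <- simulateGwas(cfg, ms$truth)
  expect_gte(mean(abs(gw$summary@beta) < 4 / sqrt(cfg$nGwas)), 0.99)
})

test_that("the strongest causal joint effect tops the marginal scan", {
  hits <- 0L
  for (seed in 1:8) {
    cfg <- tinyConfig(seed, d = 40L, nCausal = 5L, nGwas = 50000L,
                      nRef = 200L)
    ms <- simulateMultistage(cfg)
    gw <- simulateGwas(cfg, ms$truth)
    topU <- which.max(abs(ms$truth@trueU))
    hits <- hits + (which.max(abs(gw$summary@beta)) == topU)
  }
  expect_gte(hits / 8, 0.9)
})

test_that("joint effects from a self-consistent cohort recover the truth", {
  cfg <- tinyConfig(48, d = 15L, nCausal = 4L, nGwas = 8000L, gwasH2 = 0.5)
  ms <- simulateMultistage(cfg)
  set.seed(cfg$seed + 997L)
  maf <- ms$truth@configEcho$maf
  G <- simulateGenotypes(cfg$nGwas, cfg$d, maf = maf)$genotype
  Xg <- mscolor:::.genoStandardize(G)$x
  uStar <- ms$truth@trueU
  gpart <- drop(Xg %*% uStar)
  y <- gpart + rnorm(cfg$nGwas, sd = sqrt(var(gpart)))
  beta <- marginalEffectsScan(G, y)
  u <- jointEffects(beta, estimateLD(G), ridge = 0)
  # recovered joint effects equal the OLS fit of standardized y on X
  ols <- qr.solve(Xg, drop(scale(y)))
  expect_lt(max(abs(u - ols)), 1e-8)
  # and the OLS fit tracks the generating effects up to sampling error
  expect_gt(cor(u, uStar), 0.95)
})

test_that("a noiseless flat-profile cohort is fit exactly", {
  cfg <- simConfig(nPerStage = c(60L, 60L), d = 8L, nCausal = 3L, c = 2L,
                   noiseSd = 0, stageSlopeProfile = c(1, 1),
                   nGwas = 1000L, nRef = 200L, seed = 49)
  ms <- simulateMultistage(cfg)
  fit <- fitMSColoR(ms$data, NULL, gamma = 0.5, tau = 0,
                    lambdaP = 0, lambdaQ = 0, maxIter = 4000, tol = 1e-12)
  rms <- sapply(1:2, function(s) {
    sg <- fit@prepared$prep$stages[[s]]
    sqrt(mean(sapply(seq_len(sg$m), function(k)
      (sg$Z[[k]] - predict(fit, s, sg$t[k]))^2)))
  })
  expect_lt(max(rms), 1e-6)
})

test_that("simulator invalid configurations name the offending field", {
  expect_error(simConfig(nCausal = 200L), "nCausal")
  expect_error(simConfig(stageSlopeProfile = c(1, 2)), "stageSlopeProfile")
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(overlapFraction = 1.5), "overlapFraction")
  expect_error(simConfig(gwasH2 = 1), "gwasH2")
})
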