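## Synthetic multi-stage imaging-genetics cohorts with known ground truth,
## plus a paired (much larger) GWAS cohort emitting summary statistics and
## an independent reference panel for LD estimation. The generator follows
## the model's own likelihood structure, so solver correctness and
## power/recovery claims are testable end to end without any external data.

.NONAMBIG_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.ALL_PAIRS <- rbind(.NONAMBIG_PAIRS, c("A", "T"), c("T", "A"),
                    c("C", "G"), c("G", "C"))

#' Configuration of the synthetic multi-stage study
#'
#' Returns the validated configuration of the simulator. The defaults are
#' the package's reference study: a three-stage cohort of 200 subjects per
#' stage with 80% subject carry-over between consecutive stages, 100
#' independent SNPs of which 10 are causal, 4 composite imaging QTs
#' observed at 3 visits 6 months apart per stage, and a stage slope profile
#' (1.0, 1.8, 0.7) emulating the slow/rapid/plateau pattern of
#' neurodegenerative progression. The paired GWAS cohort has 20000 subjects
#' at 30% heritability with a 500-subject reference panel. See the methods
#' vignette for the rationale behind each value.
#'
#' @param nPerStage integer vector, subjects per stage (its length sets
#'   the number of stages L).
#' @param d,nCausal SNP panel size and causal-support size.
#' @param c number of imaging QTs.
#' @param m visits per stage.
#' @param visitSpacing months between within-stage visits.
#' @param mafRange minor-allele-frequency range, in (0, 0.5\].
#' @param effectSd sd of causal genetic intercept effects (standardized QT
#'   units per standardized dosage).
#' @param slopeEffectSd sd of causal genetic slope effects (per month);
#'   scaled by `stageSlopeProfile` per stage.
#' @param stageSlopeProfile per-stage slope multipliers, length L.
#' @param agingInterceptSd sd of subject baseline aging intercepts.
#' @param agingSlopeMean,agingSlopeSd mean/sd of subject aging slopes per
#'   month (negative mean: gradual decline).
#' @param noiseSd residual sd of the observed QTs.
#' @param overlapFraction fraction of a stage's subjects carried over from
#'   the previous stage, in \[0, 1\].
#' @param nGwas,nRef GWAS-cohort and reference-panel sizes.
#' @param gwasH2 heritability of the GWAS phenotype, in \[0, 1); 0 makes
#'   the phenotype pure noise (null summary statistics).
#' @param gammaStar generative weight of the genetic versus aging terms.
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return A classed list (`"simConfig"`).
#' @export
simConfig <- function(nPerStage = c(200L, 200L, 200L), d = 100L,
                      nCausal = 10L, c = 4L, m = 3L, visitSpacing = 6,
                      mafRange = c(0.05, 0.5), effectSd = 0.5,
                      slopeEffectSd = effectSd / 12,
                      stageSlopeProfile = c(1.0, 1.8, 0.7),
                      agingInterceptSd = 1, agingSlopeMean = -0.04,
                      agingSlopeSd = 0.08, noiseSd = 1,
                      overlapFraction = 0.8, nGwas = 20000L, nRef = 500L,
                      gwasH2 = 0.3, gammaStar = 0.5, seed = 1L) {
  cfg <- list(nPerStage = as.integer(nPerStage), d = as.integer(d),
              nCausal = as.integer(nCausal), c = as.integer(c),
              m = as.integer(m), visitSpacing = visitSpacing,
              mafRange = mafRange, effectSd = effectSd,
              slopeEffectSd = slopeEffectSd,
              stageSlopeProfile = stageSlopeProfile,
              agingInterceptSd = agingInterceptSd,
              agingSlopeMean = agingSlopeMean, agingSlopeSd = agingSlopeSd,
              noiseSd = noiseSd, overlapFraction = overlapFraction,
              nGwas = as.integer(nGwas), nRef = as.integer(nRef),
              gwasH2 = gwasH2, gammaStar = gammaStar, seed = as.integer(seed))
  L <- length(cfg$nPerStage)
  if (length(cfg$stageSlopeProfile) != L)
    stop("'stageSlopeProfile' must have one entry per stage (field: stageSlopeProfile)")
  if (cfg$nCausal > cfg$d) stop("'nCausal' cannot exceed 'd' (field: nCausal)")
  if (cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5 ||
      cfg$mafRange[1] > cfg$mafRange[2])
    stop("'mafRange' must lie in (0, 0.5] (field: mafRange)")
  if (cfg$overlapFraction < 0 || cfg$overlapFraction > 1)
    stop("'overlapFraction' must lie in [0, 1] (field: overlapFraction)")
  if (cfg$gwasH2 < 0 || cfg$gwasH2 >= 1)
    stop("'gwasH2' must lie in [0, 1) (field: gwasH2)")
  if (any(c(cfg$effectSd, cfg$slopeEffectSd, cfg$agingInterceptSd,
            cfg$agingSlopeSd, cfg$noiseSd) < 0))
    stop("standard deviations must be nonnegative")
  if (cfg$gammaStar < 0 || cfg$gammaStar > 1)
    stop("'gammaStar' must lie in [0, 1] (field: gammaStar)")
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a genotype matrix
#'
#' Per-SNP minor-allele frequencies are drawn uniformly from `mafRange`;
#' dosages are Binomial(2, MAF) per subject. Columns that come out
#' monomorphic are redrawn so every SNP is usable after standardization.
#' Allele labels avoid strand-ambiguous pairs unless `ambiguous = TRUE`.
#'
#' @param n,d subjects and SNPs.
#' @param mafRange numeric length-2.
#' @param seed optional integer; when given, `set.seed` is called first.
#' @param snpIds optional ids (default snp1..snpd).
#' @param ambiguous allow A/T and C/G allele pairs.
#' @param maf optional fixed per-SNP MAFs (overrides `mafRange`).
#'
#' @return list with `genotype` (n x d integer-valued matrix), `alleles`
#'   (data.frame snp_id, a1, a2) and `maf`.
#' @export
simulateGenotypes <- function(n, d, mafRange = c(0.05, 0.5), seed = NULL,
                              snpIds = NULL, ambiguous = FALSE, maf = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(d))
  if (is.null(maf)) maf <- stats::runif(d, mafRange[1], mafRange[2])
  G <- matrix(stats::rbinom(n * d, 2L, rep(maf, each = n)), n, d)
  for (j in seq_len(d)) {
    tries <- 0L
    while (length(unique(G[, j])) < 2L && tries < 100L) {
      G[, j] <- stats::rbinom(n, 2L, maf[j])
      tries <- tries + 1L
    }
    if (length(unique(G[, j])) < 2L)  # tiny n, extreme maf: force a het
      G[1L, j] <- if (G[2L, j] == 1L) 2L else 1L
  }
  pairs <- if (ambiguous) .ALL_PAIRS else .NONAMBIG_PAIRS
  pick <- sample(nrow(pairs), d, replace = TRUE)
  colnames(G) <- snpIds
  list(genotype = G,
       alleles = data.frame(snp_id = snpIds,
                            a1 = pairs[pick, 1L], a2 = pairs[pick, 2L],
                            stringsAsFactors = FALSE),
       maf = maf)
}

## subject carry-over: stage s+1 keeps a seeded sample of stage s's
## subjects and fills up with newly enrolled ones
.stageSubjectsDraw <- function(nPerStage, overlap) {
  L <- length(nPerStage)
  total <- 0L
  newIds <- function(k) {
    ids <- sprintf("S%05d", total + seq_len(k)); total <<- total + k; ids
  }
  subj <- vector("list", L)
  subj[[1L]] <- newIds(nPerStage[1L])
  if (L > 1L) for (s in 2L:L) {
    keep <- min(round(overlap * nPerStage[s]), length(subj[[s - 1L]]))
    kept <- sort(sample(subj[[s - 1L]], keep))
    subj[[s]] <- c(kept, newIds(nPerStage[s] - keep))
  }
  subj
}

#' Simulate a multi-stage longitudinal imaging-genetics cohort
#'
#' Draws one genome per registry subject, a causal SNP support, row-sparse
#' per-stage genetic intercept/slope effects (slopes scaled by the stage
#' profile), subject-level aging intercepts and slopes, and builds the QT
#' observations from the model's own structure
#' \deqn{Z_{ks} = \gamma^* (X_s W^*_s + X_s V^*_s t_k) +
#'       (1-\gamma^*)(A^* + B^* t_k) + N(0, \sigma^2)}
#' with consecutive stages sharing `overlapFraction` of their subjects.
#'
#' @param cfg a [simConfig()].
#' @return list with `data` (a [LongitudinalDataset-class] whose covariate
#'   table carries synthetic demographics, diagnosis and cognitive scores),
#'   `truth` (a [SimTruth-class]) and `snpInfo` (alleles + MAF table).
#' @export
simulateMultistage <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  L <- length(cfg$nPerStage)
  subj <- .stageSubjectsDraw(cfg$nPerStage, cfg$overlapFraction)
  registry <- sort(unique(unlist(subj)))
  nreg <- length(registry)

  gen <- simulateGenotypes(nreg, cfg$d, cfg$mafRange)
  G <- gen$genotype
  rownames(G) <- registry

  support <- sort(sample(cfg$d, cfg$nCausal))
  causal <- logical(cfg$d); causal[support] <- TRUE
  trueW <- trueV <- vector("list", L)
  for (s in seq_len(L)) {
    W <- matrix(0, cfg$d, cfg$c); V <- matrix(0, cfg$d, cfg$c)
    W[support, ] <- stats::rnorm(cfg$nCausal * cfg$c, sd = cfg$effectSd)
    V[support, ] <- stats::rnorm(cfg$nCausal * cfg$c,
                                 sd = cfg$slopeEffectSd) *
      cfg$stageSlopeProfile[s]
    trueW[[s]] <- W; trueV[[s]] <- V
  }
  trueA <- matrix(stats::rnorm(nreg * cfg$c, sd = cfg$agingInterceptSd),
                  nreg, cfg$c, dimnames = list(registry, NULL))
  trueB <- matrix(stats::rnorm(nreg * cfg$c, mean = cfg$agingSlopeMean,
                               sd = cfg$agingSlopeSd),
                  nreg, cfg$c, dimnames = list(registry, NULL))

  tWithin <- (seq_len(cfg$m) - 1L) * cfg$visitSpacing
  stageGap <- (cfg$m - 1L) * cfg$visitSpacing
  gs <- cfg$gammaStar
  qtn <- paste0("qt", seq_len(cfg$c))
  stages <- vector("list", L)
  for (s in seq_len(L)) {
    ids <- subj[[s]]
    pos <- match(ids, registry)
    Xs <- G[pos, , drop = FALSE]
    Xstd <- .genoStandardize(Xs)$x
    GWs <- Xstd %*% trueW[[s]]; HVs <- Xstd %*% trueV[[s]]
    ## per-stage aging slope: the population three-phase pattern scales each
    ## subject's aging slope by the stage profile
    Bs <- trueB[pos, , drop = FALSE] * cfg$stageSlopeProfile[s]
    qts <- array(0, dim = c(cfg$m, length(ids), cfg$c))
    for (k in seq_len(cfg$m)) {
      mu <- gs * (GWs + HVs * tWithin[k]) +
        (1 - gs) * (trueA[pos, , drop = FALSE] + Bs * tWithin[k])
      qts[k, , ] <- mu + stats::rnorm(length(mu), sd = cfg$noiseSd)
    }
    stages[[s]] <- StageData(
      stageIndex = s, subjectIds = ids, genotype = Xs, qts = qts,
      times = (s - 1L) * stageGap + tWithin,
      qtNames = qtn, snpIds = colnames(G))
  }

  covariates <- .simCovariates(cfg, registry, G, trueB, trueV, gs)

  truth <- new("SimTruth",
               trueA = trueA, trueB = trueB, trueW = trueW, trueV = trueV,
               trueU = rowMeans(Reduce(`+`, trueW) / L),
               causalSupport = causal, noiseSd = cfg$noiseSd,
               configEcho = c(unclass(cfg),
                              list(maf = gen$maf, alleles = gen$alleles,
                                   registry = registry)))
  list(data = LongitudinalDataset(stages, covariates), truth = truth,
       snpInfo = cbind(gen$alleles, maf = gen$maf))
}

## Demographics, diagnosis and cognitive scores. Diagnosis and the scores
## derive from each subject's overall progression rate (aging plus genetic
## slope contributions), so faster decline maps to worse diagnosis and
## worse cognition -- giving the post-fit statistics real signal to find.
.simCovariates <- function(cfg, registry, G, trueB, trueV, gs) {
  nreg <- length(registry)
  Xstd <- .genoStandardize(G)$x
  Vbar <- Reduce(`+`, trueV) / length(trueV)
  slope <- gs * rowMeans(Xstd %*% Vbar) + (1 - gs) * rowMeans(trueB)
  sev <- -(slope - mean(slope)) / stats::sd(slope)  # fast decline -> high severity
  q <- stats::quantile(sev, c(1 / 3, 2 / 3))
  diagnosis <- cut(sev, c(-Inf, q, Inf), labels = c("HC", "MCI", "AD"))
  noise <- function(sd) stats::rnorm(nreg, sd = sd)
  data.frame(
    subject_id = registry,
    age = round(stats::rnorm(nreg, 75, 6), 1),
    gender = sample(c("M", "F"), nreg, replace = TRUE),
    education = pmax(8, round(stats::rnorm(nreg, 16, 3))),
    handedness = sample(c("R", "L"), nreg, replace = TRUE, prob = c(.9, .1)),
    diagnosis = as.character(diagnosis),
    mmse = 27 - 1.7 * sev + noise(1.7),
    adas = 12 + 4.5 * sev + noise(4.5),
    ravlt_tot = 38 - 6 * sev + noise(6),
    ravlt_30 = 7 - 2 * sev + noise(2),
    ravlt_rec = 11 - 1.8 * sev + noise(1.8),
    stringsAsFactors = FALSE)
}

#' Simulate a paired GWAS cohort and reference panel
#'
#' Draws an independent cohort of `nGwas` subjects from the same SNP MAFs,
#' builds a phenotype y = X u* + e with u* the truth's joint SNP effects
#' and e scaled so the phenotype's heritability equals `gwasH2`, computes
#' per-SNP marginal effect sizes, and draws a further independent panel of
#' `nRef` subjects for LD estimation.
#'
#' @param cfg a [simConfig()].
#' @param truth the [SimTruth-class] from [simulateMultistage()].
#' @return list with `summary` (a [GwasSummary-class]) and `panel`
#'   (an [LdPanel-class]).
#' @export
simulateGwas <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simConfig"), is(truth, "SimTruth"))
  set.seed(cfg$seed + 997L)
  maf <- truth@configEcho$maf
  alleles <- truth@configEcho$alleles
  d <- cfg$d
  Gg <- simulateGenotypes(cfg$nGwas, d, maf = maf)$genotype
  Xg <- .genoStandardize(Gg)$x
  uStar <- truth@trueU
  if (cfg$gwasH2 > 0) {
    gpart <- drop(Xg %*% uStar)
    vg <- stats::var(gpart)
    y <- gpart + stats::rnorm(cfg$nGwas,
                              sd = sqrt(vg * (1 - cfg$gwasH2) / cfg$gwasH2))
  } else {
    y <- stats::rnorm(cfg$nGwas)
  }
  ys <- drop(scale(y))
  beta <- drop(crossprod(Xg, ys)) / (cfg$nGwas - 1)
  summary <- GwasSummary(snpIds = colnames(Gg), beta = beta,
                         effectAllele = alleles$a1, otherAllele = alleles$a2,
                         nGwas = cfg$nGwas)
  Gr <- simulateGenotypes(cfg$nRef, d, maf = maf)$genotype
  panel <- estimateLD(Gr)
  list(summary = summary, panel = panel)
}

#' Simulate the full study: cohort, truth, GWAS and harmonized summary
#'
#' One-call wrapper running [simulateMultistage()], [simulateGwas()] and
#' [harmonizeSummary()] against the cohort's SNP panel.
#'
#' @param cfg a [simConfig()].
#' @return list with `data`, `truth`, `snpInfo`, `summary`, `panel`,
#'   `harmonized`.
#' @export
simulateStudy <- function(cfg = simConfig()) {
  ms <- simulateMultistage(cfg)
  gw <- simulateGwas(cfg, ms$truth)
  hs <- harmonizeSummary(gw$summary, gw$panel,
                         targetSnpIds = snpIds(ms$data),
                         targetAlleles = ms$snpInfo)
  c(ms, gw, list(harmonized = hs))
}
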