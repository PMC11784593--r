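#' @import methods
NULL

## Central data containers. All are plain S4 with validity methods; construct
## them through the same-named constructor functions, which fill in derived
## slots and run validation.

#' One disease stage of a longitudinal imaging-genetics cohort
#'
#' A `StageData` holds the aligned genotype matrix, the longitudinal
#' quantitative-trait (QT) array, and the visit times for the subjects
#' observed during one stage of disease progression. Stages are contiguous
#' windows of visits; within a stage, visit times are coded in months since
#' the stage's first visit (so the first time is 0), with the stage's
#' absolute anchor kept in `timeOffset`.
#'
#' @slot stageIndex integer, position of the stage along the trajectory.
#' @slot subjectIds character, one id per subject (rows of `genotype`).
#' @slot genotype numeric matrix, subjects x SNPs, minor-allele dosages or
#'   standardized dosages.
#' @slot qts numeric array, timepoints x subjects x QTs.
#' @slot times numeric, within-stage visit times in months, strictly
#'   increasing, first element 0 unless constructed with absolute times.
#' @slot timeOffset numeric scalar, months from the cohort baseline to the
#'   stage's first visit.
#' @slot qtNames character, QT column names.
#' @slot snpIds character, SNP column names.
#'
#' @seealso [StageData()], [LongitudinalDataset-class]
#' @export
setClass("StageData", representation(
  stageIndex = "integer",
  subjectIds = "character",
  genotype = "matrix",
  qts = "array",
  times = "numeric",
  timeOffset = "numeric",
  qtNames = "character",
  snpIds = "character"
))

setValidity("StageData", function(object) {
  msg <- character(0)
  n <- length(object@subjectIds)
  dq <- dim(object@qts)
  if (length(dq) != 3L)
    msg <- c(msg, "'qts' must be a 3-d array (timepoints x subjects x QTs)")
  else {
    if (dq[1L] != length(object@times))
      msg <- c(msg, "first dim of 'qts' must match length(times)")
    if (dq[2L] != n)
      msg <- c(msg, "second dim of 'qts' must match length(subjectIds)")
    if (dq[3L] != length(object@qtNames))
      msg <- c(msg, "third dim of 'qts' must match length(qtNames)")
  }
  if (nrow(object@genotype) != n)
    msg <- c(msg, "nrow(genotype) must match length(subjectIds)")
  if (ncol(object@genotype) != length(object@snpIds))
    msg <- c(msg, "ncol(genotype) must match length(snpIds)")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (anyNA(object@genotype) || anyNA(object@qts))
    msg <- c(msg, "missing values must be resolved before construction")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "duplicated subject ids within a stage")
  if (length(msg)) msg else TRUE
})

#' Multi-stage longitudinal imaging-genetics dataset
#'
#' Ordered collection of [StageData-class] stages sharing one SNP panel,
#' plus the registry of all subjects ever observed and an optional
#' subject-level covariate table. Population aging effects are indexed by
#' the registry; each stage addresses the registry rows of its own subjects.
#'
#' @slot stages list of `StageData`, ordered by stage.
#' @slot subjectRegistry character, sorted union of subject ids.
#' @slot covariates `data.frame` keyed by `subject_id`, or a 0-row
#'   data.frame when absent.
#'
#' @seealso [LongitudinalDataset()]
#' @export
setClass("LongitudinalDataset", representation(
  stages = "list",
  subjectRegistry = "character",
  covariates = "data.frame"
))

setValidity("LongitudinalDataset", function(object) {
  msg <- character(0)
  if (length(object@stages) < 1L)
    msg <- c(msg, "need at least one stage")
  if (!all(vapply(object@stages, is, logical(1), class2 = "StageData")))
    msg <- c(msg, "'stages' must be a list of StageData")
  else {
    ref <- object@stages[[1L]]@snpIds
    for (s in seq_along(object@stages)) {
      st <- object@stages[[s]]
      if (!identical(st@snpIds, ref)) {
        msg <- c(msg, "snpIds must be identical and identically ordered across stages")
        break
      }
    }
    ok <- vapply(object@stages, function(st)
      all(st@subjectIds %in% object@subjectRegistry), logical(1))
    if (!all(ok))
      msg <- c(msg, "every stage's subjects must appear in the registry")
    qn <- object@stages[[1L]]@qtNames
    if (!all(vapply(object@stages, function(st) identical(st@qtNames, qn),
                    logical(1))))
      msg <- c(msg, "qtNames must agree across stages")
  }
  if (nrow(object@covariates) > 0L &&
      !"subject_id" %in% colnames(object@covariates))
    msg <- c(msg, "covariates must carry a 'subject_id' column")
  if (length(msg)) msg else TRUE
})

#' GWAS summary statistics
#'
#' Per-SNP marginal effect sizes from a single-SNP association scan of a
#' large external cohort, with the allele metadata needed to harmonize them
#' against a target genotype panel. Effects are per standardized-dosage unit
#' on a standardized phenotype, so each beta is the SNP-phenotype sample
#' correlation.
#'
#' @slot snpIds character.
#' @slot effectAllele,otherAllele character, single bases in A/C/G/T.
#' @slot beta numeric marginal effect sizes.
#' @slot nGwas integer, GWAS cohort size.
#'
#' @export
setClass("GwasSummary", representation(
  snpIds = "character",
  effectAllele = "character",
  otherAllele = "character",
  beta = "numeric",
  nGwas = "integer"
))

setValidity("GwasSummary", function(object) {
  msg <- character(0)
  d <- length(object@snpIds)
  if (d < 1L) msg <- c(msg, "need at least one SNP")
  if (length(object@beta) != d || length(object@effectAllele) != d ||
      length(object@otherAllele) != d)
    msg <- c(msg, "per-SNP slots must all have the same length")
  if (!all(is.finite(object@beta)))
    msg <- c(msg, "'beta' must be finite")
  if (!all(c(object@effectAllele, object@otherAllele) %in% c("A", "C", "G", "T")))
    msg <- c(msg, "alleles must be single bases in A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Reference-panel LD matrix
#'
#' Scaled SNP-by-SNP covariance estimated from an external genotype panel of
#' matching ancestry; with standardized dosages this is the SNP correlation
#' matrix. Substitutes for the in-sample X'X/(n-1) wherever individual-level
#' GWAS genotypes are unavailable.
#'
#' @slot snpIds character.
#' @slot sigma numeric symmetric matrix, SNPs x SNPs.
#' @slot nRef integer, reference panel size.
#'
#' @export
setClass("LdPanel", representation(
  snpIds = "character",
  sigma = "matrix",
  nRef = "integer"
))

setValidity("LdPanel", function(object) {
  msg <- character(0)
  d <- length(object@snpIds)
  if (!all(dim(object@sigma) == c(d, d)))
    msg <- c(msg, "'sigma' must be d x d with d = length(snpIds)")
  else {
    if (max(abs(object@sigma - t(object@sigma))) > 1e-10)
      msg <- c(msg, "'sigma' must be symmetric (tolerance 1e-10)")
    if (any(diag(object@sigma) <= 0))
      msg <- c(msg, "diagonal of 'sigma' must be positive")
  }
  if (object@nRef < 2L) msg <- c(msg, "'nRef' must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Harmonized GWAS summary + LD, aligned to a target SNP panel
#'
#' Result of [harmonizeSummary()]: the SNPs common to the summary
#' statistics, the LD panel and the target genotypes, with effect sizes
#' sign-flipped where the effect allele is swapped relative to the target,
#' strand-ambiguous SNPs optionally dropped, and everything reordered to the
#' target panel. `flipCount`/`dropCount` record provenance.
#'
#' @slot snpIds character, ordered as the target panel.
#' @slot beta numeric, sign-aligned effect sizes.
#' @slot sigma numeric matrix, LD restricted to the retained SNPs.
#' @slot nRef,nGwas integer cohort sizes carried through.
#' @slot flipCount,dropCount integer provenance counters.
#'
#' @export
setClass("HarmonizedSummary", representation(
  snpIds = "character",
  beta = "numeric",
  sigma = "matrix",
  nRef = "integer",
  nGwas = "integer",
  flipCount = "integer",
  dropCount = "integer"
))

setValidity("HarmonizedSummary", function(object) {
  msg <- character(0)
  d <- length(object@snpIds)
  if (length(object@beta) != d)
    msg <- c(msg, "'beta' must match snpIds")
  if (!all(dim(object@sigma) == c(d, d)))
    msg <- c(msg, "'sigma' must be d x d")
  if (length(msg)) msg else TRUE
})

#' Fitted multi-stage collaborative model
#'
#' Parameter set returned by [fitMSColoR()]: population aging intercepts `A`
#' and slopes `B` over the subject registry, per-stage genetic intercept
#' effects `W`, slope effects `V` and joint GWAS effects `u`, the
#' hyperparameters used, the objective traces of the alternating solver and
#' its convergence state. Two traces are kept: `objectiveTrace` evaluates
#' the row-sparsity penalty as the (delta-floored) l-infinity,1 norm the
#' model states, while `surrogateTrace` evaluates the quadratic surrogate
#' that the closed-form reweighted updates minimize blockwise; descent is
#' guaranteed-by-audit on the surrogate (see the methods vignette).
#'
#' @slot A,B numeric matrices, registry subjects x QTs (shared aging mode)
#'   or 0-row placeholders when aging is per stage (then see `Astage`,
#'   `Bstage`).
#' @slot Astage,Bstage lists of per-stage aging matrices (per-stage mode;
#'   empty lists in shared mode).
#' @slot W,V lists (one element per stage) of SNPs x QTs effect matrices.
#' @slot u list of per-stage joint GWAS effect vectors (length-0 vectors
#'   when the GWAS term is disabled).
#' @slot gamma,lambdaP,lambdaQ,tau numeric hyperparameters.
#' @slot objectiveTrace,surrogateTrace numeric per-iteration traces.
#' @slot converged logical, whether the coefficient-change rule fired.
#' @slot nIter integer.
#' @slot subjectRegistry,snpIds,qtNames character metadata.
#' @slot stageSubjects list of per-stage subject-id vectors.
#' @slot prepared list, the standardized per-stage design the model was
#'   fitted on (kept for prediction and post-fit statistics).
#' @slot control list, full configuration echo including the seed.
#'
#' @export
setClass("MscolorFit", representation(
  A = "matrix",
  B = "matrix",
  Astage = "list",
  Bstage = "list",
  W = "list",
  V = "list",
  u = "list",
  gamma = "numeric",
  lambdaP = "numeric",
  lambdaQ = "numeric",
  tau = "numeric",
  objectiveTrace = "numeric",
  surrogateTrace = "numeric",
  converged = "logical",
  nIter = "integer",
  subjectRegistry = "character",
  snpIds = "character",
  qtNames = "character",
  stageSubjects = "list",
  prepared = "list",
  control = "list"
))

setValidity("MscolorFit", function(object) {
  msg <- character(0)
  L <- length(object@W)
  if (length(object@V) != L || length(object@u) != L)
    msg <- c(msg, "'W', 'V' and 'u' must have one element per stage")
  d <- length(object@snpIds)
  cc <- length(object@qtNames)
  okdim <- vapply(seq_len(L), function(s)
    all(dim(object@W[[s]]) == c(d, cc)) && all(dim(object@V[[s]]) == c(d, cc)),
    logical(1))
  if (L > 0L && !all(okdim))
    msg <- c(msg, "per-stage W/V must be SNPs x QTs")
  tr <- object@surrogateTrace
  if (length(tr) > 1L) {
    # divergence guard; the fine-grained 1e-9 monotonicity claim is audited
    # in the test-suite at study sizes
    if (max(diff(tr)) > 1e-3 * max(abs(tr[1L]), 1))
      msg <- c(msg, "surrogate objective trace increased (solver divergence)")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted comparison method
#'
#' Common container for the three baselines: per-timepoint multi-task
#' regression (`"smtr"`), the one-stage mixed-effects longitudinal model
#' (`"smml"`), and the multi-stage model without GWAS collaboration
#' (`"msmml"`). The `params` list holds whatever parameter matrices the
#' method has; traces and convergence mirror [MscolorFit-class].
#'
#' @slot method character tag, one of "smtr", "smml", "msmml".
#' @slot params list of parameter matrices.
#' @slot objectiveTrace,surrogateTrace numeric traces.
#' @slot converged logical.
#' @slot nIter integer.
#' @slot subjectRegistry,snpIds,qtNames character metadata.
#' @slot prepared list, fitted design (for prediction).
#' @slot control list, configuration echo.
#'
#' @export
setClass("BaselineFit", representation(
  method = "character",
  params = "list",
  objectiveTrace = "numeric",
  surrogateTrace = "numeric",
  converged = "logical",
  nIter = "integer",
  subjectRegistry = "character",
  snpIds = "character",
  qtNames = "character",
  prepared = "list",
  control = "list"
))

setValidity("BaselineFit", function(object) {
  msg <- character(0)
  if (!object@method %in% c("smtr", "smml", "msmml"))
    msg <- c(msg, "method must be one of 'smtr', 'smml', 'msmml'")
  tr <- object@surrogateTrace
  if (length(tr) > 1L && max(diff(tr)) > 1e-3 * max(abs(tr[1L]), 1))
    msg <- c(msg, "surrogate objective trace increased (solver divergence)")
  if (length(msg)) msg else TRUE
})

#' Ground truth emitted by the synthetic cohort generator
#'
#' Generating parameters and the causal-SNP support of a simulated
#' multi-stage cohort, used to score parameter and support recovery.
#'
#' @slot trueA,trueB numeric matrices (registry x QTs) of subject aging
#'   effects.
#' @slot trueW,trueV lists of per-stage generating effect matrices.
#' @slot trueU numeric, joint SNP effects used for the paired GWAS cohort.
#' @slot causalSupport logical, length SNPs.
#' @slot noiseSd numeric.
#' @slot configEcho list, the full generator configuration incl. seed.
#'
#' @export
setClass("SimTruth", representation(
  trueA = "matrix",
  trueB = "matrix",
  trueW = "list",
  trueV = "list",
  trueU = "numeric",
  causalSupport = "logical",
  noiseSd = "numeric",
  configEcho = "list"
))

setValidity("SimTruth", function(object) {
  msg <- character(0)
  if (length(object@causalSupport) > 0L && !any(object@causalSupport) &&
      length(object@trueW) > 0L &&
      any(vapply(object@trueW, function(w) any(w != 0), logical(1))))
    msg <- c(msg, "nonzero genetic effects require a nonempty causal support")
  for (s in seq_along(object@trueW)) {
    nz <- rowSums(abs(object@trueW[[s]])) + rowSums(abs(object@trueV[[s]])) > 0
    if (any(nz & !object@causalSupport)) {
      msg <- c(msg, "nonzero effect rows must lie inside the causal support")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Nested cross-validation report
#'
#' Per-outer-fold train/test RMSE (per stage and averaged), the
#' hyperparameters selected by the inner folds, and per-fold SNP weight
#' matrices for selection scoring.
#'
#' @slot method character.
#' @slot folds data.frame, one row per (fold, stage) with train/test RMSE.
#' @slot chosen data.frame, selected hyperparameters per outer fold.
#' @slot grid numeric, the candidate values searched.
#' @slot snpScores list of per-fold named score structures.
#' @slot summary data.frame, aggregate mean/sd RMSE.
#' @slot seed integer.
#'
#' @export
setClass("CvReport", representation(
  method = "character",
  folds = "data.frame",
  chosen = "data.frame",
  grid = "numeric",
  snpScores = "list",
  summary = "data.frame",
  seed = "integer"
))

#' SNP-selection report
#'
#' Per-SNP aggregate weights (mean absolute row-max across folds, separately
#' for intercept and slope blocks per stage), the implied ranking, and,
#' when simulated ground truth is supplied, support-recovery metrics.
#'
#' @slot scores data.frame, one row per SNP with per-block scores and the
#'   overall score.
#' @slot ranking character, SNP ids ordered by decreasing overall score.
#' @slot auc numeric, ROC AUC of the overall score against the causal
#'   support (NA when unavailable).
#' @slot precisionAtK numeric.
#' @slot topK integer.
#' @slot allZero logical, set when every score is exactly zero (AUC
#'   undefined).
#'
#' @export
setClass("SelectionReport", representation(
  scores = "data.frame",
  ranking = "character",
  auc = "numeric",
  precisionAtK = "numeric",
  topK = "integer",
  allZero = "logical"
))
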