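#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("nStages", "LongitudinalDataset", function(x) length(x@stages))

#' @rdname accessors
#' @export
setMethod("nStages", "MscolorFit", function(x) length(x@W))

#' @rdname accessors
#' @export
setMethod("nSnps", "LongitudinalDataset", function(x)
  length(x@stages[[1L]]@snpIds))

#' @rdname accessors
#' @export
setMethod("nSnps", "MscolorFit", function(x) length(x@snpIds))

#' @rdname accessors
#' @export
setMethod("nQts", "LongitudinalDataset", function(x)
  length(x@stages[[1L]]@qtNames))

#' @rdname accessors
#' @export
setMethod("snpIds", "LongitudinalDataset", function(x) x@stages[[1L]]@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "StageData", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "GwasSummary", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "LdPanel", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "HarmonizedSummary", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "MscolorFit", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("qtNames", "LongitudinalDataset", function(x) x@stages[[1L]]@qtNames)

#' @rdname accessors
#' @export
setMethod("qtNames", "MscolorFit", function(x) x@qtNames)

#' @rdname accessors
#' @export
setMethod("subjectIds", "StageData", function(x) x@subjectIds)

#' @rdname accessors
#' @export
setMethod("subjectIds", "LongitudinalDataset", function(x) x@subjectRegistry)

#' @rdname accessors
#' @export
setMethod("stageData", "LongitudinalDataset", function(x, stage) {
  if (stage < 1L || stage > length(x@stages))
    stop("unknown stage: ", stage)
  x@stages[[stage]]
})

#' @rdname accessors
#' @export
setMethod("visitTimes", "StageData", function(x, stage) x@times)

#' @rdname accessors
#' @export
setMethod("visitTimes", "LongitudinalDataset", function(x, stage)
  stageData(x, stage)@times)

#' @rdname accessors
#' @export
setMethod("covariates", "LongitudinalDataset", function(x) x@covariates)

## --- fit accessors -----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("agingIntercepts", "MscolorFit", function(object, stage = NULL) {
  if (length(object@Astage)) {
    if (is.null(stage)) stop("per-stage aging mode: give a stage")
    return(object@Astage[[stage]])
  }
  if (is.null(stage)) return(object@A)
  object@A[match(object@stageSubjects[[stage]], object@subjectRegistry), ,
           drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("agingSlopes", "MscolorFit", function(object, stage = NULL) {
  if (length(object@Bstage)) {
    if (is.null(stage)) stop("per-stage aging mode: give a stage")
    return(object@Bstage[[stage]])
  }
  if (is.null(stage)) return(object@B)
  object@B[match(object@stageSubjects[[stage]], object@subjectRegistry), ,
           drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("geneticIntercepts", "MscolorFit", function(object, stage)
  object@W[[stage]])

#' @rdname accessors
#' @export
setMethod("geneticSlopes", "MscolorFit", function(object, stage)
  object@V[[stage]])

#' @rdname accessors
#' @export
setMethod("jointSnpEffects", "MscolorFit", function(object, stage)
  object@u[[stage]])

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "MscolorFit", function(object)
  object@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "BaselineFit", function(object)
  object@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("surrogateTrace", "MscolorFit", function(object)
  object@surrogateTrace)

#' @rdname accessors
#' @export
setMethod("surrogateTrace", "BaselineFit", function(object)
  object@surrogateTrace)

#' @rdname accessors
#' @export
setMethod("nStages", "BaselineFit", function(x)
  if (x@method == "msmml") length(x@params$W) else 1L)

#' @rdname accessors
#' @export
setMethod("snpIds", "BaselineFit", function(x) x@snpIds)

#' @rdname accessors
#' @export
setMethod("qtNames", "BaselineFit", function(x) x@qtNames)

#' @rdname accessors
#' @export
setMethod("isConverged", "MscolorFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "BaselineFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("causalSupport", "SimTruth", function(object) object@causalSupport)

## --- show methods ------------------------------------------------------

#' @export
setMethod("show", "StageData", function(object) {
  cat(sprintf("StageData (stage %d): %d subjects, %d SNPs, %d QTs, %d visits\n",
              object@stageIndex, length(object@subjectIds),
              length(object@snpIds), length(object@qtNames),
              length(object@times)))
  cat("  visit months:", paste(object@times, collapse = ", "),
      sprintf("(offset %+g)\n", object@timeOffset))
})

#' @export
setMethod("show", "LongitudinalDataset", function(object) {
  ns <- vapply(object@stages, function(s) length(s@subjectIds), integer(1))
  cat(sprintf("LongitudinalDataset: %d stages, %d registry subjects, %d SNPs, %d QTs\n",
              length(object@stages), length(object@subjectRegistry),
              nSnps(object), nQts(object)))
  cat("  per-stage n:", paste(ns, collapse = ", "), "\n")
  if (nrow(object@covariates))
    cat("  covariates:", paste(setdiff(colnames(object@covariates),
                                       "subject_id"), collapse = ", "), "\n")
})

#' @export
setMethod("show", "GwasSummary", function(object) {
  cat(sprintf("GwasSummary: %d SNPs, cohort n = %d\n",
              length(object@snpIds), object@nGwas))
  cat(sprintf("  beta range: [%.4g, %.4g]\n",
              min(object@beta), max(object@beta)))
})

#' @export
setMethod("show", "LdPanel", function(object) {
  cat(sprintf("LdPanel: %d SNPs, reference n = %d\n",
              length(object@snpIds), object@nRef))
})

#' @export
setMethod("show", "HarmonizedSummary", function(object) {
  cat(sprintf("HarmonizedSummary: %d SNPs (flipped %d, dropped %d), n_gwas = %d, n_ref = %d\n",
              length(object@snpIds), object@flipCount, object@dropCount,
              object@nGwas, object@nRef))
})

#' @export
setMethod("show", "MscolorFit", function(object) {
  cat(sprintf("MscolorFit: %d stages, %d SNPs, %d QTs, %d registry subjects\n",
              length(object@W), length(object@snpIds),
              length(object@qtNames), length(object@subjectRegistry)))
  cat(sprintf("  gamma = %g, lambdaP = %g, lambdaQ = %g, tau = %g\n",
              object@gamma, object@lambdaP, object@lambdaQ, object@tau))
  cat(sprintf("  %d iterations, converged: %s, final objective %.6g\n",
              object@nIter, object@converged,
              utils::tail(object@objectiveTrace, 1L)))
})

#' @export
setMethod("show", "BaselineFit", function(object) {
  cat(sprintf("BaselineFit ('%s'): %d iterations, converged: %s, final objective %.6g\n",
              object@method, object@nIter, object@converged,
              utils::tail(object@objectiveTrace, 1L)))
})

#' @export
setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d SNPs (%d causal), %d stages, noise sd %g\n",
              length(object@causalSupport), sum(object@causalSupport),
              length(object@trueW), object@noiseSd))
})

#' @export
setMethod("show", "CvReport", function(object) {
  cat(sprintf("CvReport ('%s'): %d outer folds, grid of %d values\n",
              object@method, max(object@folds$fold), length(object@grid)))
  print(object@summary, row.names = FALSE)
})

#' @export
setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d SNPs, top %d\n",
              nrow(object@scores), object@topK))
  if (object@allZero) {
    cat("  all scores zero; AUC undefined\n")
  } else if (!is.na(object@auc)) {
    cat(sprintf("  support-recovery AUC %.3f, precision@%d %.3f\n",
                object@auc, object@topK, object@precisionAtK))
  }
})
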