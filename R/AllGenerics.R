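#' @include AllClasses.R
NULL

#' Accessors for the package's data containers and fits
#'
#' Small generic accessors shared across the container classes:
#' dimensions (`nStages`, `nSnps`, `nQts`), identifier vectors (`snpIds`,
#' `qtNames`, `subjectIds`), stage extraction (`stageData`, `visitTimes`),
#' the covariate table (`covariates`), fitted-parameter access
#' (`agingIntercepts`, `agingSlopes`, `geneticIntercepts`,
#' `geneticSlopes`, `jointSnpEffects`), solver diagnostics
#' (`objectiveTrace`, `surrogateTrace`, `isConverged`) and the simulated
#' causal support (`causalSupport`).
#'
#' @param x,object the object to access.
#' @param stage integer stage index (where applicable).
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nStages", function(x) standardGeneric("nStages"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("nQts", function(x) standardGeneric("nQts"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("qtNames", function(x) standardGeneric("qtNames"))

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setGeneric("stageData", function(x, stage) standardGeneric("stageData"))

#' @rdname accessors
#' @export
setGeneric("visitTimes", function(x, stage) standardGeneric("visitTimes"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("agingIntercepts", function(object, stage = NULL)
  standardGeneric("agingIntercepts"))

#' @rdname accessors
#' @export
setGeneric("agingSlopes", function(object, stage = NULL)
  standardGeneric("agingSlopes"))

#' @rdname accessors
#' @export
setGeneric("geneticIntercepts", function(object, stage)
  standardGeneric("geneticIntercepts"))

#' @rdname accessors
#' @export
setGeneric("geneticSlopes", function(object, stage)
  standardGeneric("geneticSlopes"))

#' @rdname accessors
#' @export
setGeneric("jointSnpEffects", function(object, stage)
  standardGeneric("jointSnpEffects"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("surrogateTrace", function(object) standardGeneric("surrogateTrace"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("causalSupport", function(object) standardGeneric("causalSupport"))
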