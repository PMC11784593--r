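#' @include AllClasses.R
NULL

#' Construct a StageData object
#'
#' @param stageIndex integer position of the stage (1-based).
#' @param subjectIds character vector of subject identifiers.
#' @param genotype numeric matrix, subjects x SNPs.
#' @param qts numeric array timepoints x subjects x QTs, or a list of
#'   per-timepoint subject x QT matrices.
#' @param times numeric visit times in months. By default they are re-coded
#'   to months since the stage's first visit and the offset stored in
#'   `timeOffset`; set `relativeTimes = FALSE` to keep them as given.
#' @param qtNames,snpIds character; taken from dimnames when missing.
#' @param relativeTimes logical, re-code `times` to start at 0 (default).
#'
#' @return A [StageData-class] object.
#' @export
StageData <- function(stageIndex, subjectIds, genotype, qts, times,
                      qtNames = NULL, snpIds = NULL, relativeTimes = TRUE) {
  if (is.list(qts)) {
    stopifnot(length(qts) == length(times))
    qts <- aperm(simplify2array(qts), c(3L, 1L, 2L))
  }
  if (is.null(snpIds)) {
    snpIds <- colnames(genotype)
    if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(genotype)))
  }
  if (is.null(qtNames)) {
    qtNames <- dimnames(qts)[[3L]]
    if (is.null(qtNames)) qtNames <- paste0("qt", seq_len(dim(qts)[3L]))
  }
  offset <- if (relativeTimes && length(times)) times[1L] else 0
  genotype <- as.matrix(genotype)
  storage.mode(genotype) <- "double"
  dimnames(genotype) <- list(subjectIds, snpIds)
  dimnames(qts) <- list(NULL, subjectIds, qtNames)
  new("StageData",
      stageIndex = as.integer(stageIndex),
      subjectIds = as.character(subjectIds),
      genotype = genotype,
      qts = qts,
      times = as.numeric(times - offset),
      timeOffset = as.numeric(offset),
      qtNames = as.character(qtNames),
      snpIds = as.character(snpIds))
}

#' Construct a LongitudinalDataset
#'
#' @param stages list of [StageData-class], ordered by stage.
#' @param covariates optional data.frame with a `subject_id` column.
#'
#' @return A [LongitudinalDataset-class]; the subject registry is the sorted
#'   union of the stages' subjects.
#' @export
LongitudinalDataset <- function(stages, covariates = NULL) {
  if (is.null(covariates))
    covariates <- data.frame(subject_id = character(0))
  registry <- sort(unique(unlist(lapply(stages, function(s) s@subjectIds))))
  new("LongitudinalDataset",
      stages = stages,
      subjectRegistry = registry,
      covariates = covariates)
}

#' Construct a GwasSummary
#'
#' @param snpIds character SNP identifiers.
#' @param beta numeric marginal effect sizes (standardized scale).
#' @param effectAllele,otherAllele character single-base alleles.
#' @param nGwas integer GWAS cohort size.
#'
#' @return A [GwasSummary-class] object.
#' @export
GwasSummary <- function(snpIds, beta, effectAllele, otherAllele, nGwas) {
  new("GwasSummary",
      snpIds = as.character(snpIds),
      beta = as.numeric(beta),
      effectAllele = as.character(effectAllele),
      otherAllele = as.character(otherAllele),
      nGwas = as.integer(nGwas))
}

#' Construct an LdPanel
#'
#' Usually produced by [estimateLD()]; direct construction is for
#' pre-computed matrices.
#'
#' @param snpIds character SNP identifiers.
#' @param sigma numeric symmetric SNP x SNP scaled covariance.
#' @param nRef integer reference-panel size.
#'
#' @return An [LdPanel-class] object.
#' @export
LdPanel <- function(snpIds, sigma, nRef) {
  sigma <- as.matrix(sigma)
  dimnames(sigma) <- list(snpIds, snpIds)
  new("LdPanel", snpIds = as.character(snpIds), sigma = sigma,
      nRef = as.integer(nRef))
}
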