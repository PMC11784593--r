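#' Marginal (single-SNP) effect size
#'
#' The effect size of one standardized SNP on one standardized QT from the
#' single-SNP regression y = a + x b + e: with both vectors at mean 0 and
#' unit sample sd, b = x'y/(n-1), i.e. the sample correlation. This is the
#' quantity GWAS consortia release per SNP.
#'
#' @param x,y numeric vectors of equal length (>= 3), standardized.
#' @return scalar effect size in \[-1, 1\].
#' @examples
#' marginalEffects(c(-1, 0, 1), c(-1, 0, 1))  # 1
#' @export
marginalEffects <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  sum(x * y) / (length(x) - 1)
}

#' Estimate an LD matrix from a reference genotype panel
#'
#' Standardizes the panel columns and returns X'X/(n_ref - 1) — the SNP
#' correlation matrix — as an [LdPanel-class]. This substitutes for the
#' (unavailable) in-sample scaled covariance of the GWAS genotypes, drawing
#' on a reference cohort of matching ancestry.
#'
#' @param panel numeric matrix, subjects x SNPs (raw dosages or already
#'   standardized).
#' @param snpIds character; defaults to `colnames(panel)`.
#' @return An [LdPanel-class]. Monomorphic SNPs are dropped with a warning.
#' @export
estimateLD <- function(panel, snpIds = colnames(panel)) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2L) stop("reference panel needs at least 2 subjects")
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_len(ncol(panel)))
  std <- standardizeColumns(panel, dropConstant = TRUE)
  if (length(std$kept) < ncol(panel))
    snpIds <- snpIds[std$kept]
  sigma <- crossprod(std$x) / (nrow(panel) - 1)
  sigma <- (sigma + t(sigma)) / 2
  LdPanel(snpIds = snpIds, sigma = sigma, nRef = nrow(panel))
}

#' Joint SNP effects from marginal effects and LD
#'
#' Converts the marginal effect sizes of a single-SNP scan into the joint
#' (multivariate) effects u solving sigma u = beta, the summary-statistic
#' analogue of the multivariate OLS solution (X'X)^-1 X'y. A small ridge
#' keeps the system invertible when the reference panel is smaller than the
#' SNP count.
#'
#' @param beta numeric marginal effects.
#' @param sigma LD matrix (or an [LdPanel-class]).
#' @param ridge nonnegative scalar added to the diagonal (default 1e-3).
#' @return numeric vector u of joint effects.
#' @examples
#' jointEffects(c(1, 1), rbind(c(1, .5), c(.5, 1)), ridge = 0)  # 2/3, 2/3
#' @export
jointEffects <- function(beta, sigma, ridge = 1e-3) {
  if (is(sigma, "LdPanel")) sigma <- sigma@sigma
  sigma <- as.matrix(sigma)
  if (length(beta) != nrow(sigma)) stop("'beta' must match dim(sigma)")
  if (ridge < 0) stop("'ridge' must be nonnegative")
  u <- tryCatch(
    solve(sigma + diag(ridge, nrow(sigma)), beta),
    error = function(e)
      stop("LD system could not be solved (", conditionMessage(e),
           "); increase 'ridge'"))
  if (!all(is.finite(u)))
    stop("non-finite joint effects; increase 'ridge'")
  drop(u)
}

.AMBIGUOUS <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize GWAS summary statistics, LD panel and target genotypes
#'
#' Restricts all three sources to their common SNPs, flips the sign of beta
#' where the summary's effect allele is the target's other allele, drops
#' SNPs whose allele pairs cannot be reconciled, optionally drops
#' strand-ambiguous (A/T, C/G) SNPs, and reorders everything to the target
#' panel's SNP order.
#'
#' @param summary a [GwasSummary-class].
#' @param panel an [LdPanel-class].
#' @param targetSnpIds character, SNP ids of the genotype data to model.
#' @param targetAlleles data.frame with columns `snp_id`, `a1` (effect
#'   allele of the target coding) and `a2`.
#' @param dropAmbiguous drop A/T and C/G SNPs (default TRUE).
#'
#' @return A [HarmonizedSummary-class]. Applying the function to an already
#'   harmonized result is a no-op.
#' @export
harmonizeSummary <- function(summary, panel, targetSnpIds, targetAlleles,
                             dropAmbiguous = TRUE) {
  if (is(summary, "HarmonizedSummary")) {
    # re-entrant call: a harmonized object is already expressed on the
    # target's alleles, so rebuild the equivalent raw inputs and recurse
    ti <- match(summary@snpIds, targetAlleles$snp_id)
    summary <- GwasSummary(snpIds = summary@snpIds, beta = summary@beta,
                           effectAllele = targetAlleles$a1[ti],
                           otherAllele = targetAlleles$a2[ti],
                           nGwas = summary@nGwas)
    panel <- LdPanel(summary@snpIds, panel@sigma[
      match(summary@snpIds, panel@snpIds),
      match(summary@snpIds, panel@snpIds), drop = FALSE], panel@nRef)
  }
  stopifnot(is(summary, "GwasSummary"), is(panel, "LdPanel"))
  common <- intersect(intersect(summary@snpIds, panel@snpIds), targetSnpIds)
  if (!length(common)) stop("no SNPs shared by summary, panel and target")
  ord <- targetSnpIds[targetSnpIds %in% common]

  si <- match(ord, summary@snpIds)
  ti <- match(ord, targetAlleles$snp_id)
  if (anyNA(ti)) stop("targetAlleles must cover every target SNP")
  ea <- toupper(summary@effectAllele[si]); oa <- toupper(summary@otherAllele[si])
  a1 <- toupper(targetAlleles$a1[ti]); a2 <- toupper(targetAlleles$a2[ti])

  same <- ea == a1 & oa == a2
  flip <- ea == a2 & oa == a1
  ambiguous <- .AMBIGUOUS[ea] == oa
  keep <- (same | flip) & !(dropAmbiguous & ambiguous)
  dropped <- sum(!keep)
  if (!any(keep)) stop("no SNPs left after allele harmonization")

  ord <- ord[keep]
  beta <- summary@beta[si][keep]
  beta[flip[keep]] <- -beta[flip[keep]]
  pi <- match(ord, panel@snpIds)
  new("HarmonizedSummary",
      snpIds = ord,
      beta = beta,
      sigma = panel@sigma[pi, pi, drop = FALSE],
      nRef = panel@nRef,
      nGwas = summary@nGwas,
      flipCount = as.integer(sum(flip[keep])),
      dropCount = as.integer(dropped))
}

#' Compute per-SNP marginal effects for a whole genotype matrix
#'
#' Vectorized convenience wrapper around the single-SNP effect: standardizes
#' genotypes and phenotype, returns x_g'y/(n-1) per SNP. Used by the
#' simulated GWAS cohort and available for constructing summary statistics
#' from any individual-level cohort.
#'
#' @param genotype numeric matrix subjects x SNPs.
#' @param phenotype numeric vector.
#' @return numeric vector of marginal effects (one per SNP).
#' @export
marginalEffectsScan <- function(genotype, phenotype) {
  if (nrow(genotype) != length(phenotype))
    stop("genotype rows must match phenotype length")
  gs <- standardizeColumns(genotype)$x
  ys <- drop(standardizeColumns(cbind(phenotype))$x)
  drop(crossprod(gs, ys)) / (nrow(gs) - 1)
}
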