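## File formats. All tabular formats are tab-delimited text with a header;
## genotype orientation is subjects x SNPs everywhere. SNP matching across
## files is by id (with allele check via harmonizeSummary), never by
## position.

.readTsv <- function(file, what) {
  if (!file.exists(file)) stop(what, " file not found: ", file)
  utils::read.delim(file, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.writeTsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

.checkHeader <- function(file, expected, what) {
  if (!file.exists(file)) stop(what, " file not found: ", file)
  hdr <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(expected, hdr)
  if (length(missing))
    stop("malformed ", what, " header at ", file, " line 1: missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(hdr)
}

#' Read / write a delimited genotype matrix
#'
#' Tab-delimited, header `subject_id` followed by one column per SNP id;
#' one row per subject with numeric dosages.
#'
#' @param file path.
#' @return numeric matrix with subject-id rownames and SNP-id colnames.
#' @export
readGenotypeMatrix <- function(file) {
  .checkHeader(file, "subject_id", "genotype")
  df <- .readTsv(file, "genotype")
  if (colnames(df)[1L] != "subject_id")
    stop("malformed genotype header at ", file,
         " line 1: first column must be 'subject_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject_id
  m
}

#' @rdname readGenotypeMatrix
#' @param genotype matrix with rownames (subjects) and colnames (SNPs).
#' @export
writeGenotypeMatrix <- function(genotype, file) {
  df <- data.frame(subject_id = rownames(genotype), genotype,
                   check.names = FALSE)
  .writeTsv(df, file)
  invisible(file)
}

#' Read / write a SNP info (allele) table
#'
#' Columns `snp_id`, `a1` (effect/coded allele), `a2`, optionally `maf`.
#' @param file path.
#' @export
readSnpInfo <- function(file) {
  .checkHeader(file, c("snp_id", "a1", "a2"), "SNP info")
  .readTsv(file, "SNP info")
}

#' @rdname readSnpInfo
#' @param info data.frame with `snp_id`, `a1`, `a2` (and extras).
#' @export
writeSnpInfo <- function(info, file) {
  .writeTsv(info, file)
  invisible(file)
}

#' Read / write GWAS summary statistics
#'
#' Tab-delimited with header `SNP A1 A2 BETA N` (A1 = effect allele).
#' @param file path.
#' @return A [GwasSummary-class].
#' @export
readSumstats <- function(file) {
  .checkHeader(file, c("SNP", "A1", "A2", "BETA", "N"), "sumstats")
  df <- .readTsv(file, "sumstats")
  GwasSummary(snpIds = df$SNP, beta = df$BETA, effectAllele = df$A1,
              otherAllele = df$A2, nGwas = df$N[1L])
}

#' @rdname readSumstats
#' @param summary a [GwasSummary-class].
#' @export
writeSumstats <- function(summary, file) {
  .writeTsv(data.frame(SNP = summary@snpIds, A1 = summary@effectAllele,
                       A2 = summary@otherAllele, BETA = summary@beta,
                       N = summary@nGwas), file)
  invisible(file)
}

#' Read / write an LD panel matrix
#'
#' A text header line `#nRef <n>` followed by a tab-delimited matrix with
#' `snp_id` leading column and SNP ids as remaining columns.
#' @param file path.
#' @return An [LdPanel-class].
#' @export
readLdPanel <- function(file) {
  l1 <- readLines(file, n = 1L)
  if (!startsWith(l1, "#nRef"))
    stop("malformed LD panel header at ", file, " line 1: expected '#nRef <n>'")
  nRef <- as.integer(strsplit(l1, "[ \t]+")[[1L]][2L])
  df <- utils::read.delim(file, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$snp_id
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- (m + t(m)) / 2  # symmetrize away decimal-printing noise
  LdPanel(ids, m, nRef)
}

#' @rdname readLdPanel
#' @param panel an [LdPanel-class].
#' @export
writeLdPanel <- function(panel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("#nRef\t", panel@nRef), con)
  df <- data.frame(snp_id = panel@snpIds,
                   format(panel@sigma, digits = 17, trim = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("snp_id", panel@snpIds)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read / write the long-format QT table
#'
#' Columns `subject_id`, `stage`, `time_months` (absolute), then one
#' column per QT.
#' @param file path.
#' @export
readQtLong <- function(file) {
  .checkHeader(file, c("subject_id", "stage", "time_months"), "QT table")
  .readTsv(file, "QT table")
}

#' @rdname readQtLong
#' @param data a [LongitudinalDataset-class].
#' @export
writeQtLong <- function(data, file) {
  rows <- NULL
  for (st in data@stages) {
    n <- length(st@subjectIds)
    for (k in seq_along(st@times)) {
      zk <- st@qts[k, , , drop = FALSE]
      dim(zk) <- c(n, length(st@qtNames))
      colnames(zk) <- st@qtNames
      rows <- rbind(rows, data.frame(
        subject_id = st@subjectIds, stage = st@stageIndex,
        time_months = st@timeOffset + st@times[k], zk, check.names = FALSE))
    }
  }
  .writeTsv(rows, file)
  invisible(file)
}

#' Read / write the covariate table
#' @param file path.
#' @export
readCovariates <- function(file) {
  .checkHeader(file, "subject_id", "covariate")
  .readTsv(file, "covariate")
}

#' @rdname readCovariates
#' @param covariates data.frame keyed by `subject_id`.
#' @export
writeCovariates <- function(covariates, file) {
  .writeTsv(covariates, file)
  invisible(file)
}

#' Assemble a LongitudinalDataset from long-format tables
#'
#' Splits the long QT table by stage, keeps for each stage the subjects
#' observed at every one of its visits (no imputation), aligns the
#' genotype rows, and builds the per-stage QT arrays.
#'
#' @param qtLong data.frame from [readQtLong()].
#' @param genotype matrix from [readGenotypeMatrix()].
#' @param covariates optional data.frame.
#' @return A [LongitudinalDataset-class].
#' @export
buildDataset <- function(qtLong, genotype, covariates = NULL) {
  qtCols <- setdiff(colnames(qtLong), c("subject_id", "stage", "time_months"))
  if (!length(qtCols)) stop("QT table has no QT columns")
  stages <- list()
  for (s in sort(unique(qtLong$stage))) {
    sub <- qtLong[qtLong$stage == s, , drop = FALSE]
    times <- sort(unique(sub$time_months))
    tab <- table(sub$subject_id)
    complete <- names(tab)[tab == length(times)]
    complete <- complete[complete %in% rownames(genotype)]
    if (length(complete) < 2L)
      stop("stage ", s, " has fewer than 2 complete, genotyped subjects")
    complete <- sort(complete)
    qts <- array(NA_real_, c(length(times), length(complete), length(qtCols)))
    for (k in seq_along(times)) {
      rowk <- sub[sub$time_months == times[k], , drop = FALSE]
      pos <- match(complete, rowk$subject_id)
      qts[k, , ] <- as.matrix(rowk[pos, qtCols, drop = FALSE])
    }
    stages[[length(stages) + 1L]] <- StageData(
      stageIndex = as.integer(s), subjectIds = complete,
      genotype = genotype[complete, , drop = FALSE],
      qts = qts, times = times, qtNames = qtCols,
      snpIds = colnames(genotype))
  }
  LongitudinalDataset(stages, covariates)
}

## ---- PLINK triplet -----------------------------------------------------

#' Read / write a PLINK .bed/.bim/.fam genotype triplet
#'
#' Minimal codec for the binary PLINK 1 format (SNP-major .bed with the
#' 0x6c 0x1b 0x01 magic): dosages are counts of the .bim A1 allele,
#' missing calls become NA. The writer exists chiefly so round trips can
#' be tested; large-scale PLINK handling is out of scope.
#'
#' @param prefix path without extension.
#' @return list with `genotype` (subjects x SNPs dosage matrix) and
#'   `alleles` (snp_id, a1, a2).
#' @export
readPlink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  bimDf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  famDf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famDf); d <- nrow(bimDf)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic): ", bed)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bps <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bps * d)
    stop(".bed size does not match .bim/.fam dimensions: ", bed)
  ## 2-bit codes per subject: 00 hom A1 (dosage 2), 10 het, 11 hom A2,
  ## 01 missing
  codes <- matrix(0L, 4L * bps, d)
  ints <- as.integer(body)
  dim(ints) <- c(bps, d)
  for (shift in 0:3) {
    codes[seq_len(bps) * 4L - 3L + shift, ] <- ints %% 4L
    ints <- ints %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_real_, n, d)
  dos[codes == 0L] <- 2; dos[codes == 2L] <- 1; dos[codes == 3L] <- 0
  rownames(dos) <- as.character(famDf[[2L]])
  colnames(dos) <- bimDf$snp_id
  list(genotype = dos,
       alleles = bimDf[, c("snp_id", "a1", "a2")])
}

#' @rdname readPlink
#' @param genotype dosage matrix (subjects x SNPs, rownames/colnames set).
#' @param alleles data.frame `snp_id`, `a1`, `a2` matching the columns.
#' @export
writePlink <- function(genotype, alleles, prefix) {
  n <- nrow(genotype); d <- ncol(genotype)
  stopifnot(identical(colnames(genotype), alleles$snp_id))
  famDf <- data.frame(fid = rownames(genotype), iid = rownames(genotype),
                      pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  utils::write.table(famDf, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bimDf <- data.frame(chrom = 0L, snp_id = alleles$snp_id, cm = 0L,
                      pos = seq_len(d), a1 = alleles$a1, a2 = alleles$a2)
  utils::write.table(bimDf, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bps <- ceiling(n / 4)
  codeOf <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  out <- raw(3L + bps * d)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(d)) {
    g <- genotype[, j]
    code <- rep(1L, 4L * bps)  # pad/missing code 01
    code[seq_len(n)] <- ifelse(is.na(g), 1L, codeOf[as.character(g)])
    dim(code) <- c(4L, bps)
    bytes <- code[1L, ] + 4L * code[2L, ] + 16L * code[3L, ] + 64L * code[4L, ]
    out[3L + (j - 1L) * bps + seq_len(bps)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

## ---- fit serialization -------------------------------------------------

#' Write fit artifacts to a directory
#'
#' Per-stage TSV of SNP effects (`snp_id`, intercept-effect columns,
#' slope-effect columns, joint GWAS effect `u`), a TSV of aging effects
#' keyed by `subject_id`, and a YAML run-metadata sidecar (configuration
#' echo, seed, iterations, convergence, objective traces).
#'
#' @param fit a [MscolorFit-class] or [BaselineFit-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the method tag).
#' @return invisibly, the paths written.
#' @export
writeFitTables <- function(fit, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mscolor <- is(fit, "MscolorFit")
  if (is.null(prefix)) prefix <- if (mscolor) "mscolor" else fit@method
  paths <- character(0)
  qtn <- fit@qtNames
  if (mscolor || fit@method == "msmml") {
    W <- if (mscolor) fit@W else fit@params$W
    V <- if (mscolor) fit@V else fit@params$V
    for (s in seq_along(W)) {
      df <- data.frame(snp_id = fit@snpIds, W[[s]], V[[s]],
                       check.names = FALSE)
      colnames(df) <- c("snp_id", paste0("int_", qtn), paste0("slp_", qtn))
      if (mscolor && length(fit@u[[s]])) df$u <- fit@u[[s]]
      p <- file.path(dir, sprintf("%s_stage%d_effects.tsv", prefix, s))
      .writeTsv(df, p); paths <- c(paths, p)
    }
    if (mscolor && fit@control$shareAging) {
      ab <- data.frame(subject_id = fit@subjectRegistry, fit@A, fit@B,
                       check.names = FALSE)
      colnames(ab) <- c("subject_id", paste0("A_", qtn), paste0("B_", qtn))
      p <- file.path(dir, paste0(prefix, "_aging.tsv"))
      .writeTsv(ab, p); paths <- c(paths, p)
    }
  } else if (fit@method == "smml") {
    df <- data.frame(snp_id = fit@snpIds, fit@params$W, fit@params$V,
                     check.names = FALSE)
    colnames(df) <- c("snp_id", paste0("int_", qtn), paste0("slp_", qtn))
    p <- file.path(dir, paste0(prefix, "_effects.tsv"))
    .writeTsv(df, p); paths <- c(paths, p)
  } else {
    df <- data.frame(snp_id = fit@snpIds, fit@params$Wflat,
                     check.names = FALSE)
    p <- file.path(dir, paste0(prefix, "_effects.tsv"))
    .writeTsv(df, p); paths <- c(paths, p)
  }
  meta <- list(
    method = if (mscolor) "mscolor" else fit@method,
    control = fit@control,
    nIter = fit@nIter,
    converged = fit@converged,
    finalObjective = as.numeric(utils::tail(fit@objectiveTrace, 1L)),
    objectiveTrace = as.numeric(fit@objectiveTrace),
    surrogateTrace = as.numeric(fit@surrogateTrace),
    packageVersion = as.character(utils::packageVersion("mscolor")))
  p <- file.path(dir, paste0(prefix, "_run.yaml"))
  yaml::write_yaml(meta, p); paths <- c(paths, p)
  invisible(paths)
}
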