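#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests performed (>= 1).
#' @param alpha family-wise error level in (0, 1), default 0.05.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(1024)  # 4.9e-05 at two significant figures
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(length(nTests) == 1L, nTests >= 1, alpha > 0, alpha < 1)
  alpha / nTests
}

#' Run the full association pipeline
#'
#' Reads genotypes, gene intervals and phenotypes, builds gene groups and
#' the collapsed design, fits a descending-kappa path, and writes three
#' files: `<prefix>_path.tsv` (one row per nonzero predictor per kappa),
#' `<prefix>_summary.tsv` (kappa, model size, groups, objective,
#' convergence), and `<prefix>_log.txt` with the group-construction
#' bookkeeping (genes read, removed, merged; SNPs inside genes, outside
#' singletons, dropped).
#'
#' The phenotype table may either carry a single `trait` value per
#' individual or be a long-format repeated-measures table with covariate
#' columns, in which case it is residualized first (see [residualize()]).
#'
#' @param vcf path to the genotype VCF.
#' @param genes path to the gene interval table (see [readGeneTable()]).
#' @param pheno path to the phenotype table (see [readPhenotypeTable()]);
#'   columns `id` and `trait` required, covariates optional.
#' @param out output file prefix.
#' @param tau rare/common MAF threshold (default 0.005).
#' @param mafFloor outside-gene common-MAF floor (default 0.01).
#' @param kappas explicit descending kappa grid; default is `nKappas`
#'   log-spaced values from kappa_max down to `minFraction` of it.
#' @param nKappas,minFraction default-grid settings.
#' @param control see [percControl()].
#' @param traitCol,idCol phenotype column names.
#' @return invisibly, a list with `path` (the [PercPath-class]), `design`,
#'   `groups`, `phenotype` and the output file paths.
#' @export
percRun <- function(vcf, genes, pheno, out = "perc",
                    tau = 0.005, mafFloor = 0.01,
                    kappas = NULL, nKappas = 20L, minFraction = 0.01,
                    control = percControl(),
                    traitCol = "trait", idCol = "id") {
  gm <- readGenotypes(vcf)
  geneTab <- readGeneTable(genes)
  ptab <- readPhenotypeTable(pheno)

  covCols <- setdiff(names(ptab), c(idCol, traitCol, "time"))
  pv <- if (length(covCols) || anyDuplicated(ptab[[idCol]])) {
    residualize(ptab, idCol = idCol, traitCol = traitCol)
  } else {
    ids <- as.character(ptab[[idCol]])
    new("PhenotypeVector", sampleIds = ids[order(ids)],
        trait = as.numeric(ptab[[traitCol]])[order(ids)])
  }

  missing <- setdiff(sampleIds(gm), sampleIds(pv))
  if (length(missing))
    stop("phenotype table is missing VCF sample(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  y <- trait(pv)[sampleIds(gm)]

  groups <- buildGeneGroups(geneTab, gm, commonMafFloor = mafFloor)
  design <- buildDesign(gm, groups, tau = tau)
  path <- percFitPath(y, design, kappas = kappas, control = control,
                      nKappas = nKappas, minFraction = minFraction)

  files <- .writeRunOutputs(out, path, design, groups, geneTab, gm,
                            mafFloor)
  invisible(list(path = path, design = design, groups = groups,
                 phenotype = pv, files = files))
}

.writeRunOutputs <- function(prefix, path, design, groups, geneTab, gm,
                             mafFloor) {
  info <- columnInfo(design)
  gInfo <- groupInfo(design)
  rows <- list()
  for (k in seq_along(pathKappas(path))) {
    f <- path[[k]]
    act <- activeSet(f)
    if (!length(act)) next
    rows[[k]] <- data.frame(
      kappa = pathKappas(path)[k],
      predictor = info$label[act],
      group = gInfo$label[info$group[act]],
      kind = info$kind[act],
      coefficient = sprintf("%.12g", f@coef@beta[act]),
      stringsAsFactors = FALSE)
  }
  pathFile <- paste0(prefix, "_path.tsv")
  pathTab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kappa = numeric(), predictor = character(),
               group = character(), kind = character(),
               coefficient = character())
  utils::write.table(pathTab, pathFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summaryFile <- paste0(prefix, "_summary.tsv")
  sumTab <- data.frame(
    kappa = pathKappas(path),
    modelSize = modelSizes(path),
    nGroups = vapply(pathFits(path), function(f)
      length(selectedGroups(f)), integer(1)),
    objective = sprintf("%.12g", vapply(pathFits(path), objectiveValue,
                                        numeric(1))),
    cycles = vapply(pathFits(path), function(f) f@nCycles, integer(1)),
    status = vapply(pathFits(path), function(f) f@status, character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(sumTab, summaryFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  kind <- S4Vectors::mcols(groupRanges(groups))$kind
  nIn <- sum(lengths(groupMembers(groups))[kind == "gene"])
  logFile <- paste0(prefix, "_log.txt")
  writeLines(c(
    sprintf("gene records read: %d (%d symbols)", nrow(geneTab),
            length(unique(geneTab$symbol))),
    sprintf("gene groups after span filter and merging: %d",
            sum(kind == "gene")),
    sprintf("SNPs total: %d", nSnps(gm)),
    sprintf("SNPs within a gene: %d", nIn),
    sprintf("outside-gene SNPs kept as singletons (MAF > %g): %d",
            mafFloor, sum(kind == "singleton")),
    sprintf("SNPs dropped: %d", length(droppedSnps(groups))),
    sprintf("design columns: %d (%d collapsed rare)",
            nPredictors(design),
            sum(columnInfo(design)$kind == "collapsed_rare"))
  ), logFile)

  list(path = pathFile, summary = summaryFile, log = logFile)
}
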