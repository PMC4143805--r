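#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a desk-scale rare-plus-common variant study: 500
#' unrelated individuals, 20 genes of 30 SNPs each with 40% rare SNPs
#' (rare MAF uniform on [0.001, 0.005), common MAF uniform on
#' [0.05, 0.5]), one causal gene carrying a rare-burden effect of 0.8
#' noise SDs and one common-variant effect of 0.5 noise SDs.
#'
#' @param nIndividuals cohort size.
#' @param nGenes number of genes laid out along one chromosome.
#' @param snpsPerGene SNPs per gene.
#' @param fractionRare fraction of each gene's SNPs that are rare.
#' @param rareMafRange,commonMafRange MAF ranges (uniform draws).
#' @param causalGenes integer indices of causal genes.
#' @param burdenEffect trait increase per rare allele carried in a causal
#'   gene (same units as the trait).
#' @param commonEffect per-dosage effect of one designated common SNP in
#'   each causal gene.
#' @param noiseSd residual standard deviation of the trait.
#' @param nOutsideSnps common SNPs placed between genes (become singleton
#'   groups).
#' @param overlapGenes integer indices `g` for which gene `g`'s interval
#'   is extended to overlap gene `g + 1`, to exercise interval merging.
#' @param geneSpan base-pair span of each gene.
#' @param withCovariates also generate age/sex/smoking/medication with
#'   known coefficients and return a long-format records table with
#'   `timePoints` measurements per individual.
#' @param timePoints repeated measurements per individual when covariates
#'   are generated.
#' @param seed RNG seed fixing the full output.
#' @return classed list of settings (`PercSimConfig`).
#' @export
percSimConfig <- function(nIndividuals = 500L, nGenes = 20L,
                          snpsPerGene = 30L, fractionRare = 0.4,
                          rareMafRange = c(0.001, 0.005),
                          commonMafRange = c(0.05, 0.5),
                          causalGenes = 1L,
                          burdenEffect = 0.8, commonEffect = 0.5,
                          noiseSd = 1, nOutsideSnps = 0L,
                          overlapGenes = integer(),
                          geneSpan = 2000L,
                          withCovariates = FALSE, timePoints = 2L,
                          seed = 1L) {
  stopifnot(nIndividuals > 0, nGenes > 0, snpsPerGene > 0,
            fractionRare >= 0, fractionRare <= 1,
            all(rareMafRange > 0), all(commonMafRange <= 0.5),
            noiseSd >= 0, geneSpan >= 1,
            all(causalGenes >= 1), all(causalGenes <= nGenes))
  structure(list(
    nIndividuals = as.integer(nIndividuals), nGenes = as.integer(nGenes),
    snpsPerGene = as.integer(snpsPerGene), fractionRare = fractionRare,
    rareMafRange = rareMafRange, commonMafRange = commonMafRange,
    causalGenes = as.integer(causalGenes),
    burdenEffect = burdenEffect, commonEffect = commonEffect,
    noiseSd = noiseSd, nOutsideSnps = as.integer(nOutsideSnps),
    overlapGenes = as.integer(overlapGenes),
    geneSpan = as.integer(geneSpan),
    withCovariates = isTRUE(withCovariates),
    timePoints = as.integer(timePoints),
    seed = as.integer(seed)), class = "PercSimConfig")
}

#' Simulate genotypes and a gene map
#'
#' Each SNP's two alleles are independent Bernoulli draws at its MAF
#' (Hardy-Weinberg, no linkage disequilibrium), so dosages are
#' Binomial(2, MAF). Genes are laid out as non-overlapping intervals on
#' one chromosome; `overlapGenes` extends chosen intervals into their
#' right neighbour to exercise interval merging. Outside-gene common SNPs
#' are placed in the gaps between genes.
#'
#' @param cfg a [percSimConfig()] object.
#' @return list with `genotypes` (a [GenotypeMatrix-class]), `geneTable`
#'   (`data.frame`: chrom, start, end, symbol) and `truth` (per-SNP gene
#'   index, rare flag, causal-SNP bookkeeping).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "PercSimConfig"))
  set.seed(cfg$seed)
  nRare <- round(cfg$snpsPerGene * cfg$fractionRare)
  nCommon <- cfg$snpsPerGene - nRare
  gap <- 1000L
  pitch <- cfg$geneSpan + gap

  snpMaf <- numeric(); snpPos <- integer(); snpGene <- integer()
  snpRare <- logical()
  geneTab <- data.frame(chrom = character(), start = integer(),
                        end = integer(), symbol = character(),
                        stringsAsFactors = FALSE)
  for (g in seq_len(cfg$nGenes)) {
    gStart <- (g - 1L) * pitch + 1L
    gEnd <- gStart + cfg$geneSpan - 1L
    if (g %in% cfg$overlapGenes) gEnd <- gEnd + gap + cfg$geneSpan %/% 2L
    geneTab <- rbind(geneTab, data.frame(
      chrom = "chr1", start = gStart, end = gEnd,
      symbol = sprintf("GENE%02d", g), stringsAsFactors = FALSE))
    maf <- c(runif(nRare, cfg$rareMafRange[1], cfg$rareMafRange[2]),
             runif(nCommon, cfg$commonMafRange[1], cfg$commonMafRange[2]))
    pos <- sort(sample.int(cfg$geneSpan, cfg$snpsPerGene)) + gStart - 1L
    snpMaf <- c(snpMaf, maf); snpPos <- c(snpPos, pos)
    snpGene <- c(snpGene, rep(g, cfg$snpsPerGene))
    snpRare <- c(snpRare, rep(c(TRUE, FALSE), c(nRare, nCommon)))
  }
  if (cfg$nOutsideSnps > 0L) {
    # outside SNPs live in the gap after a random gene
    host <- sample.int(cfg$nGenes, cfg$nOutsideSnps, replace = TRUE)
    pos <- (host - 1L) * pitch + cfg$geneSpan + 1L +
      sample.int(gap - 2L, cfg$nOutsideSnps, replace = TRUE)
    maf <- runif(cfg$nOutsideSnps, cfg$commonMafRange[1],
                 cfg$commonMafRange[2])
    snpMaf <- c(snpMaf, maf); snpPos <- c(snpPos, pos)
    snpGene <- c(snpGene, rep(0L, cfg$nOutsideSnps))
    snpRare <- c(snpRare, rep(FALSE, cfg$nOutsideSnps))
  }

  ord <- order(snpPos)
  snpMaf <- snpMaf[ord]; snpPos <- snpPos[ord]
  snpGene <- snpGene[ord]; snpRare <- snpRare[ord]
  p <- length(snpPos)
  m <- cfg$nIndividuals

  dos <- matrix(rbinom(m * p, 2L, rep(snpMaf, each = m)), nrow = m)
  ids <- sprintf("S%04d", seq_len(m))
  snpIds <- sprintf("snp%05d", seq_len(p))
  rownames(dos) <- ids; colnames(dos) <- snpIds

  empMaf <- vapply(seq_len(p), function(j) computeMaf(dos[, j]),
                   numeric(1))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = snpPos, width = 1L),
                               id = snpIds)
  gm <- new("GenotypeMatrix", dosages = dos, positions = gr, maf = empMaf)
  list(genotypes = gm, geneTable = geneTab,
       truth = data.frame(id = snpIds, pos = snpPos, gene = snpGene,
                          rare = snpRare, trueMaf = snpMaf,
                          stringsAsFactors = FALSE))
}

#' Simulate a quantitative trait with known causal structure
#'
#' \deqn{y_i = \sum_{k \in causal~CVs} \beta_k x_{ik} + \sum_{g \in
#'   causal~genes} \beta_g b_{ig} + \varepsilon_i}
#' where \eqn{b_{ig}} is individual `i`'s raw rare-allele count in causal
#' gene `g` and \eqn{\varepsilon_i \sim N(0, noiseSd^2)}. In each causal
#' gene the common SNP closest to MAF 0.25 carries `commonEffect`. With
#' `withCovariates = TRUE`, covariate effects (age 0.3, age-squared
#' -0.002, sex 2, smoking 1.5, medication -3, on the trait scale) and
#' repeated time points are layered on top so the full residualization
#' pipeline can be exercised; otherwise the trait is generated directly
#' on the residual scale.
#'
#' @param sim output of [simulateGenotypes()].
#' @param cfg the same [percSimConfig()] object.
#' @return list with `phenotype` (a [PhenotypeVector-class] of the
#'   noise-level trait), `records` (long-format covariate table, `NULL`
#'   unless `withCovariates`), and `causalSnps` (ids of the planted
#'   common-variant signals).
#' @export
simulateTrait <- function(sim, cfg) {
  stopifnot(inherits(cfg, "PercSimConfig"))
  set.seed(cfg$seed + 1000000L)
  dos <- dosages(sim$genotypes)
  truth <- sim$truth
  m <- nrow(dos)
  y <- numeric(m)
  causalSnps <- character()
  for (g in cfg$causalGenes) {
    rare <- truth$gene == g & truth$rare
    if (any(rare))
      y <- y + cfg$burdenEffect * rowSums(dos[, rare, drop = FALSE])
    common <- which(truth$gene == g & !truth$rare)
    if (length(common) && cfg$commonEffect != 0) {
      pick <- common[which.min(abs(truth$trueMaf[common] - 0.25))]
      y <- y + cfg$commonEffect * dos[, pick]
      causalSnps <- c(causalSnps, truth$id[pick])
    }
  }
  y <- y + rnorm(m, 0, cfg$noiseSd)
  ids <- rownames(dos)
  pheno <- new("PhenotypeVector", sampleIds = ids, trait = as.numeric(y))

  records <- NULL
  if (cfg$withCovariates) {
    covBeta <- c(age = 0.3, age2 = -0.002, sex = 2, smoke = 1.5,
                 meds = -3)
    age0 <- runif(m, 30, 70)
    sex <- rbinom(m, 1L, 0.5)
    smoke <- rbinom(m, 1L, 0.3)
    meds <- rbinom(m, 1L, 0.2)
    tp <- cfg$timePoints
    records <- data.frame(
      id = rep(ids, each = tp),
      time = rep(seq_len(tp), times = m),
      age = rep(age0, each = tp) + rep(seq_len(tp) - 1L, times = m) * 2,
      sex = rep(sex, each = tp),
      smoke = rep(smoke, each = tp),
      meds = rep(meds, each = tp),
      stringsAsFactors = FALSE)
    records$trait <- rep(y, each = tp) +
      covBeta["age"] * records$age + covBeta["age2"] * records$age^2 +
      covBeta["sex"] * records$sex + covBeta["smoke"] * records$smoke +
      covBeta["meds"] * records$meds +
      rnorm(nrow(records), 0, cfg$noiseSd * 0.2)
  }
  list(phenotype = pheno, records = records, causalSnps = causalSnps)
}

#' One-call synthetic dataset
#'
#' Runs [simulateGenotypes()], [simulateTrait()] and
#' [buildGeneGroups()] under the config's seed and returns everything a
#' fit needs. Optionally writes the VCF, gene table and phenotype CSV to
#' `dir` in the same dialects the readers consume.
#'
#' @param cfg a [percSimConfig()] object.
#' @param dir optional output directory; when given, writes
#'   `genotypes.vcf`, `genes.tsv` and `phenotype.csv` there.
#' @return list with `genotypes`, `geneTable`, `groups`, `phenotype`,
#'   `records`, `truth`, `causalSnps`, and (when written) `paths`.
#' @export
simulatePercData <- function(cfg = percSimConfig(), dir = NULL) {
  sim <- simulateGenotypes(cfg)
  tr <- simulateTrait(sim, cfg)
  groups <- buildGeneGroups(sim$geneTable, sim$genotypes)
  out <- list(genotypes = sim$genotypes, geneTable = sim$geneTable,
              groups = groups, phenotype = tr$phenotype,
              records = tr$records, truth = sim$truth,
              causalSnps = tr$causalSnps)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                  genes = file.path(dir, "genes.tsv"),
                  pheno = file.path(dir, "phenotype.csv"))
    writeGenotypesVcf(sim$genotypes, paths$vcf)
    utils::write.table(sim$geneTable, paths$genes, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ptab <- if (!is.null(tr$records)) tr$records else
      data.frame(id = sampleIds(tr$phenotype),
                 trait = as.numeric(trait(tr$phenotype)))
    utils::write.table(ptab, paths$pheno, sep = ",", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
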