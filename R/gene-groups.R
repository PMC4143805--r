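#' Read a gene interval table
#'
#' Tab-delimited, four columns `chrom / start / end / symbol`; a header
#' line is auto-detected (a first line whose second field is not numeric).
#'
#' @param path file path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `symbol`.
#' @export
readGeneTable <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  hasHeader <- length(fields) >= 2L &&
    is.na(suppressWarnings(as.numeric(fields[2])))
  tab <- utils::read.table(path, sep = "\t", header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("gene table must have 4 columns: chrom, start, end, symbol")
  tab <- tab[, 1:4]
  names(tab) <- c("chrom", "start", "end", "symbol")
  tab$chrom <- as.character(tab$chrom)
  tab$symbol <- as.character(tab$symbol)
  tab
}

#' Build gene-based SNP groups from an interval table
#'
#' Implements the gene-region construction used for gene-based analysis:
#'
#' 1. Per gene symbol, the span is the minimum start to the maximum end of
#'    its records; symbols whose records lie on multiple chromosomes are
#'    removed.
#' 2. Spans shorter than `minSpan` base pairs are removed (span length is
#'    `end - start + 1` under 1-based fully-closed coordinates).
#' 3. Overlapping spans on a chromosome (sharing at least one base) are
#'    merged into one group whose label joins the symbols with `":"` in
#'    genomic order.
#' 4. SNPs with `start <= pos <= end` for some span are assigned to that
#'    group; SNPs outside all spans become singleton groups when their MAF
#'    exceeds `commonMafFloor` and are dropped otherwise.
#'
#' @param genes `data.frame` with columns `chrom`, `start`, `end`,
#'   `symbol` (1-based closed intervals), or a path readable by
#'   [readGeneTable()].
#' @param genotypes a [GenotypeMatrix-class] supplying SNP positions and
#'   MAFs.
#' @param commonMafFloor outside-gene SNPs with MAF at or below this value
#'   are dropped (default 0.01).
#' @param minSpan minimum gene span in base pairs (default 500).
#' @return a [GeneGroupSet-class].
#' @export
buildGeneGroups <- function(genes, genotypes, commonMafFloor = 0.01,
                            minSpan = 500L) {
  if (is.character(genes) && length(genes) == 1L)
    genes <- readGeneTable(genes)
  stopifnot(is(genotypes, "GenotypeMatrix"))
  snpGr <- snpPositions(genotypes)
  maf <- mafs(genotypes)

  if (nrow(genes) == 0L) {
    warning("empty gene table: all SNPs considered outside-gene")
    spans <- GenomicRanges::GRanges()
  } else {
    if (any(genes$end <= genes$start))
      stop("gene interval(s) with end <= start: ",
           paste(utils::head(genes$symbol[genes$end <= genes$start], 5L),
                 collapse = ", "))
    # per-symbol span: min start to max end; multi-chromosome symbols out
    bySym <- split(genes, genes$symbol)
    keep <- vapply(bySym, function(g)
      length(unique(g$chrom)) == 1L, logical(1))
    bySym <- bySym[keep]
    spans <- if (length(bySym)) {
      GenomicRanges::GRanges(
        seqnames = vapply(bySym, function(g) g$chrom[1], character(1)),
        ranges = IRanges::IRanges(
          start = vapply(bySym, function(g) min(g$start), numeric(1)),
          end = vapply(bySym, function(g) max(g$end), numeric(1))),
        symbol = names(bySym)
      )
    } else GenomicRanges::GRanges()
    # closed-coordinate span length is width (end - start + 1)
    spans <- spans[BiocGenerics::width(spans) >= minSpan]
  }

  if (length(spans)) {
    ordSp <- order(as.character(GenomicRanges::seqnames(spans)),
                   GenomicRanges::start(spans))
    spans <- spans[ordSp]
    # merge only spans that share a base; adjacency is not overlap
    merged <- GenomicRanges::reduce(spans, min.gapwidth = 0L,
                                    with.revmap = TRUE)
    labels <- vapply(S4Vectors::mcols(merged)$revmap, function(ii)
      paste(S4Vectors::mcols(spans)$symbol[ii], collapse = ":"),
      character(1))
    S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
      label = labels, kind = rep("gene", length(merged)))
  } else {
    merged <- GenomicRanges::GRanges()
  }

  hits <- GenomicRanges::findOverlaps(snpGr, merged, ignore.strand = TRUE)
  inGene <- S4Vectors::queryHits(hits)
  members <- lapply(seq_along(merged), function(g)
    sort(inGene[S4Vectors::subjectHits(hits) == g]))

  outside <- setdiff(seq_along(snpGr), inGene)
  commonOut <- outside[maf[outside] > commonMafFloor]
  droppedOut <- setdiff(outside, commonOut)

  geneDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    label = if (length(merged)) S4Vectors::mcols(merged)$label else character(),
    kind = rep("gene", length(merged)),
    stringsAsFactors = FALSE)
  singDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(snpGr))[commonOut],
    start = GenomicRanges::start(snpGr)[commonOut],
    end = GenomicRanges::start(snpGr)[commonOut],
    label = S4Vectors::mcols(snpGr)$id[commonOut],
    kind = rep("singleton", length(commonOut)),
    stringsAsFactors = FALSE)
  allDf <- rbind(geneDf, singDf)
  members <- c(members, as.list(commonOut))

  ord <- order(allDf$chrom, allDf$start, allDf$end)
  allDf <- allDf[ord, , drop = FALSE]
  allRanges <- GenomicRanges::GRanges(
    seqnames = allDf$chrom,
    ranges = IRanges::IRanges(start = allDf$start, end = allDf$end),
    label = allDf$label, kind = allDf$kind)
  new("GeneGroupSet",
      groupRanges = allRanges,
      members = lapply(members[ord], as.integer),
      dropped = as.integer(sort(droppedOut)))
}
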