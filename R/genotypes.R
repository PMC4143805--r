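#' Minor allele frequency of one dosage column
#'
#' Computes the alternate-allele frequency over non-missing diploid calls
#' and folds it to the minor side, `min(f, 1 - f)`, so the result lies in
#' `[0, 0.5]` regardless of which allele is labelled REF.
#'
#' @param dosages numeric vector of allele counts in `{0, 1, 2}`, `NA`
#'   allowed for missing calls.
#' @param snpId optional SNP name used in error messages.
#' @return minor allele frequency in `[0, 0.5]`.
#' @examples
#' computeMaf(c(0, 1, 1, 2))  # 4 alt alleles over 8 -> 0.5
#' computeMaf(c(2, 2, 2, 2))  # alt is the major allele -> 0
#' @export
computeMaf <- function(dosages, snpId = NULL) {
  ok <- !is.na(dosages)
  if (!any(ok))
    stop("all calls missing for SNP ",
         if (is.null(snpId)) "<unnamed>" else snpId)
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

## Parse a vector of GT strings ("0/1", "1|0", "./.", ...) into dosages.
.gtToDosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]", perl = TRUE)
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == "." | a == ""))
      return(NA_real_)
    sum(a == "1")
  }, numeric(1))
}

#' Read a VCF file into a GenotypeMatrix
#'
#' Reads diploid, biallelic SNP records (GT field; other FORMAT fields are
#' ignored), counts alternate alleles per call, and computes per-SNP minor
#' allele frequencies over non-missing calls. Multiallelic records (a
#' comma in ALT) are rejected by default; with `splitMultiallelic = TRUE`
#' each alternate allele becomes its own biallelic record in which calls
#' carrying any *other* alternate allele are set missing.
#'
#' @param vcfPath path to a VCF (v4.x) file, plain text or gzipped.
#' @param splitMultiallelic split multiallelic records instead of
#'   rejecting them.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(vcfPath, splitMultiallelic = FALSE) {
  if (!file.exists(vcfPath)) stop("VCF file not found: ", vcfPath)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcfPath, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcfPath, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", vcfPath)
  if (ncol(vcf@gt) < 2L) stop("VCF contains zero samples: ", vcfPath)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(chrom[noid], ":", pos[noid])
  alt <- fix[, "ALT"]

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && !splitMultiallelic)
    stop("multiallelic record(s) at ",
         paste(utils::head(paste0(chrom[multi], ":", pos[multi]), 5L),
               collapse = ", "),
         "; set splitMultiallelic = TRUE to split them")

  dosList <- vector("list", nrow(fix))
  posList <- vector("list", nrow(fix))
  for (k in seq_len(nrow(fix))) {
    calls <- gt[k, ]
    if (!multi[k]) {
      dosList[[k]] <- matrix(.gtToDosage(calls), ncol = 1)
      posList[[k]] <- data.frame(chrom = chrom[k], pos = pos[k],
                                 id = ids[k])
    } else {
      nAlt <- length(strsplit(alt[k], ",", fixed = TRUE)[[1]])
      sub <- lapply(seq_len(nAlt), function(a) {
        parts <- strsplit(sub(":.*$", "", calls), "[/|]", perl = TRUE)
        vapply(parts, function(al) {
          if (length(al) != 2L || any(al == "." | al == ""))
            return(NA_real_)
          num <- suppressWarnings(as.integer(al))
          if (any(is.na(num))) return(NA_real_)
          # calls carrying a different alt allele are uninformative here
          if (any(num != 0L & num != a)) return(NA_real_)
          sum(num == a)
        }, numeric(1))
      })
      dosList[[k]] <- do.call(cbind, lapply(sub, unname))
      posList[[k]] <- data.frame(
        chrom = unname(chrom[k]), pos = unname(pos[k]),
        id = paste0(unname(ids[k]), "_alt", seq_len(nAlt)),
        row.names = NULL)
    }
  }
  dos <- do.call(cbind, dosList)       # samples x snps
  posTab <- do.call(rbind, posList)
  rownames(dos) <- samples
  colnames(dos) <- posTab$id

  maf <- vapply(seq_len(ncol(dos)), function(j)
    computeMaf(dos[, j], snpId = posTab$id[j]), numeric(1))

  gr <- GenomicRanges::GRanges(
    seqnames = posTab$chrom,
    ranges = IRanges::IRanges(start = posTab$pos, width = 1L),
    id = posTab$id
  )
  new("GenotypeMatrix", dosages = dos, positions = gr, maf = maf)
}

#' Write a GenotypeMatrix as a minimal VCF text file
#'
#' Emits a plain-text VCF v4.2 with GT-only genotype fields, the dialect
#' consumed by [readGenotypes()]. Missing calls are written as `./.`.
#' REF/ALT are written as A/B placeholder alleles since the dosage model
#' does not track nucleotides.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  d <- dosages(genotypes)
  gr <- snpPositions(genotypes)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gtStr[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=PeRC_simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- vapply(seq_along(gr), function(j) {
    paste(c(as.character(GenomicRanges::seqnames(gr)[j]),
            GenomicRanges::start(gr)[j],
            S4Vectors::mcols(gr)$id[j],
            "A", "B", ".", "PASS", ".", "GT",
            gtStr[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
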