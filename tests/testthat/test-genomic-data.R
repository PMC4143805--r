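writeTestVcf <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

test_that("computeMaf folds to the minor allele and skips missing calls", {
  expect_identical(computeMaf(c(0, 0, 0, 0)), 0)           # monomorphic
  expect_identical(computeMaf(c(2, 2, 2, 2)), 0)           # alt is major
  expect_equal(computeMaf(c(0, 1, 1, 2)), 0.5)             # 4/8
  expect_equal(computeMaf(c(0, 1, 2, NA)), 0.5)            # 3/6 non-missing
  expect_equal(computeMaf(c(0, 0, 1)), 1 / 6)
  expect_error(computeMaf(c(NA, NA), snpId = "rs1"), "rs1")
})

test_that("computeMaf is invariant to dosage complementation", {
  set.seed(11)
  for (rep in 1:20) {
    d <- rbinom(30, 2, runif(1, 0.02, 0.98))
    d[sample(30, 3)] <- NA
    if (all(is.na(d))) next
    expect_equal(computeMaf(d), computeMaf(2 - d))
  }
})

test_that("readGenotypes counts alt alleles, flags missing, computes MAF", {
  p <- writeTestVcf(c(
    "chr3\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1\t./.",
    "chr3\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0\t0/0",
    "chr3\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1|1\t1/1\t1/1\t0/1"),
    c("s1", "s2", "s3", "s4"))
  gm <- readGenotypes(p)
  expect_equal(nSamples(gm), 4L)
  expect_equal(nSnps(gm), 3L)
  expect_equal(unname(dosages(gm)[, "rs1"]), c(1, 0, 2, NA))
  expect_equal(mafs(gm), c(3 / 6, 0, 1 / 8))   # rs1 over non-missing only
  expect_equal(GenomicRanges::start(snpPositions(gm)), c(100L, 200L, 300L))
})

test_that("single het sample gives dosage 1 and MAF 0.5", {
  p <- writeTestVcf("chr1\t50\trsX\tA\tG\t.\tPASS\t.\tGT\t0/1", "s1")
  gm <- readGenotypes(p)
  expect_equal(unname(dosages(gm)[1, 1]), 1)
  expect_equal(mafs(gm), 0.5)
})

test_that("multiallelic records are rejected by default and split on request", {
  p <- writeTestVcf(
    "chr1\t10\trsM\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2",
    c("s1", "s2", "s3"))
  expect_error(readGenotypes(p), "multiallelic")
  gm <- readGenotypes(p, splitMultiallelic = TRUE)
  expect_equal(nSnps(gm), 2L)
  # allele-1 record: 0/1 -> 1; 0/2 carries another alt -> NA; 1/2 -> NA
  expect_equal(unname(dosages(gm)[, 1]), c(1, NA, NA))
  expect_equal(unname(dosages(gm)[, 2]), c(NA, 1, NA))
})

test_that("malformed and sample-free VCFs error clearly", {
  bad <- tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", bad)
  expect_error(readGenotypes(bad))
  expect_error(readGenotypes(tempfile(fileext = ".vcf")), "not found")
})

makeGm <- function(pos, maf, chrom = "chr3", n = 40, seed = 5) {
  set.seed(seed)
  p <- length(pos)
  d <- sapply(maf, function(f) rbinom(n, 2, f))
  # force the empirical folded frequency near the requested one
  rownames(d) <- sprintf("s%03d", seq_len(n))
  colnames(d) <- sprintf("v%03d", seq_len(p))
  emp <- apply(d, 2, computeMaf)
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = pos, width = 1L), id = colnames(d))
  new("GenotypeMatrix", dosages = d, positions = gr, maf = emp)
}

test_that("overlapping gene spans merge with ':'-joined labels", {
  gm <- makeGm(pos = c(150, 650, 1200), maf = c(0.3, 0.3, 0.3))
  genes <- data.frame(chrom = "chr3", start = c(100, 600),
                      end = c(700, 1300), symbol = c("A", "B"))
  gg <- buildGeneGroups(genes, gm)
  expect_equal(nGroups(gg), 1L)
  expect_equal(S4Vectors::mcols(groupRanges(gg))$label, "A:B")
  expect_equal(GenomicRanges::start(groupRanges(gg)), 100L)
  expect_equal(GenomicRanges::end(groupRanges(gg)), 1300L)
  expect_equal(groupMembers(gg)[[1]], 1:3)
})

test_that("adjacent-but-not-overlapping spans are kept separate", {
  gm <- makeGm(pos = c(150, 800), maf = c(0.3, 0.3))
  genes <- data.frame(chrom = "chr3", start = c(100, 701),
                      end = c(700, 1300), symbol = c("A", "B"))
  gg <- buildGeneGroups(genes, gm)
  expect_equal(nGroups(gg), 2L)
  expect_equal(S4Vectors::mcols(groupRanges(gg))$label, c("A", "B"))
})

test_that("genes under 500 bp are removed and their SNPs treated as outside", {
  gm <- makeGm(pos = c(150, 250), maf = c(0.3, 0))
  genes <- data.frame(chrom = "chr3", start = 100, end = 400,
                      symbol = "C")   # 301 bp < 500
  gg <- buildGeneGroups(genes, gm)
  kind <- S4Vectors::mcols(groupRanges(gg))$kind
  expect_false(any(kind == "gene"))
  # common outside SNP -> singleton; rare outside SNP -> dropped
  expect_equal(sum(kind == "singleton"), 1L)
  expect_equal(droppedSnps(gg), 2L)
  # exactly 500 bp survives (closed-coordinate length end - start + 1)
  genes500 <- data.frame(chrom = "chr3", start = 100, end = 599,
                         symbol = "C")
  gg500 <- buildGeneGroups(genes500, gm)
  expect_true("gene" %in% S4Vectors::mcols(groupRanges(gg500))$kind)
})

test_that("SNPs at exact span boundaries belong to the gene (closed)", {
  gm <- makeGm(pos = c(100, 700, 99, 701), maf = rep(0.3, 4))
  genes <- data.frame(chrom = "chr3", start = 100, end = 700,
                      symbol = "A")
  gg <- buildGeneGroups(genes, gm)
  geneIdx <- which(S4Vectors::mcols(groupRanges(gg))$kind == "gene")
  expect_equal(sort(groupMembers(gg)[[geneIdx]]), c(1L, 2L))
})

test_that("multi-chromosome symbols are removed; floor rule is strict", {
  gm <- makeGm(pos = c(150, 5000), maf = c(0.3, 0.02))
  genes <- data.frame(chrom = c("chr3", "chr7"), start = c(100, 100),
                      end = c(700, 700), symbol = c("D", "D"))
  gg <- buildGeneGroups(genes, gm, commonMafFloor = 0.01)
  expect_false(any(S4Vectors::mcols(groupRanges(gg))$kind == "gene"))
  # MAF exactly at the floor is dropped (rule is MAF > floor)
  ggEq <- buildGeneGroups(genes, gm,
                          commonMafFloor = computeMaf(dosages(gm)[, 1]))
  expect_true(1L %in% droppedSnps(ggEq))
})

test_that("empty gene table warns and makes all SNPs outside-gene", {
  gm <- makeGm(pos = c(100, 200), maf = c(0.3, 0.004))
  genes <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), symbol = character())
  expect_warning(gg <- buildGeneGroups(genes, gm), "empty gene table")
  expect_true(all(S4Vectors::mcols(groupRanges(gg))$kind == "singleton"))
  expect_error(buildGeneGroups(
    data.frame(chrom = "chr3", start = 700, end = 700, symbol = "Z"),
    gm), "end <= start")
})

test_that("groups partition the SNP set and merging is idempotent", {
  set.seed(42)
  for (rep in 1:10) {
    nG <- sample(3:6, 1)
    starts <- sort(sample.int(9000, nG))
    ends <- starts + sample(400:1500, nG, replace = TRUE)
    genes <- data.frame(chrom = "chr3", start = starts, end = ends,
                        symbol = LETTERS[seq_len(nG)])
    pos <- sort(sample.int(11000, 30))
    gm <- makeGm(pos = pos, maf = runif(30, 0.002, 0.4), seed = rep)
    gg <- buildGeneGroups(genes, gm)
    idx <- c(unlist(groupMembers(gg)), droppedSnps(gg))
    expect_equal(sort(idx), seq_len(30L))
    expect_false(anyDuplicated(idx) > 0)
    # idempotence: re-merging the merged spans changes nothing
    gr <- groupRanges(gg)
    geneRows <- S4Vectors::mcols(gr)$kind == "gene"
    if (any(geneRows)) {
      genes2 <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr))[geneRows],
        start = GenomicRanges::start(gr)[geneRows],
        end = GenomicRanges::end(gr)[geneRows],
        symbol = S4Vectors::mcols(gr)$label[geneRows])
      gg2 <- buildGeneGroups(genes2, gm)
      gr2 <- groupRanges(gg2)
      geneRows2 <- S4Vectors::mcols(gr2)$kind == "gene"
      expect_equal(GenomicRanges::start(gr2)[geneRows2],
                   GenomicRanges::start(gr)[geneRows])
      expect_equal(GenomicRanges::end(gr2)[geneRows2],
                   GenomicRanges::end(gr)[geneRows])
    }
  }
})
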