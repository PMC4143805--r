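#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom BiocGenerics width
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges findOverlaps reduce
#' @importFrom stats lm model.matrix rbinom rnorm runif setNames coef
#' @importFrom utils write.table read.table
#' @useDynLib PeRC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sample-by-SNP allele dosage matrix
#'
#' Holds diploid allele dosages (0/1/2, `NA` for missing calls) for `m`
#' samples at `p` biallelic SNPs, together with SNP positions and per-SNP
#' minor allele frequencies. MAF is always computed over non-missing calls
#' and folded into \eqn{[0, 0.5]}.
#'
#' @slot dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   in `[0, 2]` or `NA`.
#' @slot positions `GRanges` of length `p` (width-1 loci) with an `id`
#'   metadata column naming each SNP.
#' @slot maf numeric vector of length `p`, minor allele frequencies.
#'
#' @seealso [readGenotypes()], [computeMaf()]
#' @export
setClass("GenotypeMatrix",
  representation(
    dosages = "matrix",
    positions = "GRanges",
    maf = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  p <- ncol(object@dosages)
  if (length(object@positions) != p)
    msg <- c(msg, "positions length must equal the number of SNP columns")
  if (length(object@maf) != p)
    msg <- c(msg, "maf length must equal the number of SNP columns")
  d <- object@dosages
  if (any(!is.na(d) & (d < 0 | d > 2)))
    msg <- c(msg, "non-missing dosages must lie in [0, 2]")
  if (length(object@maf) && any(object@maf < 0 | object@maf > 0.5 + 1e-12))
    msg <- c(msg, "maf values must lie in [0, 0.5]")
  if (is.null(rownames(object@dosages)))
    msg <- c(msg, "dosages must carry sample IDs as rownames")
  if (length(msg)) msg else TRUE
})

#' Gene-based SNP grouping
#'
#' The result of gene-group construction: merged gene spans (gene-kind
#' groups) plus singleton groups for common SNPs outside any gene. Every
#' SNP belongs to at most one group; outside-gene SNPs at or below the
#' common-MAF floor are dropped.
#'
#' @slot groupRanges `GRanges`, one range per group, with metadata columns
#'   `label` (gene symbol, `":"`-joined for merged spans, or the SNP id for
#'   singletons) and `kind` (`"gene"` or `"singleton"`).
#' @slot members list of integer vectors; SNP column indices belonging to
#'   each group.
#' @slot dropped integer vector of SNP indices excluded from the analysis.
#'
#' @seealso [buildGeneGroups()]
#' @export
setClass("GeneGroupSet",
  representation(
    groupRanges = "GRanges",
    members = "list",
    dropped = "integer"
  )
)

setValidity("GeneGroupSet", function(object) {
  msg <- character()
  if (length(object@groupRanges) != length(object@members))
    msg <- c(msg, "one member vector required per group range")
  idx <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(idx))
    msg <- c(msg, "a SNP may belong to at most one group")
  if (length(intersect(idx, object@dropped)))
    msg <- c(msg, "dropped SNPs may not appear in any group")
  kind <- S4Vectors::mcols(object@groupRanges)$kind
  if (!is.null(kind)) {
    single <- lengths(object@members)[kind == "singleton"]
    if (length(single) && any(single != 1L))
      msg <- c(msg, "singleton groups must contain exactly one SNP")
  }
  if (length(msg)) msg else TRUE
})

#' Expanded penalized-regression design
#'
#' The design matrix handed to the optimizer: per group, one column per
#' common variant (MAF >= tau) plus at most one collapsed rare-variant
#' column rescaled to `[0, 2]`, with the penalty weights attached.
#'
#' Column weights are \eqn{\omega_c = 2\sqrt{MAF_c(1 - MAF_c)}} for common
#' variants and \eqn{r_g = \sqrt{f_r(1 - f_r)}} for collapsed columns,
#' where \eqn{f_r} is the pooled allele frequency of the collapsed locus.
#' Group scales are \eqn{s_g = \sqrt{l_g / \max_g l_g}} with \eqn{l_g} the
#' number of common variants plus one if a collapsed column exists.
#'
#' @slot values numeric matrix, samples in rows, predictors in columns
#'   (missing dosages mean-imputed).
#' @slot columns `data.frame` with one row per column: `label`, `group`
#'   (integer index into `groups`), `kind` (`"common_variant"` or
#'   `"collapsed_rare"`), `weight`, `snp` (source SNP index, `NA` for
#'   collapsed columns).
#' @slot groups `data.frame` with one row per retained group: `label`,
#'   `kind`, `lg`, `sg`, `dmin`, `dmax`, `fr` (the last three `NA` when no
#'   collapsed column exists).
#' @slot tau MAF threshold separating rare from common variants.
#'
#' @seealso [buildDesign()], [collapseRare()]
#' @export
setClass("PercDesign",
  representation(
    values = "matrix",
    columns = "data.frame",
    groups = "data.frame",
    tau = "numeric"
  )
)

setValidity("PercDesign", function(object) {
  msg <- character()
  if (nrow(object@columns) != ncol(object@values))
    msg <- c(msg, "columns table must describe every design column")
  if (nrow(object@columns)) {
    g <- object@columns$group
    if (any(g < 1L | g > nrow(object@groups)))
      msg <- c(msg, "column group indices must point into the groups table")
    coll <- object@columns$kind == "collapsed_rare"
    if (any(coll)) {
      v <- object@values[, coll, drop = FALSE]
      if (any(v < -1e-9 | v > 2 + 1e-9))
        msg <- c(msg, "collapsed columns must take values in [0, 2]")
    }
  }
  if (nrow(object@groups)) {
    sg <- object@groups$sg
    if (any(sg <= 0 | sg > 1 + 1e-12) || abs(max(sg) - 1) > 1e-12)
      msg <- c(msg, "group scales must lie in (0, 1] with max equal to 1")
    if (any(object@groups$lg < 1L))
      msg <- c(msg, "every retained group must contribute at least one column")
  }
  if (length(object@tau) != 1L || object@tau <= 0 || object@tau > 1)
    msg <- c(msg, "tau must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Coefficients of the gene-grouped penalized regression
#'
#' An unpenalized intercept plus one coefficient per design column
#' (common-variant coefficients and collapsed rare-burden coefficients,
#' in design-column order).
#'
#' @slot beta0 numeric(1), the intercept.
#' @slot beta numeric vector aligned with the design columns.
#' @export
setClass("PercCoefficients",
  representation(beta0 = "numeric", beta = "numeric")
)

setValidity("PercCoefficients", function(object) {
  msg <- character()
  if (length(object@beta0) != 1L || !is.finite(object@beta0))
    msg <- c(msg, "beta0 must be a single finite value")
  if (length(object@beta) && any(!is.finite(object@beta)))
    msg <- c(msg, "all coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' Penalty configuration
#'
#' Penalty strengths \eqn{(\lambda_1, \lambda_2, \lambda_3)} for the
#' group-lasso, weighted-L1 and weighted-ridge terms. The default
#' parameterization ties them to a single sparsity scale via
#' \eqn{(\lambda_1,\lambda_2,\lambda_3) = \kappa (1,1,1)}; independent
#' values reproduce the classical special cases (lasso, elastic net,
#' sparse group lasso).
#'
#' @slot lambda1,lambda2,lambda3 non-negative penalty strengths.
#' @slot kappa numeric(1) scale when the tied parameterization is used,
#'   otherwise `NA_real_`.
#' @seealso [penaltyConfig()]
#' @export
setClass("PenaltyConfig",
  representation(
    lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
    kappa = "numeric"
  )
)

setValidity("PenaltyConfig", function(object) {
  lam <- c(object@lambda1, object@lambda2, object@lambda3)
  if (length(lam) != 3L || any(!is.finite(lam)) || any(lam < 0))
    return("lambda1, lambda2, lambda3 must be single non-negative values")
  if (length(object@kappa) != 1L)
    return("kappa must be a single value (NA when lambdas are independent)")
  if (!is.na(object@kappa) && object@kappa < 0)
    return("kappa must be non-negative")
  TRUE
})

#' A converged fit at one penalty strength
#'
#' @slot config the `PenaltyConfig` used.
#' @slot coef `PercCoefficients` at convergence.
#' @slot objective final objective value (recomputed from the coefficients,
#'   not the incrementally tracked value).
#' @slot nCycles number of full coordinate cycles executed.
#' @slot status `"converged"`, `"max_cycles"` or `"stalled"`.
#' @slot activeSet integer indices of design columns with nonzero
#'   coefficients.
#' @slot selectedGroups integer indices (into the design's groups table) of
#'   groups with any nonzero coefficient.
#' @slot trace numeric vector of objective values, one per cycle (empty
#'   unless tracing was requested).
#' @seealso [percFit()]
#' @export
setClass("PercFit",
  representation(
    config = "PenaltyConfig",
    coef = "PercCoefficients",
    objective = "numeric",
    nCycles = "integer",
    status = "character",
    activeSet = "integer",
    selectedGroups = "integer",
    trace = "numeric"
  )
)

#' A sequence of fits along a descending kappa grid
#'
#' @slot kappas descending grid of penalty scales.
#' @slot fits list of `PercFit`, one per kappa, warm-started in order.
#' @seealso [percFitPath()]
#' @export
setClass("PercPath",
  representation(kappas = "numeric", fits = "list")
)

setValidity("PercPath", function(object) {
  if (length(object@kappas) != length(object@fits))
    return("one fit required per kappa")
  if (is.unsorted(rev(object@kappas), strictly = FALSE))
    return("kappas must be sorted in descending order")
  TRUE
})

#' Per-individual quantitative trait
#'
#' One trait value per individual, typically the mean residual after
#' regressing repeated measurements on covariates.
#'
#' @slot sampleIds character vector of individual IDs.
#' @slot trait numeric vector aligned with `sampleIds`, in the original
#'   trait's units.
#' @seealso [residualize()]
#' @export
setClass("PhenotypeVector",
  representation(sampleIds = "character", trait = "numeric")
)

setValidity("PhenotypeVector", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@trait))
    msg <- c(msg, "one trait value required per sample ID")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample IDs must be unique")
  if (length(object@trait) && any(!is.finite(object@trait)))
    msg <- c(msg, "trait values must be finite")
  if (length(msg)) msg else TRUE
})
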