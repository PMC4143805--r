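#' Split a group's SNPs into rare and common by MAF threshold
#'
#' Rare variants are those with MAF strictly below `tau`; a SNP whose MAF
#' equals `tau` is common.
#'
#' @param mafs numeric vector of minor allele frequencies.
#' @param tau MAF threshold in `(0, 1]`.
#' @return list with integer index vectors `rare` and `common` (either may
#'   be empty).
#' @export
splitRareCommon <- function(mafs, tau) {
  stopifnot(length(tau) == 1L, tau > 0, tau <= 1)
  list(rare = which(mafs < tau), common = which(mafs >= tau))
}

#' Collapse a group's rare variants into one rescaled burden column
#'
#' The raw burden for individual `i` is the total rare-allele count
#' \eqn{b_i = \sum_{r} x_{ir}} over the group's rare SNPs. The collapsed
#' column rescales the burden to the dosage range:
#' \deqn{2 (b_i - d_{min}) / (d_{max} - d_{min})}
#' where \eqn{d_{min}} and \eqn{d_{max}} are the minimum and maximum
#' burden any individual carries. The collapsed-locus frequency is the
#' pooled minor allele frequency of the rare SNPs,
#' \eqn{f_r = \min(f, 1-f)} with \eqn{f = \sum_i b_i / (2 m k)} for `k`
#' rare SNPs, and feeds the penalty weight \eqn{r_g = \sqrt{f_r(1-f_r)}}.
#'
#' @param rareDosages numeric matrix, samples in rows, the group's rare
#'   SNPs in columns (no missing values; impute first).
#' @return list with `column` (numeric in `[0, 2]`), `dmin`, `dmax`, `fr`;
#'   or `NULL` (with a warning) when every individual carries the same
#'   burden, in which case the group keeps only its common variants.
#' @examples
#' x <- matrix(c(0,1,2,4, 0,0,0,0), ncol = 2)  # burdens 0,1,2,4
#' collapseRare(x)$column   # 0, 0.5, 1, 2
#' @export
collapseRare <- function(rareDosages) {
  rareDosages <- as.matrix(rareDosages)
  stopifnot(ncol(rareDosages) >= 1L, !anyNA(rareDosages))
  b <- rowSums(rareDosages)
  dmin <- min(b); dmax <- max(b)
  if (dmax == dmin) {
    warning("no burden variation across individuals; ",
            "collapsed rare column dropped")
    return(NULL)
  }
  f <- sum(b) / (2 * nrow(rareDosages) * ncol(rareDosages))
  list(column = 2 * (b - dmin) / (dmax - dmin),
       dmin = dmin, dmax = dmax, fr = min(f, 1 - f))
}

## Mean-impute missing dosages per SNP column.
.imputeDosages <- function(d) {
  miss <- which(colSums(is.na(d)) > 0L)
  for (j in miss) {
    v <- d[, j]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    d[, j] <- v
  }
  d
}

#' Build the expanded penalized-regression design
#'
#' For every group: one column per common variant (MAF >= `tau`, ordered
#' by position) followed by at most one collapsed rare-variant column
#' (see [collapseRare()]). Missing dosages are mean-imputed per SNP.
#' Penalty weights are attached per column
#' (\eqn{\omega_c = 2\sqrt{MAF_c(1-MAF_c)}} for common variants,
#' \eqn{r_g = \sqrt{f_r(1-f_r)}} for collapsed columns) and per group
#' (\eqn{s_g = \sqrt{l_g/\max_g l_g}}). Groups left with no columns —
#' e.g. only monomorphic rare SNPs — are dropped.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param groups a [GeneGroupSet-class] over the same SNPs.
#' @param tau MAF threshold separating rare from common (default 0.005).
#' @return a [PercDesign-class].
#' @export
buildDesign <- function(genotypes, groups, tau = 0.005) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(groups, "GeneGroupSet"))
  if (nGroups(groups) == 0L) stop("empty group set")
  d <- .imputeDosages(dosages(genotypes))
  maf <- mafs(genotypes)
  pos <- GenomicRanges::start(snpPositions(genotypes))
  ids <- S4Vectors::mcols(snpPositions(genotypes))$id
  gLabels <- S4Vectors::mcols(groupRanges(groups))$label
  gKind <- S4Vectors::mcols(groupRanges(groups))$kind
  memb <- groupMembers(groups)

  cols <- list(); colTab <- list(); grpTab <- list()
  gi <- 0L
  for (g in seq_along(memb)) {
    snps <- memb[[g]]
    if (!length(snps)) next
    sp <- splitRareCommon(maf[snps], tau)
    common <- snps[sp$common]
    common <- common[order(pos[common])]
    rare <- snps[sp$rare]

    gCols <- list(); gColTab <- list()
    for (j in common) {
      gCols[[length(gCols) + 1L]] <- d[, j]
      gColTab[[length(gColTab) + 1L]] <- data.frame(
        label = ids[j], kind = "common_variant",
        weight = 2 * sqrt(maf[j] * (1 - maf[j])), snp = j,
        stringsAsFactors = FALSE)
    }
    dmin <- NA_real_; dmax <- NA_real_; fr <- NA_real_
    hasCollapsed <- FALSE
    if (length(rare)) {
      cl <- collapseRare(d[, rare, drop = FALSE])
      if (!is.null(cl)) {
        hasCollapsed <- TRUE
        dmin <- cl$dmin; dmax <- cl$dmax; fr <- cl$fr
        gCols[[length(gCols) + 1L]] <- cl$column
        gColTab[[length(gColTab) + 1L]] <- data.frame(
          label = paste0(gLabels[g], "_RVburden"), kind = "collapsed_rare",
          weight = sqrt(fr * (1 - fr)), snp = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(gCols)) next
    gi <- gi + 1L
    ct <- do.call(rbind, gColTab)
    ct$group <- gi
    colTab[[gi]] <- ct
    cols[[gi]] <- do.call(cbind, gCols)
    grpTab[[gi]] <- data.frame(
      label = gLabels[g], kind = gKind[g],
      lg = sum(ct$kind == "common_variant") + as.integer(hasCollapsed),
      dmin = dmin, dmax = dmax, fr = fr, stringsAsFactors = FALSE)
  }
  if (gi == 0L) stop("no group contributed any design column")

  values <- do.call(cbind, cols)
  columns <- do.call(rbind, colTab)
  groupsDf <- do.call(rbind, grpTab)
  groupsDf$sg <- sqrt(groupsDf$lg / max(groupsDf$lg))
  rownames(columns) <- NULL; rownames(groupsDf) <- NULL
  colnames(values) <- columns$label
  rownames(values) <- sampleIds(genotypes)
  columns <- columns[, c("label", "group", "kind", "weight", "snp")]

  new("PercDesign", values = values, columns = columns,
      groups = groupsDf[, c("label", "kind", "lg", "sg",
                            "dmin", "dmax", "fr")],
      tau = tau)
}
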