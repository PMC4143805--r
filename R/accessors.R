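#' @rdname GenotypeMatrix-class
#' @param object,x a `GenotypeMatrix`.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname PhenotypeVector-class
#' @export
setMethod("sampleIds", "PhenotypeVector", function(x) x@sampleIds)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpPositions", "GenotypeMatrix", function(x) x@positions)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("mafs", "GenotypeMatrix", function(x) x@maf)

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosages))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSnps", "GenotypeMatrix", function(x) ncol(x@dosages))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "SNPs\n")
  if (length(object@maf))
    cat("  MAF range:", format(range(object@maf), digits = 3), "\n")
  nmiss <- sum(is.na(object@dosages))
  if (nmiss) cat("  missing calls:", nmiss, "\n")
})

#' @rdname GeneGroupSet-class
#' @param object,x a `GeneGroupSet`.
#' @export
setGeneric("groupRanges", function(x) standardGeneric("groupRanges"))

#' @rdname GeneGroupSet-class
#' @export
setMethod("groupRanges", "GeneGroupSet", function(x) x@groupRanges)

#' @rdname GeneGroupSet-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname GeneGroupSet-class
#' @export
setMethod("groupMembers", "GeneGroupSet", function(x) x@members)

#' @rdname GeneGroupSet-class
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))

#' @rdname GeneGroupSet-class
#' @export
setMethod("droppedSnps", "GeneGroupSet", function(x) x@dropped)

#' @rdname GeneGroupSet-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname GeneGroupSet-class
#' @export
setMethod("nGroups", "GeneGroupSet", function(x) length(x@groupRanges))

setMethod("show", "GeneGroupSet", function(object) {
  kind <- S4Vectors::mcols(object@groupRanges)$kind
  cat("GeneGroupSet:", length(object@groupRanges), "groups (",
      sum(kind == "gene"), "gene,", sum(kind == "singleton"),
      "singleton )\n")
  cat("  SNPs grouped:", sum(lengths(object@members)),
      " dropped:", length(object@dropped), "\n")
})

#' @rdname PercDesign-class
#' @param object,x a `PercDesign`.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname PercDesign-class
#' @export
setMethod("designMatrix", "PercDesign", function(x) x@values)

#' @rdname PercDesign-class
#' @export
setGeneric("columnInfo", function(x) standardGeneric("columnInfo"))

#' @rdname PercDesign-class
#' @export
setMethod("columnInfo", "PercDesign", function(x) x@columns)

#' @rdname PercDesign-class
#' @export
setGeneric("groupInfo", function(x) standardGeneric("groupInfo"))

#' @rdname PercDesign-class
#' @export
setMethod("groupInfo", "PercDesign", function(x) x@groups)

#' @rdname PercDesign-class
#' @export
setGeneric("nPredictors", function(x) standardGeneric("nPredictors"))

#' @rdname PercDesign-class
#' @export
setMethod("nPredictors", "PercDesign", function(x) ncol(x@values))

setMethod("show", "PercDesign", function(object) {
  cat("PercDesign:", nrow(object@values), "samples x",
      ncol(object@values), "predictors in", nrow(object@groups),
      "groups (tau =", object@tau, ")\n")
  cat("  collapsed rare columns:",
      sum(object@columns$kind == "collapsed_rare"), "\n")
})

#' @rdname PhenotypeVector-class
#' @param object,x a `PhenotypeVector`.
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))

#' @rdname PhenotypeVector-class
#' @export
setMethod("trait", "PhenotypeVector", function(x) {
  setNames(x@trait, x@sampleIds)
})

setMethod("show", "PhenotypeVector", function(object) {
  cat("PhenotypeVector:", length(object@trait), "individuals, mean",
      format(mean(object@trait), digits = 4), ", sd",
      format(stats::sd(object@trait), digits = 4), "\n")
})

#' @rdname PercFit-class
#' @param object,x a `PercFit`.
#' @export
setGeneric("activeSet", function(x) standardGeneric("activeSet"))

#' @rdname PercFit-class
#' @export
setMethod("activeSet", "PercFit", function(x) x@activeSet)

#' @rdname PercFit-class
#' @export
setGeneric("selectedGroups", function(x) standardGeneric("selectedGroups"))

#' @rdname PercFit-class
#' @export
setMethod("selectedGroups", "PercFit", function(x) x@selectedGroups)

#' @rdname PercFit-class
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname PercFit-class
#' @export
setMethod("objectiveValue", "PercFit", function(x) x@objective)

#' @rdname PercFit-class
#' @export
setGeneric("modelSize", function(x) standardGeneric("modelSize"))

#' @rdname PercFit-class
#' @export
setMethod("modelSize", "PercFit", function(x) length(x@activeSet))

#' @rdname PercFit-class
#' @export
setMethod("coef", "PercFit", function(object) {
  c(`(Intercept)` = object@coef@beta0, object@coef@beta)
})

setMethod("show", "PercFit", function(object) {
  kap <- object@config@kappa
  lab <- if (is.na(kap)) {
    sprintf("lambda = (%g, %g, %g)", object@config@lambda1,
            object@config@lambda2, object@config@lambda3)
  } else sprintf("kappa = %g", kap)
  cat("PercFit (", lab, "): ", length(object@activeSet),
      " active predictors in ", length(object@selectedGroups),
      " groups\n", sep = "")
  cat("  objective ", format(object@objective, digits = 8), ", ",
      object@nCycles, " cycles, ", object@status, "\n", sep = "")
})

#' @rdname PercPath-class
#' @param object,x a `PercPath`.
#' @export
setGeneric("pathKappas", function(x) standardGeneric("pathKappas"))

#' @rdname PercPath-class
#' @export
setMethod("pathKappas", "PercPath", function(x) x@kappas)

#' @rdname PercPath-class
#' @export
setGeneric("pathFits", function(x) standardGeneric("pathFits"))

#' @rdname PercPath-class
#' @export
setMethod("pathFits", "PercPath", function(x) x@fits)

#' @rdname PercPath-class
#' @export
setGeneric("modelSizes", function(x) standardGeneric("modelSizes"))

#' @rdname PercPath-class
#' @export
setMethod("modelSizes", "PercPath", function(x) {
  vapply(x@fits, function(f) length(f@activeSet), integer(1))
})

setMethod("show", "PercPath", function(object) {
  cat("PercPath:", length(object@kappas), "kappa values from",
      format(max(object@kappas), digits = 4), "to",
      format(min(object@kappas), digits = 4), "\n")
  cat("  model sizes:", paste(modelSizes(object), collapse = " "), "\n")
})

#' Extract a fit from a path
#' @param x a `PercPath`.
#' @param i fit index (1 = largest kappa).
#' @export
setMethod("[[", "PercPath", function(x, i) x@fits[[i]])

#' Number of fits in a path
#' @param x a `PercPath`.
#' @export
setMethod("length", "PercPath", function(x) length(x@fits))
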