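#' Convergence settings for the coordinate-ascent optimizer
#'
#' @param tol relative objective change per full cycle below which the fit
#'   is declared converged (default 1e-8).
#' @param maxCycles maximum number of full coordinate cycles (default
#'   1000).
#' @param maxHalvings maximum number of step halvings per coordinate
#'   update before the coordinate is left unchanged for the cycle
#'   (default 30).
#' @param traceLevel 0 = none, 1 = record the objective after every full
#'   cycle, 2 = after every coordinate update.
#' @return list of validated settings.
#' @export
percControl <- function(tol = 1e-8, maxCycles = 1000L, maxHalvings = 30L,
                        traceLevel = 0L) {
  stopifnot(tol > 0, maxCycles >= 1L, maxHalvings >= 0L,
            traceLevel %in% 0:2)
  list(tol = tol, maxCycles = as.integer(maxCycles),
       maxHalvings = as.integer(maxHalvings),
       traceLevel = as.integer(traceLevel))
}

.checkY <- function(y, design) {
  if (is(y, "PhenotypeVector")) {
    ids <- rownames(designMatrix(design))
    if (!is.null(ids)) {
      missing <- setdiff(ids, sampleIds(y))
      if (length(missing))
        stop("phenotype is missing sample(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
      y <- trait(y)[ids]
    } else y <- y@trait
  }
  y <- as.numeric(y)
  if (length(y) != nrow(designMatrix(design)))
    stop("y length does not match the design's sample count")
  if (anyNA(y)) stop("y contains missing values")
  y
}

.asFit <- function(res, config, design) {
  coefs <- new("PercCoefficients", beta0 = res$beta0, beta = res$beta)
  active <- which(res$beta != 0)
  new("PercFit",
      config = config,
      coef = coefs,
      objective = res$objective,
      nCycles = as.integer(res$nCycles),
      status = res$status,
      activeSet = as.integer(active),
      selectedGroups = as.integer(
        sort(unique(columnInfo(design)$group[active]))),
      trace = as.numeric(res$cycleTrace))
}

#' Fit the gene-grouped penalized regression at one penalty strength
#'
#' Maximizes \eqn{O = -\tfrac12 \mathrm{RSS} - f} by cyclic coordinate
#' ascent: the intercept first, then every design column in order, each
#' taking a Newton (CLG) step \eqn{-O'/O''} that is halved until the
#' objective improves and clamped at zero if it would cross sign. The
#' objective never decreases across accepted updates; the fit stops when
#' the relative objective change over a full cycle drops below
#' `control$tol`.
#'
#' @param y numeric trait vector, or a [PhenotypeVector-class] matched to
#'   the design's sample IDs.
#' @param design a [PercDesign-class].
#' @param config a [PenaltyConfig-class] (or a single kappa value).
#' @param control see [percControl()].
#' @param init optional [PercCoefficients-class] warm start; defaults to
#'   all zeros with the intercept at `mean(y)`.
#' @return a [PercFit-class].
#' @examples
#' set.seed(1)
#' sim <- simulatePercData(percSimConfig(nIndividuals = 80, nGenes = 4,
#'                                       snpsPerGene = 6, seed = 1))
#' des <- buildDesign(sim$genotypes, sim$groups)
#' fit <- percFit(sim$phenotype, des, penaltyConfig(kappa = 1))
#' modelSize(fit)
#' @export
percFit <- function(y, design, config, control = percControl(),
                    init = NULL) {
  if (is.numeric(config) && length(config) == 1L)
    config <- penaltyConfig(kappa = config)
  stopifnot(is(design, "PercDesign"), is(config, "PenaltyConfig"))
  y <- .checkY(y, design)
  if (is.null(init)) init <- percCoefficients(beta0 = mean(y),
                                              design = design)
  stopifnot(length(init@beta) == nPredictors(design))
  res <- .perc_fit_cpp(
    designMatrix(design), y,
    as.integer(columnInfo(design)$group),
    columnInfo(design)$weight,
    groupInfo(design)$sg,
    config@lambda1, config@lambda2, config@lambda3,
    init@beta0, init@beta,
    control$tol, control$maxCycles, control$maxHalvings,
    control$traceLevel)
  .asFit(res, config, design)
}

#' Single CLG coordinate update
#'
#' Applies one safeguarded Newton update to coordinate `j` (0 = the
#' intercept) from the given state and reports whether the move was
#' accepted. Exposed mainly for inspection and testing; [percFit()] runs
#' the same update in its inner loop.
#'
#' @inheritParams percFit
#' @param j coordinate index, 0 for the intercept.
#' @param coefs current [PercCoefficients-class].
#' @return list with the updated `coefs`, the objective gain
#'   `deltaObjective` (>= 0) and logical `moved`.
#' @export
updateCoordinate <- function(j, y, design, coefs, config,
                             control = percControl()) {
  if (is.numeric(config) && length(config) == 1L)
    config <- penaltyConfig(kappa = config)
  y <- .checkY(y, design)
  res <- .perc_update_coordinate_cpp(
    as.integer(j), designMatrix(design), y,
    as.integer(columnInfo(design)$group),
    columnInfo(design)$weight,
    groupInfo(design)$sg,
    config@lambda1, config@lambda2, config@lambda3,
    coefs@beta0, coefs@beta, control$maxHalvings)
  list(coefs = new("PercCoefficients", beta0 = res$beta0,
                   beta = res$beta),
       deltaObjective = res$deltaObjective,
       moved = res$moved)
}

#' Smallest kappa at which the model is empty
#'
#' Under the tied parameterization
#' \eqn{(\lambda_1,\lambda_2,\lambda_3) = \kappa(1,1,1)}, the all-zero
#' coefficient vector (with the intercept at `mean(y)`) is stationary for
#' every coordinate exactly when
#' \eqn{|x_j^\top (y - \bar y)| \le \kappa\, (s_{g(j)} + w_j)} for all
#' `j`: at zero, the group-norm and L1 terms each contribute their full
#' one-sided slope and the ridge term none. The returned value is the
#' largest left-hand side over columns divided by its
#' \eqn{s_{g(j)} + w_j}.
#'
#' @inheritParams percFit
#' @return scalar; for `kappa >=` this value, [percFit()] from a zero
#'   start returns the empty model.
#' @export
kappaMax <- function(y, design) {
  y <- .checkY(y, design)
  X <- designMatrix(design)
  z <- abs(drop(crossprod(X, y - mean(y))))
  denom <- groupInfo(design)$sg[columnInfo(design)$group] +
    columnInfo(design)$weight
  max(z / denom)
}

#' Fit a descending-kappa regularization path
#'
#' Fits one model per kappa, largest first, warm-starting each fit at the
#' previous solution. Larger kappa gives sparser models; model size
#' typically grows as kappa decreases.
#'
#' @inheritParams percFit
#' @param kappas positive penalty scales, sorted descending. Defaults to
#'   `nKappas` log-spaced values from [kappaMax()] down to
#'   `minFraction * kappaMax()`.
#' @param nKappas,minFraction default-grid settings used when `kappas` is
#'   `NULL`.
#' @param maxGroups stop the path early once this many distinct groups
#'   have carried a nonzero coefficient (like `dfmax` in glmnet);
#'   `Inf` fits the whole grid.
#' @return a [PercPath-class] (truncated at the early stop, if any).
#' @export
percFitPath <- function(y, design, kappas = NULL, control = percControl(),
                        nKappas = 20L, minFraction = 0.01,
                        maxGroups = Inf) {
  yv <- .checkY(y, design)
  if (is.null(kappas)) {
    km <- kappaMax(yv, design)
    kappas <- exp(seq(log(km), log(minFraction * km),
                      length.out = nKappas))
  }
  if (!length(kappas)) stop("empty kappa grid")
  if (any(kappas <= 0)) stop("kappa values must be positive")
  if (is.unsorted(rev(kappas), strictly = FALSE))
    stop("kappa grid must be sorted in descending order")
  fits <- vector("list", length(kappas))
  init <- NULL
  entered <- integer()
  nFit <- 0L
  for (k in seq_along(kappas)) {
    fits[[k]] <- percFit(yv, design, penaltyConfig(kappa = kappas[k]),
                         control = control, init = init)
    init <- fits[[k]]@coef
    nFit <- k
    entered <- union(entered, selectedGroups(fits[[k]]))
    if (length(entered) >= maxGroups) break
  }
  new("PercPath", kappas = as.numeric(kappas[seq_len(nFit)]),
      fits = fits[seq_len(nFit)])
}

#' Order in which groups enter a regularization path
#'
#' Scans the fits from the largest kappa down and records each group the
#' first time it carries a nonzero coefficient.
#'
#' @param path a [PercPath-class].
#' @param design the [PercDesign-class] the path was fit on; when given,
#'   groups entering at the same kappa are ordered by their largest
#'   coefficient magnitude at that kappa, otherwise by group index.
#' @return integer vector of group indices in order of first appearance.
#' @export
groupEntryOrder <- function(path, design = NULL) {
  colGroup <- if (!is.null(design)) columnInfo(design)$group else NULL
  seen <- integer()
  for (f in pathFits(path)) {
    newG <- setdiff(selectedGroups(f), seen)
    if (length(newG) > 1L && !is.null(colGroup)) {
      mag <- vapply(newG, function(g)
        max(abs(f@coef@beta[colGroup == g])), numeric(1))
      newG <- newG[order(-mag)]
    }
    seen <- c(seen, newG)
  }
  seen
}
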