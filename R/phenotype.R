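#' Covariate residualization of repeated trait measurements
#'
#' Regresses the trait on covariates by ordinary least squares, treating
#' every time point of every individual as a separate observation, then
#' averages the residuals within individual. The per-individual mean
#' residual becomes the quantitative trait for association analysis. The
#' default covariate set is intercept, age, age squared, sex, smoking
#' status and medication use; pass `covariates` to adapt it to other
#' traits (age is always accompanied by its square when present).
#'
#' Records with a missing trait or covariate value are dropped
#' (complete-case); individuals left with no usable records are omitted
#' with a warning.
#'
#' @param records `data.frame` in long format: one row per individual per
#'   time point.
#' @param idCol name of the individual-ID column.
#' @param traitCol name of the trait column.
#' @param covariates character vector of covariate column names; numeric
#'   or 0/1 coded.
#' @param squared covariate names to also enter as squared terms (default
#'   `"age"` when present).
#' @return a [PhenotypeVector-class], ordered by sample ID.
#' @examples
#' rec <- data.frame(id = rep(c("a", "b"), each = 2),
#'                   dbp = c(80, 82, 95, 93),
#'                   age = c(40, 42, 60, 62),
#'                   sex = c(0, 0, 1, 1),
#'                   smoke = 0, meds = c(0, 0, 1, 1))
#' residualize(rec, traitCol = "dbp")
#' @export
residualize <- function(records, idCol = "id", traitCol = "trait",
                        covariates = intersect(
                          c("age", "sex", "smoke", "smoking",
                            "medication", "meds"), names(records)),
                        squared = intersect("age", covariates)) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  for (col in c(idCol, traitCol, covariates))
    if (!col %in% names(records))
      stop("column '", col, "' not found in the phenotype table")

  used <- records[, c(idCol, traitCol, covariates), drop = FALSE]
  ok <- stats::complete.cases(used)
  lost <- unique(records[[idCol]][!ok])
  used <- used[ok, , drop = FALSE]
  gone <- setdiff(lost, used[[idCol]])
  if (length(gone))
    warning("individual(s) with no usable records omitted: ",
            paste(utils::head(gone, 5L), collapse = ", "))
  if (nrow(used) < 2L) stop("fewer than 2 usable records")

  terms <- covariates
  for (sq in squared)
    terms <- c(terms, sprintf("I(%s^2)", sq))
  fml <- stats::as.formula(paste(
    traitCol, "~",
    if (length(terms)) paste(terms, collapse = " + ") else "1"))
  fit <- stats::lm(fml, data = used)
  bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(bad))
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))

  res <- stats::residuals(fit)
  means <- tapply(res, used[[idCol]], mean)
  ids <- sort(names(means))
  new("PhenotypeVector", sampleIds = ids,
      trait = as.numeric(means[ids]))
}

#' Read a long-format phenotype table
#'
#' Delimited text (tab or comma auto-detected), header required.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
readPhenotypeTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
}
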