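#' Create a penalty configuration
#'
#' Either supply a single sparsity scale `kappa`, in which case
#' \eqn{(\lambda_1,\lambda_2,\lambda_3) = \kappa (1,1,1)}, or the three
#' strengths independently. Special cases: `lambda1 = 0` gives the
#' weighted elastic net; `lambda3 = 0` (with all SNPs treated as rare,
#' `tau = 1`) gives a sparse group lasso.
#'
#' @param kappa single non-negative sparsity scale (ignored when any
#'   lambda is given).
#' @param lambda1 group-lasso strength.
#' @param lambda2 weighted-L1 strength.
#' @param lambda3 weighted-ridge strength.
#' @return a [PenaltyConfig-class].
#' @examples
#' penaltyConfig(kappa = 2)           # lambdas (2, 2, 2)
#' penaltyConfig(lambda2 = 1, lambda3 = 0.5)  # elastic net
#' @export
penaltyConfig <- function(kappa = NULL, lambda1 = NULL, lambda2 = NULL,
                          lambda3 = NULL) {
  anyLambda <- !is.null(lambda1) || !is.null(lambda2) || !is.null(lambda3)
  if (anyLambda) {
    lam <- c(lambda1 %||% 0, lambda2 %||% 0, lambda3 %||% 0)
    if (any(lam < 0)) stop("penalty strengths must be non-negative")
    new("PenaltyConfig", lambda1 = lam[1], lambda2 = lam[2],
        lambda3 = lam[3], kappa = NA_real_)
  } else {
    if (is.null(kappa)) stop("supply kappa or at least one lambda")
    if (kappa < 0) stop("kappa must be non-negative")
    new("PenaltyConfig", lambda1 = kappa, lambda2 = kappa,
        lambda3 = kappa, kappa = as.numeric(kappa))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a coefficient vector
#'
#' @param beta0 intercept.
#' @param beta per-column coefficients (length `nPredictors(design)`).
#' @param design optional [PercDesign-class]; when given, `beta` defaults
#'   to all zeros of the right length and lengths are checked.
#' @return a [PercCoefficients-class].
#' @export
percCoefficients <- function(beta0 = 0, beta = NULL, design = NULL) {
  if (is.null(beta)) {
    if (is.null(design)) stop("supply beta or a design")
    beta <- numeric(nPredictors(design))
  }
  if (!is.null(design) && length(beta) != nPredictors(design))
    stop("beta length ", length(beta), " does not match the design's ",
         nPredictors(design), " columns")
  new("PercCoefficients", beta0 = as.numeric(beta0),
      beta = as.numeric(beta))
}

#' Linear predictor of the gene-grouped model
#'
#' \deqn{\eta_i = \beta_0 + \sum_g \big( \sum_{c \in g_c} x_{ic}\beta_c
#'   + \gamma_g z_{ig} \big)}
#' where \eqn{z_{ig}} is the group's rescaled collapsed rare-variant
#' column; in matrix form, the intercept plus the design times the
#' coefficient vector.
#'
#' @param design a [PercDesign-class].
#' @param coefs a [PercCoefficients-class].
#' @return numeric vector of fitted trait values, one per sample.
#' @export
linearPredictor <- function(design, coefs) {
  X <- designMatrix(design)
  if (length(coefs@beta) != ncol(X))
    stop("coefficient length ", length(coefs@beta),
         " does not match design columns ", ncol(X))
  drop(coefs@beta0 + X %*% coefs@beta)
}

#' Residual sum of squares
#'
#' @param y observed trait values.
#' @param eta fitted values from [linearPredictor()].
#' @return \eqn{\sum_i (y_i - \eta_i)^2}.
#' @export
percRss <- function(y, eta) {
  if (length(y) != length(eta))
    stop("y and eta lengths differ")
  sum((y - eta)^2)
}

#' Combined group-lasso / elastic-net penalty
#'
#' \deqn{f = \sum_g \Big[ \lambda_1 s_g \big(\textstyle\sum_{c\in g_c}
#'   \beta_c^2 + \gamma_g^2\big)^{1/2}
#'   + \lambda_2 \big(\textstyle\sum_{c\in g_c} \omega_c|\beta_c| +
#'     r_g|\gamma_g|\big)
#'   + \lambda_3 \big(\textstyle\sum_{c\in g_c} \omega_c\beta_c^2 +
#'     r_g\gamma_g^2\big) \Big]}
#' The intercept is never penalized. The first term selects whole groups;
#' the second and third act as a weighted elastic net within groups.
#'
#' @param coefs a [PercCoefficients-class].
#' @param design a [PercDesign-class] carrying the weights.
#' @param config a [PenaltyConfig-class].
#' @return non-negative scalar, zero iff all penalized coefficients are 0.
#' @export
percPenalty <- function(coefs, design, config) {
  b <- coefs@beta
  w <- columnInfo(design)$weight
  grp <- columnInfo(design)$group
  sg <- groupInfo(design)$sg
  gss <- vapply(seq_len(nrow(groupInfo(design))), function(g)
    sum(b[grp == g]^2), numeric(1))
  config@lambda1 * sum(sg * sqrt(gss)) +
    config@lambda2 * sum(w * abs(b)) +
    config@lambda3 * sum(w * b^2)
}

#' Penalized objective
#'
#' The quantity maximized by the optimizer:
#' \deqn{O = -\tfrac12 \mathrm{RSS} - f}
#' Always non-positive; equal to \eqn{-\tfrac12\mathrm{RSS}} when all
#' penalty strengths are zero.
#'
#' @inheritParams percPenalty
#' @param y observed trait values.
#' @return scalar objective value.
#' @export
percObjective <- function(y, design, coefs, config) {
  -0.5 * percRss(y, linearPredictor(design, coefs)) -
    percPenalty(coefs, design, config)
}

#' Coordinate-wise derivatives of the objective
#'
#' First and second derivatives of the objective with respect to one
#' coordinate, as used by the safeguarded Newton (CLG) update
#' \eqn{\beta_j \leftarrow \beta_j - O'/O''}. At points where the penalty
#' is not differentiable (a coefficient at zero, or an all-zero group for
#' the group-norm term) the one-sided derivative in `direction` is
#' returned; no smoothing is applied, so exact zeros stay exact.
#'
#' `j = 0` addresses the unpenalized intercept. The second derivative is
#' the true (signed) curvature of the objective and is negative whenever
#' the column varies.
#'
#' @param j coordinate index: 0 for the intercept, otherwise a design
#'   column index.
#' @param y observed trait values.
#' @param design a [PercDesign-class].
#' @param coefs a [PercCoefficients-class].
#' @param config a [PenaltyConfig-class].
#' @param direction +1 or -1; the direction used for one-sided terms when
#'   the coordinate sits at zero.
#' @return list with `d1` (first derivative of O, one-sided where needed)
#'   and `d2` (second derivative of O).
#' @export
percCoordDerivs <- function(j, y, design, coefs, config, direction = 1) {
  X <- designMatrix(design)
  r <- y - linearPredictor(design, coefs)
  if (j == 0L)
    return(list(d1 = sum(r), d2 = -length(y)))
  stopifnot(j >= 1L, j <= ncol(X))
  x <- X[, j]
  a <- sum(x^2)
  if (a == 0) stop("zero-variance design column ", j,
                   " (should have been dropped)")
  info <- columnInfo(design)
  w <- info$weight[j]
  g <- info$group[j]
  sg <- groupInfo(design)$sg[g]
  bj <- coefs@beta[j]
  bg <- coefs@beta[info$group == g]
  gnorm <- sqrt(sum(bg^2))

  smooth1 <- sum(r * x)
  sgn <- if (bj != 0) sign(bj) else sign(direction)
  d1 <- smooth1 - config@lambda2 * w * sgn - 2 * config@lambda3 * w * bj
  d2 <- -a - 2 * config@lambda3 * w
  if (gnorm > 0) {
    d1 <- d1 - config@lambda1 * sg * bj / gnorm
    d2 <- d2 - config@lambda1 * sg * (gnorm^2 - bj^2) / gnorm^3
  } else {
    # all-zero group: norm is |beta_j| along this axis, slope sg one-sided
    d1 <- d1 - config@lambda1 * sg * sgn
  }
  list(d1 = d1, d2 = d2)
}
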