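test_that("one unpenalized update lands on the OLS coefficient", {
  set.seed(31)
  x <- rnorm(25)
  des <- toyDesign(matrix(x, ncol = 1), group = 1)
  y <- 0.7 * x + rnorm(25, 0, 0.1)
  co <- percCoefficients(0, beta = 0)
  up <- updateCoordinate(1, y, des, co, penaltyConfig(kappa = 0))
  expect_true(up$moved)
  expect_equal(up$coefs@beta, sum(x * y) / sum(x^2))   # Newton exact
})

test_that("a coefficient pinned at zero by L1 stays exactly zero", {
  set.seed(32)
  x <- rnorm(25)
  y <- 0.1 * x + rnorm(25, 0, 0.1)
  des <- toyDesign(matrix(x, ncol = 1), group = 1)
  w <- columnInfo(des)$weight
  lam <- (abs(sum(x * y)) / w) * 1.5   # exceeds the subgradient bound
  co <- percCoefficients(0, beta = 0)
  up <- updateCoordinate(1, y, des, co,
                         penaltyConfig(lambda2 = lam))
  expect_false(up$moved)
  expect_identical(up$coefs@beta, 0)
})

test_that("single-column L1 fit matches the soft-threshold closed form", {
  set.seed(33)
  x <- scale(rnorm(50))[, 1]           # centered, unit scale
  y <- scale(0.6 * x + rnorm(50))[, 1]
  des <- toyDesign(matrix(x, ncol = 1), group = 1)
  w <- columnInfo(des)$weight
  rho <- sum(x * y)
  for (l2 in c(0.1, 0.5, 2, abs(rho) / w * 1.1)) {
    cfg <- penaltyConfig(lambda1 = 0, lambda2 = l2, lambda3 = 0)
    fit <- percFit(y, des, cfg, percControl(tol = 1e-14))
    closed <- sign(rho) * max(abs(rho) - l2 * w, 0) / sum(x^2)
    expect_equal(fit@coef@beta, closed, tolerance = 1e-8)
  }
})

test_that("kappa = 0 reproduces ordinary least squares", {
  set.seed(34)
  for (rep in 1:5) {
    inst <- randomInstance(400 + rep)
    des <- inst$design; y <- inst$y
    X1 <- cbind(1, designMatrix(des))
    ols <- solve(crossprod(X1), crossprod(X1, y))   # normal equations
    fit <- percFit(y, des, penaltyConfig(kappa = 0),
                   percControl(tol = 1e-15, maxCycles = 50000))
    expect_equal(unname(c(fit@coef@beta0, fit@coef@beta)),
                 unname(drop(ols)), tolerance = 1e-6)
  }
})

test_that("kappa at or above kappaMax yields the exactly-empty model", {
  set.seed(35)
  inst <- randomInstance(411)
  des <- inst$design; y <- inst$y
  km <- kappaMax(y, des)
  for (k in c(km, 1.01 * km, 5 * km)) {
    fit <- percFit(y, des, penaltyConfig(kappa = k))
    expect_identical(fit@coef@beta, rep(0, nPredictors(des)))
    expect_equal(fit@coef@beta0, mean(y))
    expect_length(activeSet(fit), 0L)
  }
  # and just below, the model is non-empty
  fitBelow <- percFit(y, des, penaltyConfig(kappa = 0.5 * km))
  expect_gt(modelSize(fitBelow), 0L)
})

test_that("kappaMax matches the hand subgradient formula on one column", {
  set.seed(36)
  x <- rbinom(40, 2, 0.3)
  y <- rnorm(40) + 0.4 * x
  des <- toyDesign(matrix(x, ncol = 1), group = 1, maf = 0.3)
  w <- columnInfo(des)$weight
  sg <- groupInfo(des)$sg     # single group -> 1
  expect_equal(kappaMax(y, des),
               abs(sum(x * (y - mean(y)))) / (sg + w))
  # a column uncorrelated with centered y contributes nothing
  x2 <- c(rep(1, 20), rep(0, 20))
  y2 <- rep(c(2, 4), 20)   # cor(x2, y2) = 0 by construction
  des2 <- toyDesign(cbind(x, x2), group = c(1, 2), maf = c(0.3, 0.25))
  z <- abs(sum(x2 * (y2 - mean(y2))))
  expect_equal(z, 0)
})

test_that("converged objective matches the independent maximizer", {
  for (seed in 1:8) {
    inst <- randomInstance(500 + seed)
    des <- inst$design; y <- inst$y
    cfg <- penaltyConfig(kappa = 0.15 * kappaMax(y, des))
    fit <- percFit(y, des, cfg, percControl(tol = 1e-10,
                                            maxCycles = 20000))
    oracle <- oracleMaxObjective(y, des, cfg)
    expect_lt(abs(objectiveValue(fit) - oracle), 1e-6)
  }
})

test_that("objective never decreases across updates and cycles", {
  set.seed(37)
  inst <- randomInstance(601)
  des <- inst$design; y <- inst$y
  fit <- percFit(y, des, penaltyConfig(kappa = 0.2 * kappaMax(y, des)),
                 percControl(traceLevel = 1))
  expect_true(all(diff(fit@trace) >= 0))
  # single-update property from random states
  q <- nPredictors(des)
  cfg <- penaltyConfig(kappa = 0.5)
  for (rep in 1:20) {
    co <- percCoefficients(rnorm(1), beta = rnorm(q) *
                             rbinom(q, 1, 0.7))
    before <- percObjective(y, des, co, cfg)
    j <- sample(0:q, 1)
    up <- updateCoordinate(j, y, des, co, cfg)
    after <- percObjective(y, des, up$coefs, cfg)
    expect_gte(after - before, -1e-12)
    expect_equal(after - before, up$deltaObjective, tolerance = 1e-8)
  }
})

test_that("reported objective equals recomputation on the coefficients", {
  inst <- randomInstance(602)
  cfg <- penaltyConfig(kappa = 0.1 * kappaMax(inst$y, inst$design))
  fit <- percFit(inst$y, inst$design, cfg)
  expect_equal(objectiveValue(fit),
               percObjective(inst$y, inst$design, fit@coef, cfg),
               tolerance = 1e-10)
  expect_identical(activeSet(fit), which(fit@coef@beta != 0))
})

test_that("warm-started path dominates cold restarts and orders sizes", {
  inst <- randomInstance(603)
  des <- inst$design; y <- inst$y
  km <- kappaMax(y, des)
  kappas <- exp(seq(log(km), log(0.02 * km), length.out = 12))
  ctrlTight <- percControl(tol = 1e-12, maxCycles = 20000)
  path <- percFitPath(y, des, kappas, control = ctrlTight)
  expect_s4_class(path, "PercPath")
  expect_length(path, 12L)
  sizes <- modelSizes(path)
  for (k in seq_along(kappas)) {
    cold <- percFit(y, des, penaltyConfig(kappa = kappas[k]), ctrlTight)
    expect_gte(objectiveValue(path[[k]]) - objectiveValue(cold), -1e-8)
  }
  # single huge kappa -> single empty model
  p1 <- percFitPath(y, des, kappas = 2 * km)
  expect_length(p1, 1L)
  expect_equal(modelSizes(p1), 0L)
  expect_error(percFitPath(y, des, kappas = numeric()), "empty")
  expect_error(percFitPath(y, des, kappas = c(1, 2)), "descending")
})

test_that("model size grows monotonically along most of the path", {
  # trend property over seeded simulations, not a theorem
  agree <- 0L; total <- 0L
  for (seed in 1:10) {
    inst <- randomInstance(700 + seed)
    km <- kappaMax(inst$y, inst$design)
    path <- percFitPath(inst$y, inst$design,
                        exp(seq(log(km), log(0.02 * km),
                                length.out = 10)))
    d <- diff(modelSizes(path))
    agree <- agree + sum(d >= 0)
    total <- total + length(d)
  }
  expect_gte(agree / total, 0.95)
})

test_that("column order does not change converged objectives", {
  inst <- randomInstance(801)
  des <- inst$design; y <- inst$y
  cfg <- penaltyConfig(kappa = 0.2 * kappaMax(y, des))
  ctrl <- percControl(tol = 1e-12, maxCycles = 20000)
  fit <- percFit(y, des, cfg, ctrl)
  q <- nPredictors(des)
  set.seed(99)
  perm <- sample.int(q)
  desP <- new("PercDesign",
              values = designMatrix(des)[, perm, drop = FALSE],
              columns = columnInfo(des)[perm, ],
              groups = groupInfo(des), tau = des@tau)
  fitP <- percFit(y, desP, cfg, ctrl)
  expect_lt(abs(objectiveValue(fit) - objectiveValue(fitP)), 1e-6)
})
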