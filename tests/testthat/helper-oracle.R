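# Independent general-purpose maximizer of the penalized objective, used
# to cross-check the coordinate-ascent optimizer. The nonsmooth objective
# is rewritten exactly as a smooth box-constrained problem: each
# coefficient splits into positive and negative parts (L1 becomes linear)
# and the group norm gets an epsilon inside the square root whose effect
# on the optimum is ~1e-9. stats::optim L-BFGS-B with analytic gradients
# then solves a concave maximization; the reported value is the TRUE
# objective evaluated at the recovered coefficients, maximized over
# several starts.

oracleMaxObjective <- function(y, design, config, eps = 1e-18) {
  X <- designMatrix(design)
  m <- nrow(X); q <- ncol(X)
  w <- columnInfo(design)$weight
  grp <- columnInfo(design)$group
  sg <- groupInfo(design)$sg
  l1 <- config@lambda1; l2 <- config@lambda2; l3 <- config@lambda3
  G <- nrow(groupInfo(design))

  fn <- function(th) {
    b0 <- th[1]; bp <- th[2:(q + 1)]; bn <- th[(q + 2):(2 * q + 1)]
    b <- bp - bn
    r <- y - b0 - drop(X %*% b)
    gss <- vapply(seq_len(G), function(g) sum(b[grp == g]^2), numeric(1))
    0.5 * sum(r^2) + l1 * sum(sg * sqrt(gss + eps)) +
      l2 * sum(w * (bp + bn)) + l3 * sum(w * b^2)
  }
  gr <- function(th) {
    b0 <- th[1]; bp <- th[2:(q + 1)]; bn <- th[(q + 2):(2 * q + 1)]
    b <- bp - bn
    r <- y - b0 - drop(X %*% b)
    gss <- vapply(seq_len(G), function(g) sum(b[grp == g]^2), numeric(1))
    gnorm <- sqrt(gss + eps)
    smooth <- -drop(crossprod(X, r)) + l1 * sg[grp] * b / gnorm[grp] +
      2 * l3 * w * b
    c(-sum(r), smooth + l2 * w, -smooth + l2 * w)
  }

  starts <- list(c(mean(y), rep(0, 2 * q)))
  xtx <- crossprod(cbind(1, X))
  if (qr(xtx)$rank == q + 1) {
    ols <- solve(xtx, crossprod(cbind(1, X), y))
    b <- ols[-1]
    starts[[2]] <- c(ols[1], pmax(b, 0), pmax(-b, 0))
  }
  best <- -Inf
  for (st in starts) {
    opt <- stats::optim(st, fn, gr, method = "L-BFGS-B",
                        lower = c(-Inf, rep(0, 2 * q)),
                        control = list(maxit = 5000, factr = 1e1,
                                       pgtol = 0))
    b <- opt$par[2:(q + 1)] - opt$par[(q + 2):(2 * q + 1)]
    co <- percCoefficients(beta0 = opt$par[1], beta = b)
    val <- percObjective(y, design, co, config)
    if (val > best) best <- val
  }
  best
}

# Brute-force per-base interval merge: two intervals belong together iff
# they share at least one base (adjacency is not overlap); merging is the
# transitive closure of that relation, each merged span running from its
# component's minimum start to maximum end. Oracle for the IRanges-based
# gene-group construction.
bruteForceMerge <- function(starts, ends) {
  n <- length(starts)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            length(intersect(starts[i]:ends[i], starts[j]:ends[j]))) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    data.frame(start = min(starts[comp == cc]),
               end = max(ends[comp == cc]))
  }))
  out[order(out$start), , drop = FALSE]
}
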