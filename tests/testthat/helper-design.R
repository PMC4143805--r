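# Construct small PercDesign objects directly for model/optimizer tests.
# kinds: "common_variant" columns get weight 2*sqrt(maf(1-maf)) from the
# supplied maf; "collapsed_rare" columns get sqrt(fr(1-fr)).

toyDesign <- function(X, group, kind = rep("common_variant", ncol(X)),
                      maf = rep(0.25, ncol(X)), fr = 0.1, tau = 0.005) {
  stopifnot(ncol(X) == length(group), length(kind) == ncol(X))
  weight <- ifelse(kind == "common_variant",
                   2 * sqrt(maf * (1 - maf)),
                   sqrt(fr * (1 - fr)))
  labels <- sprintf("col%02d", seq_len(ncol(X)))
  colnames(X) <- labels
  cols <- data.frame(label = labels, group = as.integer(group),
                     kind = kind, weight = weight,
                     snp = ifelse(kind == "common_variant",
                                  seq_len(ncol(X)), NA_integer_),
                     stringsAsFactors = FALSE)
  lg <- vapply(seq_len(max(group)), function(g) {
    sum(group == g & kind == "common_variant") +
      as.integer(any(group == g & kind == "collapsed_rare"))
  }, integer(1))
  groups <- data.frame(
    label = sprintf("G%d", seq_len(max(group))),
    kind = "gene", lg = lg, sg = sqrt(lg / max(lg)),
    dmin = NA_real_, dmax = NA_real_, fr = NA_real_,
    stringsAsFactors = FALSE)
  new("PercDesign", values = X, columns = cols, groups = groups,
      tau = tau)
}

# A random small fitting instance: m samples, 2-3 groups, <= 8 columns,
# mixed common-variant and collapsed-rare columns, trait with signal.
randomInstance <- function(seed, m = 50L) {
  set.seed(seed)
  G <- sample(2:3, 1)
  nc <- sample(1:3, G, replace = TRUE)   # common variants per group
  hasColl <- sample(c(TRUE, FALSE), G, replace = TRUE)
  cols <- list(); group <- integer(); kind <- character()
  maf <- numeric()
  for (g in seq_len(G)) {
    for (k in seq_len(nc[g])) {
      mafk <- runif(1, 0.05, 0.5)
      cols[[length(cols) + 1L]] <- rbinom(m, 2, mafk)
      group <- c(group, g); kind <- c(kind, "common_variant")
      maf <- c(maf, mafk)
    }
    if (hasColl[g]) {
      burden <- rbinom(m, 4, 0.1)
      if (max(burden) == min(burden)) burden[1] <- burden[1] + 1L
      cols[[length(cols) + 1L]] <-
        2 * (burden - min(burden)) / (max(burden) - min(burden))
      group <- c(group, g); kind <- c(kind, "collapsed_rare")
      maf <- c(maf, NA)
    }
  }
  X <- do.call(cbind, cols)
  # guard against monomorphic draws
  for (j in seq_len(ncol(X)))
    if (var(X[, j]) == 0) X[1, j] <- X[1, j] + 1
  des <- toyDesign(X, group, kind,
                   maf = ifelse(is.na(maf), 0.25, maf), fr = 0.08)
  beta <- rnorm(ncol(X), 0, 0.5) * rbinom(ncol(X), 1, 0.6)
  y <- drop(2 + X %*% beta + rnorm(m))
  list(y = y, design = des)
}
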