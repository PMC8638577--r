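# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit matrix inversion, explicit root-to-tip
# path intersection, and nested lm() fits.

# Brownian covariance by explicit path intersection: walk each tip's
# root-to-tip edge path (edges keyed by child node) and sum the lengths of
# the shared edges.
vcv_path_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen[tree$edge[, 2L]] <- tree$edge.length
  paths <- lapply(seq_len(n), function(tip) {
    e <- integer()
    node <- tip
    while (node != root) {
      e <- c(e, node)
      node <- parent[node]
    }
    e
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n))
    for (j in seq_len(n))
      V[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  V
}

# GLS coefficients by brute-force normal equations with explicit inverses.
gls_normal_eq_oracle <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# Classical nested-regression ANCOVA F test on OLS fits.
ols_ancova_oracle <- function(x, y, groups, test) {
  d <- data.frame(x = x, y = y, g = factor(groups))
  full <- switch(test, "S" = lm(y ~ g * x, d), "I" = lm(y ~ g + x, d),
                 "S+I" = lm(y ~ g * x, d))
  red <- switch(test, "S" = lm(y ~ g + x, d), "I" = lm(y ~ x, d),
                "S+I" = lm(y ~ x, d))
  rss_f <- sum(resid(full)^2)
  rss_r <- sum(resid(red)^2)
  df1 <- length(coef(full)) - length(coef(red))
  df2 <- nrow(d) - length(coef(full))
  F <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  list(F = F, df1 = df1, df2 = df2,
       P = pf(F, df1, df2, lower.tail = FALSE))
}

# A random ultrametric tree with named tips, via the package generator
# (unit depth) — convenience for tests that only need *some* tree.
rand_tree <- function(n, seed) sim_limb_tree(n, seed)$tree

# Identity covariance with taxon dimnames, for OLS-degenerate fits.
identity_vcv <- function(taxa) {
  V <- diag(length(taxa))
  dimnames(V) <- list(taxa, taxa)
  V
}
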