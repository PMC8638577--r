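# Design matrices for the nested ANCOVA models (reference coding).
.ancova_design <- function(x, groups,
                           model = c("common", "group_intercepts",
                                     "group_slopes_and_intercepts")) {
  model <- match.arg(model)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (any(table(g) < 3L))
    stop("every group needs at least 3 observations; too few in: ",
         paste(names(which(table(g) < 3L)), collapse = ", "))
  d <- data.frame(x = x, g = g)
  switch(model,
         common = stats::model.matrix(~x, d),
         group_intercepts = stats::model.matrix(~g + x, d),
         group_slopes_and_intercepts = stats::model.matrix(~g * x, d))
}

#' Design matrix for an ANCOVA model
#'
#' Builds the (reference-coded) design matrix for one of the three nested
#' models used in the slope/intercept comparisons: a common line
#' (\code{~x}), group-specific intercepts with a common slope
#' (\code{~group + x}), or group-specific slopes and intercepts
#' (\code{~group * x}).
#'
#' @param x Numeric predictor.
#' @param groups Group labels (>= 2 groups, each with >= 3 observations).
#' @param model \code{"common"}, \code{"group_intercepts"} or
#'   \code{"group_slopes_and_intercepts"}.
#' @return The model matrix.
#' @export
ancova_design <- function(x, groups, model = "common") {
  .ancova_design(x, groups, model)
}

#' Phylogenetic (or ordinary) analysis of covariance between groups
#'
#' Tests whether groups differ in slope (S), intercept (I), or both
#' (S + I) by comparing nested GLS fits under a common residual covariance
#' V. The data are whitened by the Cholesky factor of V and the usual
#' nested-model F statistic is formed:
#' \deqn{F = ((RSS_{red} - RSS_{full}) / df_1) / (RSS_{full} / df_2)}
#' with \eqn{df_1} the number of parameters released and
#' \eqn{df_2 = n - p_{full}}. The model pairs are: S — group slopes +
#' intercepts vs common slope + group intercepts; I — common slope + group
#' intercepts vs a single common line; S + I — group slopes + intercepts
#' vs a single common line. With \code{V} diagonal (lambda = 0) this is the
#' classical OLS ANCOVA. No multiple-testing correction is applied.
#'
#' @param x,y Numeric predictor and response (log10 scale in the allometric
#'   analyses).
#' @param groups Group labels aligned with \code{x}.
#' @param V Residual covariance matrix for these observations (e.g. a
#'   lambda-scaled phylogenetic covariance); \code{NULL} for the identity.
#' @param test \code{"S"}, \code{"I"} or \code{"S+I"}.
#' @return An object of class \code{"ancova_result"}: list with \code{F},
#'   \code{df1}, \code{df2}, \code{P}, \code{test}, \code{groups},
#'   \code{rss_full}, \code{rss_reduced}.
#' @export
pgls_ancova <- function(x, y, groups, V = NULL, test = c("S", "I", "S+I")) {
  test <- match.arg(test)
  n <- length(y)
  if (length(x) != n || length(groups) != n)
    stop("x, y and groups must have equal length")
  if (is.null(V)) V <- diag(n)
  models <- switch(test,
    "S"   = c("group_slopes_and_intercepts", "group_intercepts"),
    "I"   = c("group_intercepts", "common"),
    "S+I" = c("group_slopes_and_intercepts", "common"))
  Xf <- .ancova_design(x, groups, models[1L])
  Xr <- .ancova_design(x, groups, models[2L])
  full <- .gls_core(Xf, y, V)
  red <- .gls_core(Xr, y, V)
  df1 <- ncol(Xf) - ncol(Xr)
  df2 <- n - ncol(Xf)
  if (df2 < 1L) stop("no residual degrees of freedom for the full model")
  num <- (red$rss - full$rss) / df1
  den <- full$rss / df2
  # both models interpolating (noiseless identical lines): F defined as 0
  Fstat <- if (red$rss - full$rss <= 1e-12 * max(1, red$rss)) 0 else num / den
  P <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(F = Fstat, df1 = df1, df2 = df2, P = P, test = test,
                 groups = levels(factor(groups)),
                 rss_full = full$rss, rss_reduced = red$rss),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA %s test (%s): F(%d, %d) = %.4f, P = %.4g\n",
              x$test, paste(x$groups, collapse = " vs "),
              x$df1, x$df2, x$F, x$P))
  invisible(x)
}

#' Pairwise group comparisons of allometric slopes and intercepts
#'
#' For every pair of groups, runs the S, I and S + I tests of
#' [pgls_ancova()] twice: once phylogenetically (residual covariance equal
#' to the pair's Brownian matrix with off-diagonals scaled by
#' \code{lambda}, conventionally the ML lambda of the pooled fit of the
#' same comparison) and once without phylogeny (lambda = 0, ordinary
#' ANCOVA). Groups with fewer than \code{min_n} observations are skipped
#' with a message.
#'
#' @param xy A data.frame with columns \code{species, group, x, y} (e.g.
#'   from [comparison_xy()]).
#' @param tree A \code{"phylo"} tree covering the species.
#' @param lambda Lambda applied to the phylogenetic runs (default 1).
#' @param min_n Minimum observations per group (default 3).
#' @param quiet Suppress skip messages.
#' @return A data.frame with one row per pair x test x mode: columns
#'   \code{group1, group2, test, phylogenetic, n, df1, df2, F, P}.
#' @export
pairwise_group_tests <- function(xy, tree, lambda = 1, min_n = 3L,
                                 quiet = FALSE) {
  counts <- table(xy$group)
  keep <- names(counts)[counts >= min_n]
  dropped <- setdiff(names(counts), keep)
  if (length(dropped) && !quiet)
    message("skipping group(s) with fewer than ", min_n, " species: ",
            paste(dropped, collapse = ", "))
  if (length(keep) < 2L)
    stop("fewer than two groups with enough observations")
  pairs <- utils::combn(sort(keep), 2L, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    d <- xy[xy$group %in% pr, , drop = FALSE]
    V1 <- phylo_vcv(prune_taxa(tree, d$species), taxa = d$species,
                    lambda = lambda)
    V0 <- lambda_transform(V1, 0)
    for (test in c("S", "I", "S+I")) {
      for (phylo in c(TRUE, FALSE)) {
        res <- pgls_ancova(d$x, d$y, d$group,
                           V = if (phylo) V1 else V0, test = test)
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = pr[1L], group2 = pr[2L], test = test,
          phylogenetic = phylo, n = nrow(d), df1 = res$df1, df2 = res$df2,
          F = res$F, P = res$P, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
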