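# Generalized least squares core. Whitens by the Cholesky factor of V and
# solves the resulting OLS problem by QR; returns everything the profile
# likelihood and the downstream inference need.
.gls_core <- function(X, y, V) {
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimensions of X, y and V do not agree")
  U <- tryCatch(chol(V), error = function(e)
    stop("V is not positive-definite (", conditionMessage(e), ")"))
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) {
    sv <- svd(Xw, nu = 0, nv = 0)$d
    stop(sprintf(
      "design matrix is collinear after whitening (condition number %.3g)",
      max(sv) / max(min(sv), .Machine$double.xmin)))
  }
  beta <- drop(qr.coef(qx, yw))
  res_w <- drop(yw - Xw %*% beta)
  rss <- sum(res_w^2)
  logdet <- 2 * sum(log(diag(U)))
  s2_ml <- rss / n
  loglik <- if (s2_ml <= 0) Inf else
    -0.5 * (n * log(2 * pi * s2_ml) + logdet + n)
  XtViX_inv <- chol2inv(qr.R(qx))
  dimnames(XtViX_inv) <- list(colnames(X), colnames(X))
  list(beta = beta, rss = rss, logdet = logdet, loglik = loglik,
       s2_ml = s2_ml, XtViX_inv = XtViX_inv,
       fitted = drop(X %*% beta), residuals = drop(y - X %*% beta),
       residuals_w = res_w)
}

# Profile log-likelihood maximisation over Pagel's lambda: coarse grid then
# bounded refinement; ties (flat likelihood, e.g. zero residuals) resolve
# to the smallest lambda.
.profile_lambda <- function(X, y, V_bm, grid_points = 21, tol = 1e-6) {
  ll_at <- function(lam) .gls_core(X, y, lambda_transform(V_bm, lam))$loglik
  # degenerate (noiseless) data: likelihood is unbounded for every lambda
  f0 <- .gls_core(X, y, lambda_transform(V_bm, 0))
  if (f0$rss <= 1e-20 * max(1, sum(y^2)))
    return(list(lambda = 0, degenerate = TRUE, grid = NULL))
  grid <- seq(0, 1, length.out = grid_points)
  ll <- vapply(grid, ll_at, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll_at, interval = c(lo, hi), maximum = TRUE,
                         tol = tol)
  cand <- data.frame(lambda = c(grid, opt$maximum),
                     ll = c(ll, opt$objective))
  cand <- cand[order(cand$lambda), ]
  best <- max(cand$ll)
  if (!is.finite(best))
    stop("lambda profile likelihood did not evaluate to finite values; ",
         "profiled grid: ",
         paste(sprintf("%.2f:%.3g", cand$lambda, cand$ll), collapse = " "))
  tie_tol <- 1e-8 * max(1, abs(best))
  lam_hat <- cand$lambda[which(cand$ll >= best - tie_tol)[1L]]
  list(lambda = lam_hat, degenerate = FALSE,
       grid = stats::setNames(ll, format(grid, digits = 3)))
}

#' Phylogenetic generalized least squares with ML estimation of lambda
#'
#' Fits a linear model by generalized least squares under a residual
#' covariance proportional to a Brownian-motion phylogenetic covariance
#' matrix whose off-diagonals are scaled by Pagel's lambda. By default
#' lambda is estimated by maximising the profile (Gaussian) log-likelihood
#' over [0, 1]; with \code{lambda = 0} the fit reduces exactly to ordinary
#' least squares. Intended for log10-transformed allometric data
#' (\code{log10 Y = log10 A + B log10 X}), but the formula interface is
#' general.
#'
#' The likelihood uses the ML variance estimate (\code{RSS/n}); standard
#' errors, confidence intervals and prediction intervals use the unbiased
#' estimate (\code{RSS/(n - p)}) with t quantiles on \code{n - p} degrees
#' of freedom. Slope estimates are invariant to multiplying V by any
#' positive constant, so the overall depth scaling of the tree is
#' immaterial to the fitted exponents.
#'
#' @param formula Model formula, e.g. \code{y ~ x} on log10 variables.
#' @param data A data.frame containing the model variables and (unless
#'   \code{species} is given) a \code{species} column naming the tip of
#'   each row.
#' @param tree A \code{"phylo"} tree covering every species in \code{data}.
#'   Ignored if \code{V} is supplied.
#' @param V Optional precomputed Brownian covariance matrix (lambda = 1)
#'   with dimnames; it is subset/ordered to the data's species.
#' @param species Optional character vector of tip names, one per row of
#'   \code{data}; defaults to \code{data$species}.
#' @param lambda \code{"ML"} (default) to estimate by maximum likelihood,
#'   or a fixed number in [0, 1].
#' @param level Confidence level for intervals (default 0.95).
#' @param grid_points Number of grid points in the coarse lambda scan.
#' @param tol Tolerance of the bounded lambda refinement.
#' @return An object of class \code{"pgls"} with components including
#'   \code{coefficients}, \code{se}, \code{lambda}, \code{sigma2} (unbiased),
#'   \code{sigma2_ml}, \code{logLik}, \code{ci} (coefficient confidence
#'   bounds), \code{n}, \code{df.residual}, \code{fitted.values},
#'   \code{residuals}. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{vcov}, \code{confint}, \code{logLik}, \code{nobs},
#'   \code{fitted}, \code{residuals}, \code{predict}, \code{simulate},
#'   \code{plot}.
#' @examples
#' d <- isometric_fixture(20, seed = 1)
#' agg <- aggregate_limbs(d$muscles)
#' xy <- comparison_xy(agg[agg$limb == "hind", ], "mass_v_body")
#' fit <- pgls(y ~ x, data = xy, tree = d$tree)
#' coef(fit)   # slope is exactly 1 under geometric similarity
#' @export
pgls <- function(formula, data, tree = NULL, V = NULL, species = NULL,
                 lambda = "ML", level = 0.95, grid_points = 21, tol = 1e-6) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  if (n < 3L) stop("at least 3 observations are required")
  if (is.null(species)) {
    if (!"species" %in% names(data))
      stop("supply 'species' or include a species column in 'data'")
    species <- data$species
  }
  species <- normalize_taxon(as.character(species))
  if (anyDuplicated(species))
    stop("duplicate species in data: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  if (is.null(V)) {
    if (is.null(tree)) stop("supply either 'tree' or 'V'")
    V_bm <- phylo_vcv(prune_taxa(tree, species), taxa = species)
  } else {
    if (is.null(rownames(V))) stop("'V' must have taxon dimnames")
    rownames(V) <- colnames(V) <- normalize_taxon(rownames(V))
    unknown <- setdiff(species, rownames(V))
    if (length(unknown))
      stop("species missing from V: ", paste(unknown, collapse = ", "))
    V_bm <- structure(V[species, species, drop = FALSE],
                      class = c("phylo_vcv", "matrix"), lambda = 1)
  }
  ml <- identical(lambda, "ML")
  degenerate <- FALSE
  profile <- NULL
  if (ml) {
    prof <- .profile_lambda(X, y, V_bm, grid_points = grid_points, tol = tol)
    lam_hat <- prof$lambda
    degenerate <- prof$degenerate
    profile <- prof$grid
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
      stop("'lambda' must be \"ML\" or a number in [0, 1]")
    lam_hat <- lambda
  }
  fit <- .gls_core(X, y, lambda_transform(V_bm, lam_hat))
  p <- ncol(X)
  df <- n - p
  s2 <- fit$rss / df
  se <- sqrt(s2 * diag(fit$XtViX_inv))
  tq <- stats::qt(1 - (1 - level) / 2, df)
  ci <- cbind(lower = fit$beta - tq * se, upper = fit$beta + tq * se)
  rownames(ci) <- colnames(X)
  structure(list(
    coefficients = stats::setNames(fit$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    ci = ci, level = level,
    lambda = lam_hat, lambda_ml = ml, lambda_profile = profile,
    degenerate = degenerate,
    sigma2 = s2, sigma2_ml = fit$s2_ml,
    logLik = fit$loglik, rss = fit$rss,
    n = n, p = p, df.residual = df,
    fitted.values = fit$fitted, residuals = fit$residuals,
    residuals_normalized = fit$residuals_w,
    XtViX_inv = fit$XtViX_inv,
    V_bm = V_bm, species = species,
    model = mf, terms = attr(mf, "terms"), formula = formula,
    call = cl), class = "pgls")
}

#' Classify a fitted allometry against its isometric expectation
#'
#' Compares the confidence interval of a fitted slope with the slope
#' expected under geometric similarity: if the expectation falls below the
#' interval the trait scales with positive allometry, above it with
#' negative allometry, and inside it the departure from isometry is not
#' significant at the interval's level.
#'
#' @param fit A \code{"pgls"} fit.
#' @param expected The isometric slope, e.g. from [isometric_slope()].
#' @param which Index or name of the slope coefficient (default 2, the
#'   slope of a bivariate fit).
#' @param tol Numerical guard band around the interval; the expectation
#'   must fall outside the interval by more than \code{tol} to be called a
#'   departure (protects degenerate zero-width intervals on noiseless data
#'   from floating-point round-off).
#' @return An object of class \code{"isometry_verdict"}: list with
#'   \code{expected}, \code{ci}, \code{verdict} (one of
#'   \code{"negative_allometry"}, \code{"isometry_not_rejected"},
#'   \code{"positive_allometry"}).
#' @export
assess_isometry <- function(fit, expected, which = 2L, tol = 1e-8) {
  ci <- fit$ci[which, ]
  verdict <- if (expected < ci[["lower"]] - tol) "positive_allometry"
  else if (expected > ci[["upper"]] + tol) "negative_allometry"
  else "isometry_not_rejected"
  structure(list(expected = expected, ci = ci, slope = coef(fit)[[which]],
                 level = fit$level, verdict = verdict),
            class = "isometry_verdict")
}

#' @export
print.isometry_verdict <- function(x, ...) {
  cat(sprintf("slope %.4f, %d%% CI [%.4f, %.4f], isometric expectation %.4f\n",
              x$slope, round(100 * x$level), x$ci[["lower"]],
              x$ci[["upper"]], x$expected))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
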