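#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic generalized least squares fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("lambda = %.4f%s, n = %d, logLik = %.3f\n", x$lambda,
              if (x$lambda_ml) " (ML)" else " (fixed)", x$n,
              x$logLik))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tval <- object$coefficients / object$se
  pval <- 2 * stats::pt(abs(tval), object$df.residual, lower.tail = FALSE)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval, `Pr(>|t|)` = pval,
               lower = object$ci[, "lower"], upper = object$ci[, "upper"])
  structure(list(call = object$call, coefficients = tab,
                 lambda = object$lambda, lambda_ml = object$lambda_ml,
                 sigma2 = object$sigma2, logLik = object$logLik,
                 n = object$n, df.residual = object$df.residual,
                 level = object$level),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic generalized least squares fit\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits)
  cat(sprintf("\n%d%% CI bounds:\n", round(100 * x$level)))
  print(round(x$coefficients[, 5:6, drop = FALSE], digits))
  cat(sprintf("\nPagel's lambda: %.4f%s\n", x$lambda,
              if (x$lambda_ml) " (ML estimate)" else " (fixed)"))
  cat(sprintf("Residual variance (unbiased): %.6g on %d df; logLik %.3f; n = %d\n",
              x$sigma2, x$df.residual, x$logLik, x$n))
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$sigma2 * object$XtViX_inv

#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  est <- object$coefficients
  ci <- cbind(est - tq * object$se, est + tq * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = object$p + 1L + object$lambda_ml,
            nobs = object$n, class = "logLik")
}

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$residuals_normalized
}

#' Predictions, confidence and prediction intervals from a pGLS fit
#'
#' Computes point predictions at new predictor values, optionally with
#' confidence intervals for the regression line or prediction intervals
#' for a new observation. The new taxon is treated as phylogenetically
#' independent of the training sample: zero covariance with every sampled
#' tip, and own variance equal to the mean root-to-tip depth of the
#' training tree (equal to every tip's depth on an ultrametric tree).
#'
#' With \code{antilog = TRUE}, the predictions (and interval bounds) are
#' back-transformed by \code{10^x} to original units; by default no
#' log-normal bias correction is applied, matching the plain antilog
#' convention for allometric prediction equations
#' (\code{bias_correct = TRUE} applies the parametric correction
#' \code{10^(ln(10) sigma^2 / 2)}).
#'
#' @param object A \code{"pgls"} fit.
#' @param newdata Data.frame of predictor values; defaults to the training
#'   data.
#' @param interval \code{"none"}, \code{"confidence"} or
#'   \code{"prediction"}.
#' @param level Interval level in (0, 1); defaults to the fit's level.
#' @param antilog Back-transform results by \code{10^x}?
#' @param bias_correct Apply the log-normal correction on back-transform?
#' @param ... Unused.
#' @return A vector (\code{interval = "none"}) or a data.frame with
#'   columns \code{fit, lwr, upr}.
#' @export
predict.pgls <- function(object, newdata = NULL,
                         interval = c("none", "confidence", "prediction"),
                         level = object$level, antilog = FALSE,
                         bias_correct = FALSE, ...) {
  interval <- match.arg(interval)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a single number in (0, 1)")
  tt <- stats::delete.response(object$terms)
  X0 <- if (is.null(newdata))
    stats::model.matrix(object$terms, object$model)
  else stats::model.matrix(tt, stats::model.frame(tt, newdata))
  yhat <- drop(X0 %*% object$coefficients)
  if (interval == "none") {
    out <- yhat
    if (antilog) {
      out <- 10^out
      if (bias_correct) out <- out * 10^(log(10) * object$sigma2 / 2)
    }
    return(out)
  }
  q <- rowSums((X0 %*% object$XtViX_inv) * X0)
  v0 <- if (interval == "prediction") mean(diag(object$V_bm)) else 0
  se <- sqrt(object$sigma2 * (v0 + q))
  tq <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  out <- data.frame(fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se)
  if (antilog) {
    out[] <- lapply(out, function(v) 10^v)
    if (bias_correct)
      out$fit <- out$fit * 10^(log(10) * object$sigma2 / 2)
  }
  out
}

#' Simulate responses from a fitted pGLS model
#'
#' Draws response vectors from the fitted model: mean \code{X beta},
#' covariance \code{sigma2 * V(lambda-hat)} (multivariate normal via a
#' Cholesky factor).
#'
#' @param object A \code{"pgls"} fit.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with \code{nsim} columns, one simulated response
#'   per column, rows aligned with the training data.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Vl <- lambda_transform(object$V_bm, object$lambda)
  U <- chol(object$sigma2 * Vl)
  Z <- matrix(stats::rnorm(object$n * nsim), object$n, nsim)
  out <- as.data.frame(object$fitted.values + crossprod(U, Z))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$species
  out
}

#' Plot a bivariate pGLS fit
#'
#' Scatter plot of the (log10) data with the fitted regression line and a
#' confidence band for the line. Only defined for bivariate fits.
#'
#' @param x A \code{"pgls"} fit with a single predictor.
#' @param band \code{"confidence"}, \code{"prediction"} or \code{"none"}.
#' @param n_grid Number of grid points for the band.
#' @param ... Passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.pgls <- function(x, band = c("confidence", "prediction", "none"),
                      n_grid = 100, ...) {
  band <- match.arg(band)
  if (x$p != 2L) stop("plot.pgls is defined for bivariate fits only")
  mf <- x$model
  xv <- mf[[2L]]; yv <- mf[[1L]]
  xn <- names(mf)[2L]; yn <- names(mf)[1L]
  graphics::plot(xv, yv, xlab = xn, ylab = yn, ...)
  xs <- seq(min(xv), max(xv), length.out = n_grid)
  nd <- stats::setNames(data.frame(xs), xn)
  if (band == "none") {
    graphics::abline(x$coefficients[1L], x$coefficients[2L])
  } else {
    pr <- predict(x, nd, interval = band)
    graphics::lines(xs, pr$fit)
    graphics::lines(xs, pr$lwr, lty = 2)
    graphics::lines(xs, pr$upr, lty = 2)
  }
  invisible(x)
}

#' Mean percent prediction error of a fitted allometry
#'
#' Expresses the in-sample accuracy of a log10-scale regression in the
#' original (antilog) units: for each training observation,
#' \code{\%PE = 100 |Y - Yhat| / Yhat} with both quantities
#' back-transformed, which reduces to \code{100 |10^r - 1|} for the log10
#' residual r. The arithmetic mean over observations is returned. \%PE is
#' unchanged if all responses are multiplied by a constant (the intercept
#' absorbs the factor).
#'
#' @param fit A \code{"pgls"} fit on log10 data.
#' @return Mean percent prediction error (a single non-negative number).
#' @export
percent_prediction_error <- function(fit) {
  r <- residuals(fit)
  mean(100 * abs(10^r - 1))
}
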