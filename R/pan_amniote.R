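#' Pooled ("pan-amniote") predictive allometry for one comparison
#'
#' Pools the groups of an aggregate table (by default excluding bipeds,
#' whose hindlimb allometries frequently diverge from the quadrupedal
#' pattern) and fits a single pGLS with ML lambda for one anatomical
#' comparison, attaching the in-sample mean percent prediction error. The
#' resulting equation, on the log10 scale
#' \code{log10 Y = intercept + slope * log10 X}, is the basis for
#' estimating muscle properties of unsampled (e.g. extinct) taxa.
#'
#' @param agg An aggregate table from [aggregate_limbs()] (already filtered
#'   to one limb and computed at the desired scope/CFL variant).
#' @param tree A \code{"phylo"} tree covering the species.
#' @param comparison A comparison id (see [limb_comparisons()]).
#' @param exclude_groups Groups to drop before pooling (default
#'   \code{"biped"}).
#' @param min_n Minimum pooled sample size (default 10).
#' @param ... Passed to [pgls()] (e.g. \code{lambda}).
#' @return An object of class \code{c("pan_amniote", "pgls")}; the
#'   underlying fit plus \code{comparison}, \code{mean_pct_PE},
#'   \code{excluded_groups} and \code{isometric_slope}.
#' @examples
#' d <- isometric_fixture(20, seed = 1)
#' agg <- aggregate_limbs(d$muscles)
#' eq <- pan_amniote_fit(agg[agg$limb == "hind", ], d$tree, "mass_v_body")
#' coef(eq)
#' @export
pan_amniote_fit <- function(agg, tree, comparison,
                            exclude_groups = "biped", min_n = 10L, ...) {
  xy <- comparison_xy(agg, comparison, quiet = TRUE)
  xy <- xy[!xy$group %in% exclude_groups, , drop = FALSE]
  if (nrow(xy) < min_n)
    stop("only ", nrow(xy), " species remain after filters; at least ",
         min_n, " are required")
  fit <- pgls(y ~ x, data = xy, tree = tree, ...)
  fit$comparison <- comparison
  fit$isometric_slope <- isometric_slope(comparison)
  fit$excluded_groups <- exclude_groups
  fit$mean_pct_PE <- percent_prediction_error(fit)
  class(fit) <- c("pan_amniote", "pgls")
  fit
}

#' @export
print.pan_amniote <- function(x, digits = 4, ...) {
  cat("Pan-amniote predictive equation —", x$comparison, "\n")
  cat(sprintf("log10 Y = %.4f + %.4f log10 X   (lambda = %.4f, n = %d)\n",
              x$coefficients[[1L]], x$coefficients[[2L]], x$lambda, x$n))
  cat(sprintf("isometric slope %.4f; mean %%PE = %.2f%%",
              x$isometric_slope, x$mean_pct_PE))
  if (length(x$excluded_groups))
    cat("; excluded groups: ", paste(x$excluded_groups, collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' Predict in original units from a fitted allometry
#'
#' Applies a fitted log10-scale equation to a predictor in original units
#' (e.g. body mass in kg) and returns the point estimate with two
#' alternative error margins, both back-transformed to original units:
#' the 95% (or \code{level}) prediction interval, and the mean-%PE margin
#' \code{fit * (1 -/+ \%PE/100)}.
#'
#' @param fit A \code{"pgls"} fit on log10 data (typically a
#'   \code{"pan_amniote"} equation).
#' @param x0 Predictor values in original (linear) units; must be > 0.
#' @param level Prediction-interval level.
#' @return A data.frame with columns \code{x, fit, pi_lwr, pi_upr} and,
#'   when the fit carries a mean %PE, \code{pe_lwr, pe_upr}.
#' @examples
#' d <- isometric_fixture(20, seed = 1)
#' agg <- aggregate_limbs(d$muscles)
#' eq <- pan_amniote_fit(agg[agg$limb == "hind", ], d$tree, "mass_v_body")
#' predict_antilog(eq, c(10, 100, 1000))
#' @export
predict_antilog <- function(fit, x0, level = 0.95) {
  if (any(!is.finite(x0) | x0 <= 0))
    stop("'x0' must be finite and > 0 (original, non-log units)")
  nd <- stats::setNames(data.frame(log10(x0)),
                        all.vars(stats::delete.response(fit$terms)))
  pr <- predict(fit, nd, interval = "prediction", level = level,
                antilog = TRUE)
  out <- data.frame(x = x0, fit = pr$fit, pi_lwr = pr$lwr, pi_upr = pr$upr)
  if (!is.null(fit$mean_pct_PE)) {
    out$pe_lwr <- out$fit * (1 - fit$mean_pct_PE / 100)
    out$pe_upr <- out$fit * (1 + fit$mean_pct_PE / 100)
  }
  out
}
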