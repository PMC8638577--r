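#' Assemble an analysis configuration
#'
#' Normalises a configuration for [run_limb_analysis()], either from a
#' named list or a YAML file with the same field names. The default
#' analysis grid mirrors the standard design: for each anatomical
#' comparison, forelimb and hindlimb each at whole/proximal/distal scope,
#' plus hindlimb whole and proximal re-run with the caudofemoralis longus
#' excluded — eight sub-analyses per comparison. Forelimb cells never
#' include bipeds.
#'
#' @param config A named list or path to a YAML file. Recognised fields:
#'   \code{muscles} (data.frame or CSV path), \code{tree} (\code{"phylo"}
#'   or Newick path), \code{comparisons}, \code{limbs}, \code{scopes},
#'   \code{cfl_scopes} (hindlimb scopes re-run without the CFL),
#'   \code{exclude_groups_pan} (groups excluded from pooled equations,
#'   default \code{"biped"}), \code{min_group_n}, \code{constants}
#'   (list of density/stress/g overrides), \code{out_dir}, \code{seed}.
#' @return A validated configuration list of class \code{"limb_config"}.
#' @export
limb_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(comparisons = limb_comparisons(),
                   limbs = c("fore", "hind"),
                   scopes = c("whole", "proximal", "distal"),
                   cfl_scopes = c("whole", "proximal"),
                   exclude_groups_pan = "biped",
                   min_group_n = 3L, constants = list(), out_dir = NULL,
                   seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.character(config$muscles))
    config$muscles <- read_muscle_table(config$muscles)
  if (is.character(config$tree))
    config$tree <- read_limb_tree(config$tree)
  if (is.null(config$muscles) || is.null(config$tree))
    stop("'muscles' and 'tree' are required")
  config$constants <- do.call(limb_constants, config$constants)
  bad <- setdiff(config$comparisons, limb_comparisons())
  if (length(bad)) stop("unknown comparison(s): ", paste(bad, collapse = ", "))
  structure(config, class = "limb_config")
}

# grid of (limb, scope, exclude_cfl) analysis cells
.analysis_cells <- function(config) {
  cells <- expand.grid(limb = config$limbs, scope = config$scopes,
                       exclude_cfl = FALSE, stringsAsFactors = FALSE)
  if ("hind" %in% config$limbs && length(config$cfl_scopes))
    cells <- rbind(cells, data.frame(limb = "hind",
                                     scope = config$cfl_scopes,
                                     exclude_cfl = TRUE))
  cells
}

#' Run the full whole-limb allometry analysis
#'
#' Executes, for every analysis cell (limb x scope x CFL variant) and
#' anatomical comparison: per-group pGLS fits with ML lambda and isometry
#' verdicts; the pooled predictive equation (pan fit, bipeds excluded by
#' default) with confidence bounds and mean \%PE; and pairwise group
#' comparisons by pANCOVA (lambda taken from the pooled fit of the same
#' cell) and ordinary ANCOVA (lambda = 0). Species present in the muscle
#' table but absent from the tree are a hard error. Groups below the
#' minimum sample size are skipped with a message. Deterministic: the same
#' configuration always reproduces identical outputs.
#'
#' @param config A [limb_config()] (or list/YAML path coercible to one).
#' @return A list of class \code{"limb_analysis"} with data.frames
#'   \code{fits} (per-group and pooled coefficients, CIs, lambda, verdicts,
#'   \%PE), \code{comparisons} (pairwise F tests) and \code{manifest}.
#'   If \code{out_dir} is set, writes \code{fits.csv},
#'   \code{comparisons.csv}, \code{equations.csv} and
#'   \code{manifest.json} there.
#' @examples
#' d <- isometric_fixture(16, seed = 7)
#' res <- run_limb_analysis(list(muscles = d$muscles, tree = d$tree,
#'                               scopes = "whole", cfl_scopes = character()))
#' subset(res$fits, group == "pan")[, c("limb", "comparison", "slope")]
#' @export
run_limb_analysis <- function(config) {
  if (!inherits(config, "limb_config")) config <- limb_config(config)
  muscles <- config$muscles
  tree <- config$tree
  missing_tips <- setdiff(normalize_taxon(unique(muscles$species)),
                          normalize_taxon(tree$tip.label))
  if (length(missing_tips))
    stop("species missing from the tree: ",
         paste(missing_tips, collapse = ", "))
  cells <- .analysis_cells(config)
  fits <- list(); comps <- list(); notes <- character()
  for (ci in seq_len(nrow(cells))) {
    limb <- cells$limb[ci]; scope <- cells$scope[ci]
    excl <- cells$exclude_cfl[ci]
    md <- muscles[muscles$limb == limb, , drop = FALSE]
    if (limb == "fore") md <- md[md$group != "biped", , drop = FALSE]
    if (!nrow(md)) next
    agg <- aggregate_limbs(md, scope = scope, exclude_cfl = excl,
                           constants = config$constants)
    for (comparison in config$comparisons) {
      xy <- tryCatch(comparison_xy(agg, comparison, quiet = TRUE),
                     error = function(e) NULL)
      if (is.null(xy) || nrow(xy) < 3L) {
        notes <- c(notes, sprintf("skipped %s/%s/%s/cfl=%s: too few species",
                                  limb, scope, comparison, excl))
        next
      }
      pan <- tryCatch(
        pan_amniote_fit(agg, tree, comparison,
                        exclude_groups = config$exclude_groups_pan,
                        min_n = max(3L, config$min_group_n)),
        error = function(e) NULL)
      if (!is.null(pan)) {
        fits[[length(fits) + 1L]] <- .fit_row(pan, "pan", limb, scope, excl,
                                              comparison)
      }
      for (g in sort(unique(xy$group))) {
        xg <- xy[xy$group == g, , drop = FALSE]
        if (nrow(xg) < config$min_group_n) {
          notes <- c(notes, sprintf("skipped group %s in %s/%s/%s (n=%d)",
                                    g, limb, scope, comparison, nrow(xg)))
          next
        }
        fit <- pgls(y ~ x, data = xg, tree = tree)
        fits[[length(fits) + 1L]] <- .fit_row(fit, g, limb, scope, excl,
                                              comparison)
      }
      n_ok <- sum(table(xy$group) >= config$min_group_n)
      if (n_ok >= 2L) {
        lam_pan <- if (!is.null(pan)) pan$lambda else 1
        pw <- pairwise_group_tests(xy, tree, lambda = lam_pan,
                                   min_n = config$min_group_n, quiet = TRUE)
        pw <- cbind(limb = limb, scope = scope, exclude_cfl = excl,
                    comparison = comparison, lambda_pan = lam_pan, pw)
        comps[[length(comps) + 1L]] <- pw
      }
    }
  }
  fits <- do.call(rbind, fits)
  comps <- if (length(comps)) do.call(rbind, comps) else NULL
  manifest <- .run_manifest(config, notes)
  out <- structure(list(fits = fits, comparisons = comps,
                        manifest = manifest, notes = notes),
                   class = "limb_analysis")
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

.fit_row <- function(fit, group, limb, scope, exclude_cfl, comparison) {
  iso <- isometric_slope(comparison)
  verdict <- assess_isometry(fit, iso)$verdict
  data.frame(limb = limb, scope = scope, exclude_cfl = exclude_cfl,
             comparison = comparison, group = group, n = fit$n,
             slope = fit$coefficients[[2L]],
             slope_lwr = fit$ci[2L, "lower"], slope_upr = fit$ci[2L, "upper"],
             intercept = fit$coefficients[[1L]],
             intercept_lwr = fit$ci[1L, "lower"],
             intercept_upr = fit$ci[1L, "upper"],
             lambda = fit$lambda, iso_slope = iso, verdict = verdict,
             mean_pct_PE = if (is.null(fit$mean_pct_PE)) NA_real_ else
               fit$mean_pct_PE,
             stringsAsFactors = FALSE)
}

.run_manifest <- function(config, notes) {
  cfg <- config[setdiff(names(config), c("muscles", "tree"))]
  cfg$constants <- unclass(cfg$constants)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  list(config = cfg, config_md5 = unname(tools::md5sum(tf)),
       seed = config$seed,
       n_species = length(unique(config$muscles$species)),
       n_records = nrow(config$muscles),
       package_version = as.character(utils::packageVersion("limbscale")),
       r_version = R.version.string, notes = notes)
}

.write_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$fits, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  if (!is.null(res$comparisons))
    utils::write.csv(res$comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  eq <- res$fits[res$fits$group == "pan", , drop = FALSE]
  utils::write.csv(eq, file.path(out_dir, "equations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.limb_analysis <- function(x, ...) {
  cat("Whole-limb allometry analysis\n")
  cat(sprintf("  %d fitted allometries (%d pooled equations)\n",
              nrow(x$fits), sum(x$fits$group == "pan")))
  if (!is.null(x$comparisons))
    cat(sprintf("  %d pairwise group tests\n", nrow(x$comparisons)))
  if (length(x$notes)) cat(sprintf("  %d skip notices\n", length(x$notes)))
  invisible(x)
}
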