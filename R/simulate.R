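#' Specification of a synthetic whole-limb dataset
#'
#' Collects the parameters that define a simulated comparative dataset:
#' sample size, group composition, the span of body masses (the default
#' covers five orders of magnitude, as in broad interspecific samples),
#' per-group allometric slopes and intercepts for total limb muscle mass
#' and characteristic fascicle length, the residual scatter and its
#' phylogenetic structure (Pagel's lambda of the generating process), and
#' the shape of the per-muscle decomposition. The defaults are chosen to
#' resemble published whole-limb allometries: total muscle mass scaling
#' near isometry with a slightly negative reptile slope and slightly
#' positive biped slope, hindlimb muscle comprising a few percent of body
#' mass, and log10 residual scatter of 0.08.
#'
#' @param n_species Number of species (>= 4).
#' @param group_fractions Named proportions over
#'   \code{mammal/reptile/biped}; must sum to 1.
#' @param log10_mass_range Range of log10 body mass in kg.
#' @param mass_slope,mass_intercept Named per-group coefficients of
#'   log10 total limb muscle mass on log10 body mass.
#' @param lstar_slope,lstar_intercept Same for log10 characteristic
#'   fascicle length.
#' @param residual_sd Residual standard deviation on the log10 scale.
#' @param lambda_true Pagel's lambda of the generating residual covariance.
#' @param muscles_per_species Muscles per species x limb.
#' @param pennation_range Pennation range in degrees.
#' @param cfl_fraction Fraction of reptile hindlimb muscle mass held by the
#'   caudofemoralis longus.
#' @param dirichlet_conc Concentration of the Dirichlet mass partition
#'   (1 = uniform simplex; smaller values give the skewed per-muscle mass
#'   distributions typical of real limbs).
#' @param limbs Limbs to simulate.
#' @return A validated list of class \code{"sim_spec"}.
#' @export
sim_spec <- function(n_species = 60,
                     group_fractions = c(mammal = 0.55, reptile = 0.30,
                                         biped = 0.15),
                     log10_mass_range = c(-1.5, 3.5),
                     mass_slope = c(mammal = 1.00, reptile = 0.92,
                                    biped = 1.10),
                     mass_intercept = c(mammal = -1.28, reptile = -1.55,
                                        biped = -1.10),
                     lstar_slope = c(mammal = 0.29, reptile = 0.33,
                                     biped = 0.25),
                     lstar_intercept = c(mammal = -1.57, reptile = -1.50,
                                         biped = -1.60),
                     residual_sd = 0.08, lambda_true = 1,
                     muscles_per_species = 12,
                     pennation_range = c(0, 35),
                     cfl_fraction = 0.15, dirichlet_conc = 1,
                     limbs = c("fore", "hind")) {
  if (n_species < 4) stop("'n_species' must be >= 4")
  if (abs(sum(group_fractions) - 1) > 1e-8)
    stop("'group_fractions' must sum to 1")
  if (is.null(names(group_fractions)) ||
      !all(names(group_fractions) %in% c("mammal", "reptile", "biped")))
    stop("'group_fractions' must be named mammal/reptile/biped")
  if (log10_mass_range[1L] >= log10_mass_range[2L])
    stop("'log10_mass_range' must be increasing")
  if (residual_sd < 0) stop("'residual_sd' must be >= 0")
  if (lambda_true < 0 || lambda_true > 1)
    stop("'lambda_true' must lie in [0, 1]")
  if (pennation_range[1L] < 0 || pennation_range[2L] >= 90 ||
      pennation_range[1L] > pennation_range[2L])
    stop("'pennation_range' must be ordered within [0, 90)")
  if (cfl_fraction < 0 || cfl_fraction >= 1)
    stop("'cfl_fraction' must lie in [0, 1)")
  structure(list(n_species = n_species, group_fractions = group_fractions,
                 log10_mass_range = log10_mass_range,
                 mass_slope = mass_slope, mass_intercept = mass_intercept,
                 lstar_slope = lstar_slope,
                 lstar_intercept = lstar_intercept,
                 residual_sd = residual_sd, lambda_true = lambda_true,
                 muscles_per_species = muscles_per_species,
                 pennation_range = pennation_range,
                 cfl_fraction = cfl_fraction,
                 dirichlet_conc = dirichlet_conc, limbs = limbs),
            class = "sim_spec")
}

# integer group sizes by largest remainder, each >= 1
.group_sizes <- function(n, fractions) {
  raw <- fractions * n
  sizes <- floor(raw)
  while (sum(sizes) < n) {
    i <- which.max(raw - sizes)
    sizes[i] <- sizes[i] + 1L
  }
  if (any(sizes == 0L)) {
    for (i in which(sizes == 0L)) {
      j <- which.max(sizes)
      sizes[j] <- sizes[j] - 1L
      sizes[i] <- 1L
    }
  }
  stats::setNames(as.integer(sizes), names(fractions))
}

# one pure-birth clade rescaled to the given depth, returned without its
# stem edge; a single tip is a depth-0 "clade" (bare label)
.clade_newick <- function(n, depth, labels) {
  if (n == 1L) return(list(str = labels, depth = 0))
  phy <- ape::rphylo(n, birth = 1, death = 0)
  phy$tip.label <- labels
  d <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * depth / d
  list(str = sub(";$", "", ape::write.tree(phy, digits = 12)),
       depth = depth)
}

# append the stem edge that brings a clade up to the target depth
.with_stem <- function(part, target_depth) {
  sprintf("%s:%.10f", part$str, target_depth - part$depth)
}

#' Simulate an ultrametric tree with monophyletic group clades
#'
#' Builds a unit-depth ultrametric tree in which each group
#' (mammal/reptile/biped) forms a monophyletic clade: per-group pure-birth
#' subtrees are grafted onto a fixed backbone
#' \code{(group1, (group2, group3))}. Output is a deterministic function of
#' the seed.
#'
#' @param n_species Total number of tips (>= 4).
#' @param seed Integer seed.
#' @param group_fractions Named group proportions (see [sim_spec()]).
#' @return A list with \code{tree} (a \code{"phylo"}, depth 1) and
#'   \code{groups} (named character vector mapping tip label to group).
#' @export
sim_limb_tree <- function(n_species, seed,
                          group_fractions = c(mammal = 0.55,
                                              reptile = 0.30,
                                              biped = 0.15)) {
  if (n_species < 4) stop("'n_species' must be >= 4")
  set.seed(seed + 1L)
  sizes <- .group_sizes(n_species, group_fractions)
  grp <- names(sizes)
  labels <- lapply(seq_along(sizes), function(i)
    sprintf("%s_%02d", grp[i], seq_len(sizes[i])))
  clade_depth <- 0.7
  parts <- lapply(seq_along(sizes), function(i)
    .clade_newick(sizes[i], clade_depth, labels[[i]]))
  nwk <- if (length(parts) >= 3L) {
    sprintf("(%s,(%s,%s):%.1f);",
            .with_stem(parts[[1L]], 1),
            .with_stem(parts[[2L]], 0.9), .with_stem(parts[[3L]], 0.9), 0.1)
  } else if (length(parts) == 2L) {
    sprintf("(%s,%s);", .with_stem(parts[[1L]], 1),
            .with_stem(parts[[2L]], 1))
  } else {
    if (sizes[1L] == 1L) stop("a single-species tree is not supported")
    paste0(.clade_newick(sizes[1L], 1, labels[[1L]])$str, ";")
  }
  tree <- read_limb_tree(nwk)
  groups <- stats::setNames(rep(grp, sizes), normalize_taxon(unlist(labels)))
  list(tree = tree, groups = groups[tree$tip.label])
}

#' Simulate group-structured allometric traits on a tree
#'
#' Draws log10 body masses uniformly over the configured range and
#' generates log10 total limb muscle mass and log10 characteristic fascicle
#' length as group-specific linear allometries with residuals that are
#' multivariate normal with covariance
#' \code{residual_sd^2 * V(lambda_true)}, where V is the tree's
#' Brownian-motion covariance. With \code{residual_sd = 0} the traits lie
#' exactly on the group lines. Bipeds receive no forelimb rows.
#'
#' @param tree A unit-depth ultrametric \code{"phylo"} tree.
#' @param groups Named group vector over the tips (see [sim_limb_tree()]).
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns \code{species, group, limb, body_mass,
#'   sum_mass, L_star} (linear units).
#' @export
sim_allometric_traits <- function(tree, groups, spec, seed) {
  set.seed(seed + 2L)
  tips <- tree$tip.label
  n <- length(tips)
  g <- groups[tips]
  x <- stats::runif(n, spec$log10_mass_range[1L], spec$log10_mass_range[2L])
  V <- phylo_vcv(tree, taxa = tips, lambda = spec$lambda_true)
  U <- chol(V)
  draw_eps <- function() {
    if (spec$residual_sd == 0) return(numeric(n))
    spec$residual_sd * drop(crossprod(U, stats::rnorm(n)))
  }
  rows <- list()
  for (limb in spec$limbs) {
    keep <- if (limb == "fore") g != "biped" else rep(TRUE, n)
    log_m <- spec$mass_intercept[g] + spec$mass_slope[g] * x + draw_eps()
    log_l <- spec$lstar_intercept[g] + spec$lstar_slope[g] * x + draw_eps()
    rows[[limb]] <- data.frame(
      species = tips[keep], group = unname(g[keep]), limb = limb,
      body_mass = 10^x[keep], sum_mass = 10^log_m[keep],
      L_star = 10^log_l[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Decompose per-species limb totals into per-muscle records
#'
#' Splits each species x limb total muscle mass into individual muscle
#' records whose aggregation recovers the targets exactly: masses are a
#' Dirichlet partition of the total, pennation angles are drawn uniformly
#' in the configured range, and effective fascicle lengths
#' (\code{length / cos(pennation)}) are lognormal multipliers rescaled by a
#' closed-form constant so that the mass-weighted harmonic mean equals the
#' target characteristic fascicle length. In reptile hindlimbs one muscle
#' is marked as the caudofemoralis longus (CFL) holding a fixed fraction of
#' the total mass.
#'
#' @param traits A species table from [sim_allometric_traits()].
#' @param spec A [sim_spec()].
#' @param seed Integer seed.
#' @return A muscle table in the package's CSV dialect (see
#'   [read_muscle_table()]).
#' @export
sim_muscle_table <- function(traits, spec, seed) {
  set.seed(seed + 3L)
  n_m <- spec$muscles_per_species
  rows <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    is_cfl <- rep(FALSE, n_m)
    if (tr$group == "reptile" && tr$limb == "hind" &&
        spec$cfl_fraction > 0) {
      w <- stats::rgamma(n_m - 1L, spec$dirichlet_conc)
      mass <- c(tr$sum_mass * spec$cfl_fraction,
                tr$sum_mass * (1 - spec$cfl_fraction) * w / sum(w))
      is_cfl[1L] <- TRUE
    } else {
      w <- stats::rgamma(n_m, spec$dirichlet_conc)
      mass <- tr$sum_mass * w / sum(w)
    }
    alpha <- stats::runif(n_m, spec$pennation_range[1L],
                          spec$pennation_range[2L])
    v <- 10^stats::rnorm(n_m, 0, 0.15)
    # exact solve: effective lengths c*v give the target harmonic mean
    cc <- tr$L_star * sum(mass / v) / tr$sum_mass
    ell <- cc * v * cos(alpha * pi / 180)
    name <- sprintf("m%02d", seq_len(n_m))
    name[is_cfl] <- "CFL"
    compartment <- ifelse(stats::runif(n_m) < 0.6, "proximal", "distal")
    compartment[is_cfl] <- "proximal"
    rows[[i]] <- data.frame(
      species = tr$species, group = tr$group, limb = tr$limb,
      compartment = compartment, muscle = name, mass = mass,
      fascicle_length = ell, pennation = alpha, is_cfl = is_cfl,
      body_mass = tr$body_mass, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  .validate_muscle_df(out)
}

#' Simulate a complete synthetic whole-limb dataset
#'
#' Chains [sim_limb_tree()], [sim_allometric_traits()] and
#' [sim_muscle_table()] under sub-generator seed streams (tree, traits and
#' muscles use distinct streams derived from \code{seed}, so enlarging one
#' stage never perturbs the draws of another). The result is a drop-in
#' bundle for the full analysis: a tree plus a muscle table in the
#' package's CSV dialect.
#'
#' @param spec A [sim_spec()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with \code{tree}, \code{groups}, \code{species} (trait
#'   table) and \code{muscles} (per-muscle table).
#' @export
sim_limb_dataset <- function(spec = sim_spec(), seed = 1) {
  tt <- sim_limb_tree(spec$n_species, seed, spec$group_fractions)
  traits <- sim_allometric_traits(tt$tree, tt$groups, spec, seed)
  muscles <- sim_muscle_table(traits, spec, seed)
  list(tree = tt$tree, groups = tt$groups, species = traits,
       muscles = muscles)
}

#' Noiseless dataset under exact geometric similarity
#'
#' Constructs a synthetic dataset in which every species is a scaled copy
#' of the same limb: muscle masses are proportional to body mass, fascicle
#' lengths to body mass^(1/3), and pennation is constant. Every anatomical
#' comparison's fitted log-log slope then equals its isometric expectation
#' exactly (1, -1/3, 1/3 and 2/3), for any residual covariance, making the
#' fixture a machine-precision oracle for the whole fitting pipeline.
#'
#' @param n_species Number of species (>= 4).
#' @param seed Integer seed (shapes the tree; the traits are
#'   deterministic).
#' @param mass_fraction Named fraction of body mass in limb muscle per
#'   limb.
#' @param n_muscles Muscles per limb.
#' @param pennation Constant pennation angle in degrees.
#' @return A list with \code{tree}, \code{groups} and \code{muscles}.
#' @examples
#' d <- isometric_fixture(12, seed = 42)
#' agg <- aggregate_limbs(d$muscles)
#' @export
isometric_fixture <- function(n_species, seed,
                              mass_fraction = c(fore = 0.04, hind = 0.06),
                              n_muscles = 10, pennation = 20) {
  tt <- sim_limb_tree(n_species, seed)
  tips <- tt$tree$tip.label
  n <- length(tips)
  x <- seq(-1.5, 3.5, length.out = n)          # log10 body mass, kg
  body_mass <- 10^x
  w <- seq_len(n_muscles) / sum(seq_len(n_muscles))   # fixed mass split
  l0 <- 0.03 * (0.5 + seq_len(n_muscles) / n_muscles) # length coefficients
  compartment <- rep(c("proximal", "distal"),
                     c(ceiling(n_muscles * 0.6), n_muscles -
                         ceiling(n_muscles * 0.6)))
  rows <- list()
  for (limb in names(mass_fraction)) {
    for (i in seq_len(n)) {
      if (limb == "fore" && tt$groups[tips[i]] == "biped") next
      M <- mass_fraction[[limb]] * body_mass[i]
      rows[[length(rows) + 1L]] <- data.frame(
        species = tips[i], group = unname(tt$groups[tips[i]]), limb = limb,
        compartment = compartment, muscle = sprintf("m%02d", seq_len(n_muscles)),
        mass = M * w, fascicle_length = l0 * body_mass[i]^(1 / 3),
        pennation = pennation, is_cfl = FALSE, body_mass = body_mass[i],
        stringsAsFactors = FALSE)
    }
  }
  muscles <- do.call(rbind, rows)
  rownames(muscles) <- NULL
  list(tree = tt$tree, groups = tt$groups,
       muscles = .validate_muscle_df(muscles))
}
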