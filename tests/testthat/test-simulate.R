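test_that("generators are pure functions of the seed", {
  t1 <- sim_limb_tree(30, seed = 5)
  t2 <- sim_limb_tree(30, seed = 5)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$groups, t2$groups)
  d1 <- sim_limb_dataset(sim_spec(n_species = 15), seed = 8)
  d2 <- sim_limb_dataset(sim_spec(n_species = 15), seed = 8)
  expect_identical(d1$muscles, d2$muscles)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_muscle_table(d1$muscles, f1)
  write_muscle_table(d2$muscles, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical CSVs
  expect_false(identical(ape::write.tree(sim_limb_tree(30, seed = 6)$tree),
                         ape::write.tree(t1$tree)))
})

test_that("simulated trees are ultrametric with unit depth and monophyletic groups", {
  tt <- sim_limb_tree(50, seed = 3)
  expect_equal(ape::Ntip(tt$tree), 50L)
  depths <- ape::node.depth.edgelength(tt$tree)[1:50]
  expect_true(all(abs(depths - 1) < 1e-9))
  for (g in unique(tt$groups)) {
    tips <- names(tt$groups)[tt$groups == g]
    mrca <- ape::getMRCA(tt$tree, tips)
    clade <- ape::extract.clade(tt$tree, mrca)$tip.label
    expect_setequal(clade, tips)  # MRCA tip set equals the group
  }
})

test_that("noiseless traits lie exactly on the group lines", {
  spec <- sim_spec(n_species = 20, residual_sd = 0)
  d <- sim_limb_dataset(spec, seed = 4)
  hind <- d$species[d$species$limb == "hind", ]
  for (g in unique(hind$group)) {
    xy <- hind[hind$group == g, ]
    fit <- pgls(y ~ x, tree = d$tree,
                data = data.frame(species = xy$species,
                                  x = log10(xy$body_mass),
                                  y = log10(xy$sum_mass)))
    expect_equal(unname(coef(fit)[2]), unname(spec$mass_slope[g]),
                 tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), unname(spec$mass_intercept[g]),
                 tolerance = 1e-8)
  }
})

test_that("simulated residuals have the lambda-scaled tree covariance", {
  spec <- sim_spec(n_species = 6, residual_sd = 0.1, lambda_true = 0.6,
                   group_fractions = c(mammal = 0.5, reptile = 0.3,
                                       biped = 0.2),
                   limbs = "hind")
  tt <- sim_limb_tree(6, seed = 21)
  Vtrue <- 0.1^2 * unclass(phylo_vcv(tt$tree, taxa = tt$tree$tip.label,
                                     lambda = 0.6))
  reps <- vapply(1:12000, function(i) {
    tr <- sim_allometric_traits(tt$tree, tt$groups, spec, seed = 10000 + i)
    tr <- tr[match(tt$tree$tip.label, tr$species), ]
    log10(tr$sum_mass) -
      (spec$mass_intercept[tr$group] + spec$mass_slope[tr$group] *
         log10(tr$body_mass))
  }, numeric(6))
  emp <- stats::cov(t(reps))
  expect_lt(max(abs(emp - Vtrue)), 0.05 * max(Vtrue))
})

test_that("muscle decomposition recovers the species totals exactly", {
  spec <- sim_spec(n_species = 18)
  d <- sim_limb_dataset(spec, seed = 6)
  agg <- aggregate_limbs(d$muscles)
  m <- merge(agg, d$species, by = c("species", "limb"))
  expect_lt(max(abs(m$sum_mass.x - m$sum_mass.y) / m$sum_mass.y), 1e-9)
  expect_lt(max(abs(m$L_star.x - m$L_star.y) / m$L_star.y), 1e-6)
  # pennation stays inside the configured range
  expect_true(all(d$muscles$pennation >= spec$pennation_range[1] &
                    d$muscles$pennation <= spec$pennation_range[2]))
})

test_that("the CFL carries its configured fraction of reptile hindlimb mass", {
  spec <- sim_spec(n_species = 18, cfl_fraction = 0.15)
  d <- sim_limb_dataset(spec, seed = 7)
  hind <- d$muscles[d$muscles$limb == "hind", ]
  rep_hind <- hind[hind$group == "reptile", ]
  expect_true(all(tapply(rep_hind$is_cfl, rep_hind$species, sum) == 1))
  expect_false(any(hind$is_cfl[hind$group != "reptile"]))
  with_cfl <- aggregate_limbs(hind)
  no_cfl <- aggregate_limbs(hind, exclude_cfl = TRUE)
  drop_frac <- 1 - no_cfl$sum_mass / with_cfl$sum_mass
  is_rep <- with_cfl$group == "reptile"
  expect_equal(drop_frac[is_rep], rep(0.15, sum(is_rep)), tolerance = 1e-9)
  expect_equal(drop_frac[!is_rep], rep(0, sum(!is_rep)))
})

test_that("the geometric-similarity fixture forces every comparison onto its isometric slope", {
  d <- isometric_fixture(20, seed = 11)
  agg <- aggregate_limbs(d$muscles)
  hind <- agg[agg$limb == "hind", ]
  for (cmp in limb_comparisons()) {
    xy <- comparison_xy(hind, cmp, quiet = TRUE)
    fit <- pgls(y ~ x, data = xy, tree = d$tree)
    expect_equal(unname(coef(fit)[2]), isometric_slope(cmp),
                 tolerance = 1e-8, label = cmp)
  }
})

test_that("group-wise slope recovery works at realistic noise and full phylogenetic signal", {
  spec <- sim_spec(n_species = 150, residual_sd = 0.08, lambda_true = 1,
                   mass_slope = c(mammal = 1.0, reptile = 0.9, biped = 0.75),
                   limbs = "hind")
  hits <- unlist(lapply(1:10, function(seed) {
    d <- sim_limb_dataset(spec, seed = 3000 + seed)
    hind <- d$species[d$species$limb == "hind", ]
    vapply(c("mammal", "reptile", "biped"), function(g) {
      xy <- hind[hind$group == g, ]
      fit <- pgls(y ~ x, tree = d$tree,
                  data = data.frame(species = xy$species,
                                    x = log10(xy$body_mass),
                                    y = log10(xy$sum_mass)))
      abs(unname(coef(fit)[2]) - spec$mass_slope[[g]]) <= 0.05
    }, logical(1))
  }))
  expect_gte(mean(hits), 0.9)
})
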