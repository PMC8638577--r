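test_that("GLS with identity covariance reproduces ordinary least squares", {
  set.seed(21)
  n <- 25
  sp <- sprintf("t%02d", 1:n)
  d <- data.frame(species = sp, x = runif(n, -1, 3))
  d$y <- 0.5 + 0.8 * d$x + rnorm(n, 0, 0.1)
  fit <- pgls(y ~ x, data = d, V = identity_vcv(sp), lambda = 0)
  ref <- lm(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(coef(summary(ref))[, 2]),
               tolerance = 1e-10)
  expect_equal(unname(fit$ci), unname(confint(ref)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$sigma2, summary(ref)$sigma^2, tolerance = 1e-10)
})

test_that("GLS coefficients match a brute-force normal-equations oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- rand_tree(15, seed)
    V <- phylo_vcv(tr, taxa = tr$tip.label, lambda = runif(1))
    x <- rnorm(15)
    y <- 1 + 0.6 * x + drop(crossprod(chol(V), rnorm(15))) * 0.2
    d <- data.frame(species = tr$tip.label, x = x, y = y)
    fit <- pgls(y ~ x, data = d, V = unclass(V), lambda = 1)
    oracle <- gls_normal_eq_oracle(cbind(1, x), y, unclass(V))
    expect_equal(unname(coef(fit)), unname(drop(oracle)), tolerance = 1e-8)
  }
})

test_that("the lambda = 0 path equals OLS inference on many random problems", {
  for (seed in 1:50) {
    set.seed(100 + seed)
    n <- sample(10:40, 1)
    tr <- rand_tree(n, seed)  # unit depth, so lambda = 0 gives the identity
    d <- data.frame(species = tr$tip.label, x = runif(n, -2, 2))
    d$y <- rnorm(1) + rnorm(1) * d$x + rnorm(n, 0, 0.3)
    fit <- pgls(y ~ x, data = d, tree = tr, lambda = 0)
    ref <- lm(y ~ x, d)
    expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(coef(summary(ref))[, 2]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$ci), unname(confint(ref)), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("noiseless linear data recover the slope exactly with the smallest-lambda tie-break", {
  tr <- rand_tree(30, 8)
  d <- data.frame(species = tr$tip.label, x = seq(-1, 4, length.out = 30))
  d$y <- -1.2 + 0.75 * d$x
  fit <- pgls(y ~ x, data = d, tree = tr)
  expect_equal(unname(coef(fit)), c(-1.2, 0.75), tolerance = 1e-8)
  expect_identical(fit$lambda, 0)
  expect_true(fit$degenerate)
  # and at any fixed lambda too
  for (lam in c(0, 0.5, 1))
    expect_equal(unname(coef(pgls(y ~ x, data = d, tree = tr,
                                  lambda = lam))[2]), 0.75,
                 tolerance = 1e-8)
})

test_that("the profiled likelihood at lambda-hat dominates a fine grid", {
  set.seed(31)
  tr <- rand_tree(40, 31)
  V <- phylo_vcv(tr, taxa = tr$tip.label, lambda = 0.6)
  d <- data.frame(species = tr$tip.label, x = runif(40, -1, 3))
  d$y <- 0.3 + 0.9 * d$x + 0.2 * drop(crossprod(chol(V), rnorm(40)))
  fit <- pgls(y ~ x, data = d, tree = tr)
  grid_ll <- vapply(seq(0, 1, length.out = 101), function(lam)
    pgls(y ~ x, data = d, tree = tr, lambda = lam)$logLik, numeric(1))
  expect_gte(fit$logLik, max(grid_ll) - 1e-6)
})

test_that("slopes are invariant to rescaling the covariance matrix", {
  set.seed(41)
  tr <- rand_tree(25, 41)
  V <- phylo_vcv(tr, taxa = tr$tip.label)
  d <- data.frame(species = tr$tip.label, x = runif(25))
  d$y <- 1 + 2 * d$x + 0.3 * drop(crossprod(chol(V), rnorm(25)))
  base <- pgls(y ~ x, data = d, V = unclass(V), lambda = 0.8)
  for (k in c(0.1, 10)) {
    fk <- pgls(y ~ x, data = d, V = unclass(V) * k, lambda = 0.8)
    expect_equal(coef(fk), coef(base), tolerance = 1e-9)
    expect_equal(fk$se, base$se, tolerance = 1e-9)
  }
})

test_that("ML lambda and coefficients agree with an independent GLS implementation", {
  set.seed(10)
  tt <- sim_limb_tree(80, seed = 5)
  V <- phylo_vcv(tt$tree, lambda = 0.7)
  x <- runif(80, -1, 3)
  y <- 0.2 + 0.8 * x + 0.15 * drop(crossprod(chol(V), rnorm(80)))
  d <- data.frame(species = tt$tree$tip.label, x = x, y = y)
  fit <- pgls(y ~ x, data = d, tree = tt$tree)
  rownames(d) <- d$species
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, phy = tt$tree,
                                               form = ~species),
                   method = "ML")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(fit$lambda, unname(ref$modelStruct$corStruct[1]),
               tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("simulated-lambda recovery: no phylogenetic signal is detected as lambda near 0", {
  lam_hat <- vapply(1:20, function(seed) {
    set.seed(1000 + seed)
    tr <- rand_tree(200, seed)
    d <- data.frame(species = tr$tip.label, x = runif(200, -1, 3))
    d$y <- 0.5 + 0.9 * d$x + rnorm(200, 0, 0.1)  # iid residuals: lambda 0
    pgls(y ~ x, data = d, tree = tr)$lambda
  }, numeric(1))
  expect_lt(median(lam_hat), 0.15)
  expect_gte(mean(lam_hat < 0.15), 0.9)
})

test_that("slope CIs achieve nominal coverage under a lambda = 1 generating process", {
  n <- 200
  tr <- rand_tree(n, 77)
  V <- phylo_vcv(tr, taxa = tr$tip.label)
  U <- chol(V)
  covered <- vapply(1:50, function(seed) {
    set.seed(2000 + seed)
    d <- data.frame(species = tr$tip.label, x = runif(n, -1, 3))
    d$y <- 0.1 + 0.75 * d$x + 0.15 * drop(crossprod(U, rnorm(n)))
    ci <- pgls(y ~ x, data = d, V = unclass(V))$ci[2, ]
    ci[["lower"]] <= 0.75 && 0.75 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("isometry verdicts follow the CI classification rule", {
  fake <- function(lo, hi) structure(
    list(ci = matrix(c(NA, lo, NA, hi), 2, 2,
                     dimnames = list(NULL, c("lower", "upper"))),
         coefficients = c(0, (lo + hi) / 2), level = 0.95),
    class = "pgls")
  expect_equal(assess_isometry(fake(0.9, 1.1), 1)$verdict,
               "isometry_not_rejected")
  expect_equal(assess_isometry(fake(0.70, 0.95), 1)$verdict,
               "negative_allometry")
  expect_equal(assess_isometry(fake(-0.30, -0.10), -1 / 3)$verdict,
               "positive_allometry")
})

test_that("rescaling the stress constant leaves fitted strength exponents unchanged", {
  d <- sim_limb_dataset(sim_spec(n_species = 25), seed = 9)
  hind <- d$muscles[d$muscles$limb == "hind", ]
  slope_at <- function(k) {
    agg <- aggregate_limbs(hind, constants = limb_constants(stress = 3e5 * k))
    xy <- comparison_xy(agg, "fmax_total", quiet = TRUE)
    fit <- pgls(y ~ x, data = xy, tree = d$tree)
    c(slope = unname(coef(fit)[2]), int = unname(coef(fit)[1]))
  }
  s1 <- slope_at(1); s2 <- slope_at(4)
  expect_equal(s1[["slope"]], s2[["slope"]], tolerance = 1e-9)
  expect_equal(s2[["int"]] - s1[["int"]], log10(4), tolerance = 1e-9)
})
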