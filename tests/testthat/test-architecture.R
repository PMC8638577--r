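test_that("pcsa matches hand-computed values and rejects invalid inputs", {
  expect_equal(pcsa(0.053, 0, 0.05), 1e-3)
  expect_equal(pcsa(0.053, 60, 0.05), 5e-4)  # cos 60 halves it
  expect_equal(pcsa(0, 20, 0.02), 0)
  # independent one-line oracle on random inputs
  set.seed(11)
  for (i in 1:20) {
    m <- runif(1, 1e-4, 5)
    a <- runif(1, 0, 89)
    l <- runif(1, 1e-3, 0.5)
    rho <- runif(1, 900, 1200)
    expect_equal(pcsa(m, a, l, rho), m * cos(a * pi / 180) / (rho * l),
                 tolerance = 1e-12)
  }
  expect_error(pcsa(0.1, 95, 0.05), "pennation")
  expect_error(pcsa(0.1, 10, -0.05), "fascicle")
  expect_error(pcsa(0.1, 10, 0.05, muscle = "biceps", fascicle_length = 0),
               "biceps")
})

test_that("fmax_star evaluates the body-weight normalization and scales as expected", {
  expect_equal(fmax_star(1e-3, 10, 3e5, 9.81), 300 / 98.1)  # ~3.058 BW
  expect_equal(fmax_star(0, 7), 0)
  a <- fmax_star(2.3e-4, 5)
  expect_equal(fmax_star(2.3e-4, 10), a / 2)       # doubling body mass halves it
  expect_equal(fmax_star(2.3e-4, 5, stress = 6e5), 2 * a)  # exact in stress
  expect_error(fmax_star(1e-3, -1), "body_mass")
})

test_that("characteristic fascicle length is the mass- and pennation-weighted harmonic mean", {
  expect_equal(char_fascicle_length(0.2, 0, 0.04), 0.04)
  expect_equal(char_fascicle_length(0.2, 60, 0.04), 0.08)
  # two equal-mass unpennated muscles: plain harmonic mean
  L1 <- 0.03; L2 <- 0.09
  expect_equal(char_fascicle_length(c(1, 1), c(0, 0), c(L1, L2)),
               2 / (1 / L1 + 1 / L2))
  expect_error(char_fascicle_length(numeric(0), numeric(0), numeric(0)))
  # merging two records of identical length/pennation into one of summed
  # mass leaves L* unchanged
  set.seed(4)
  m <- runif(5); a <- runif(5, 0, 40); l <- runif(5, 0.01, 0.1)
  merged <- char_fascicle_length(c(m[1] + m[2], m[3:5]),
                                 c(a[1], a[3:5]), c(l[1], l[3:5]))
  a[2] <- a[1]; l[2] <- l[1]
  expect_equal(char_fascicle_length(m, a, l), merged, tolerance = 1e-12)
})

test_that("isometric expectations are the geometric-similarity exponents", {
  expect_identical(isometric_slope("mass_v_body"), 1)
  expect_identical(isometric_slope("fmax_mean"), -1 / 3)
  expect_identical(isometric_slope("fmax_median"), -1 / 3)
  expect_identical(isometric_slope("fmax_total"), -1 / 3)
  expect_identical(isometric_slope("Lstar"), 1 / 3)
  expect_identical(isometric_slope("pcsa_v_mass"), 2 / 3)
  expect_error(isometric_slope("nope"))
})

make_profile <- function() {
  data.frame(
    species = "sp A", group = "reptile", limb = "hind",
    compartment = c("proximal", "proximal", "distal", "distal"),
    muscle = c("CFL", "m1", "m2", "m3"),
    mass = c(0.4, 0.3, 0.2, 0.1),
    fascicle_length = c(0.08, 0.05, 0.03, 0.02),
    pennation = c(0, 10, 20, 30),
    is_cfl = c(TRUE, FALSE, FALSE, FALSE),
    body_mass = 12, stringsAsFactors = FALSE)
}

test_that("aggregation respects scope partition, CFL exclusion and the median convention", {
  d <- make_profile()
  whole <- aggregate_limbs(d)
  prox <- aggregate_limbs(d, scope = "proximal")
  dist <- aggregate_limbs(d, scope = "distal")
  expect_equal(prox$sum_mass + dist$sum_mass, whole$sum_mass)
  expect_equal(prox$sum_pcsa + dist$sum_pcsa, whole$sum_pcsa)
  expect_equal(prox$n_muscles + dist$n_muscles, whole$n_muscles)
  nocfl <- aggregate_limbs(d, exclude_cfl = TRUE)
  expect_equal(whole$sum_mass - nocfl$sum_mass, 0.4)
  # odd-count median of PCSAs {1, 2, 10} x 1e-4
  d3 <- data.frame(species = "s", group = "mammal", limb = "fore",
                   compartment = "proximal", muscle = c("a", "b", "c"),
                   mass = 1060 * 0.05 * c(1e-4, 2e-4, 1e-3),
                   fascicle_length = 0.05, pennation = 0, is_cfl = FALSE,
                   body_mass = 3)
  expect_equal(aggregate_limbs(d3)$median_pcsa, 2e-4)
  # L* identity against the direct formula
  expect_equal(whole$L_star, whole$sum_mass / (1060 * whole$sum_pcsa))
})

test_that("mass-only species aggregate to total mass with PCSA fields unavailable", {
  d <- make_profile()
  mo <- data.frame(species = "sp B", group = "mammal", limb = "hind",
                   compartment = NA, muscle = "all", mass = 0.9,
                   fascicle_length = NA_real_, pennation = NA_real_,
                   is_cfl = FALSE, body_mass = 20)
  agg <- aggregate_limbs(rbind(d, mo))
  b <- agg[agg$species == "sp B", ]
  expect_true(b$mass_only)
  expect_equal(b$sum_mass, 0.9)
  expect_true(all(is.na(c(b$sum_pcsa, b$fmax_mean, b$L_star))))
  # participates in the mass comparison, skipped elsewhere with a notice
  expect_true("sp B" %in% comparison_xy(agg, "mass_v_body")$species)
  expect_message(xy <- comparison_xy(agg, "fmax_mean"), "sp B")
  expect_false("sp B" %in% xy$species)
})

test_that("the muscle-table CSV dialect round-trips and converts units", {
  d <- isometric_fixture(6, seed = 2)$muscles
  tf <- tempfile(fileext = ".csv")
  write_muscle_table(d, tf)
  back <- read_muscle_table(tf)
  expect_equal(back$mass, d$mass, tolerance = 1e-12)
  expect_equal(back$fascicle_length, d$fascicle_length, tolerance = 1e-12)
  # g/mm declarations convert on read
  d2 <- d
  d2$mass <- d2$mass * 1e3; d2$body_mass <- d2$body_mass * 1e3
  d2$fascicle_length <- d2$fascicle_length * 1e3
  tf2 <- tempfile(fileext = ".csv")
  utils::write.csv(d2, tf2, row.names = FALSE)
  back2 <- read_muscle_table(tf2, mass_unit = "g", length_unit = "mm")
  expect_equal(back2$mass, d$mass, tolerance = 1e-9)
  expect_equal(back2$fascicle_length, d$fascicle_length, tolerance = 1e-9)
  # strict header validation
  d3 <- d; names(d3)[names(d3) == "pennation"] <- "penn"
  tf3 <- tempfile(fileext = ".csv")
  utils::write.csv(d3, tf3, row.names = FALSE)
  expect_error(read_muscle_table(tf3), "pennation")
})
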