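test_that("maturity classification uses an inclusive 14-cm threshold", {
  p <- reproduction_params()
  m <- classify_maturity(c(14, 22), p)
  expect_equal(m$n_mature, 2)
  expect_equal(m$mean_mature_diameter_cm, 18)

  below <- classify_maturity(c(2, 5, 13.9), p)
  expect_equal(below$prop_mature, 0)
  expect_true(is.na(below$mean_mature_diameter_cm))

  # a census like the back reef 2014: 19 of 191 colonies mature
  d <- c(rep(5, 172), rep(22.3, 19))
  m191 <- classify_maturity(d, p)
  expect_equal(m191$n_colonies, 191)
  expect_equal(m191$prop_mature, 19 / 191)
  expect_equal(round(m191$prop_mature, 2), 0.10)

  expect_error(classify_maturity(numeric(0), p), "at least one colony")
  expect_error(classify_maturity(c(5, -1), p), "positive")
})

test_that("tissue area evaluates the power-law calibration", {
  expect_equal(tissue_area(1), 2.493)
  # direct power-law evaluation oracle
  expect_equal(tissue_area(22.3), 2.493 * 22.3^2.312)
  expect_equal(tissue_area(22.3), 3266, tolerance = 1e-3)
  expect_equal(tissue_area(17.1), 1768, tolerance = 1e-3)
  expect_error(tissue_area(0), "positive")
  expect_error(tissue_area(-2), "positive")
  # strictly increasing in diameter
  d <- seq(0.5, 40, by = 0.5)
  expect_true(all(diff(tissue_area(d)) > 0))
})

test_that("log-log regression recovers the allometry", {
  a <- 2.493; b <- 2.312
  d <- c(5, 10, 15, 20, 25, 30)
  exact <- fit_allometry(d, a * d^b)
  expect_equal(exact$coefficient_a, a, tolerance = 1e-9)
  expect_equal(exact$exponent_b, b, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1)

  # two exact points plus their (log-space) midpoint give the same model
  d3 <- c(5, sqrt(5 * 30), 30)
  three <- fit_allometry(d3, a * d3^b)
  expect_equal(three$exponent_b, exact$exponent_b, tolerance = 1e-9)

  # lognormal noise: the true exponent lies in the fitted 95% interval
  set.seed(77)
  dn <- stats::runif(50, 4, 30)
  area <- a * dn^b * stats::rlnorm(50, 0, 0.1)
  noisy <- fit_allometry(dn, area)
  expect_gt(b, noisy$b_ci[1])
  expect_lt(b, noisy$b_ci[2])
  expect_lt(noisy$r_squared, 1)

  expect_error(fit_allometry(c(1, 2), c(1, 2)), "3 calibration pairs")
  expect_error(fit_allometry(c(1, 2, -3), c(1, 2, 3)), "positive")
})

test_that("fecundity pooling converts per-polyp values and matches brute force", {
  pooled <- pooled_fecundity(moorea_fecundity_studies(), 66)
  converted <- c(7300, 63 * 66, 114 * 66)
  expect_equal(pooled$mean, mean(converted))
  expect_equal(pooled$sd, stats::sd(converted))
  expect_equal(pooled$n_studies, 3)

  # brute-force equivalence on an arbitrary study list
  studies <- tibble::tibble(
    study = letters[1:4], value = c(100, 5000, 42, 9000),
    unit = c("eggs_per_polyp", "eggs_per_cm2_per_yr", "eggs_per_polyp",
             "eggs_per_cm2_per_yr")
  )
  pl <- pooled_fecundity(studies, 50)
  manual <- c(100 * 50, 5000, 42 * 50, 9000)
  expect_equal(pl$mean, sum(manual) / 4)
  expect_equal(pl$sd, sqrt(sum((manual - mean(manual))^2) / 3))

  # degenerate spreads
  same <- tibble::tibble(study = c("x", "y", "z"), value = 63,
                         unit = "eggs_per_polyp")
  expect_equal(pooled_fecundity(same)$sd, 0)
  expect_warning(one <- pooled_fecundity(same[1, ]), "single")
  expect_equal(one$mean, 63 * 66)
  expect_true(is.na(one$sd))

  bad <- tibble::tibble(study = "q", value = 10, unit = "eggs_per_larva")
  expect_error(pooled_fecundity(bad), "unknown fecundity unit")
})

test_that("fertilization pooling summarises raw fractions", {
  expect_equal(pooled_fertilization(c(0, 1))$mean, 0.5)
  expect_equal(pooled_fertilization(rep(0.3, 5))$sd, 0)
  obs <- c(0.05, 0.1, 0.3)
  pl <- pooled_fertilization(obs)
  expect_equal(pl$mean, mean(obs))
  expect_equal(pl$sd, stats::sd(obs))
  expect_error(pooled_fertilization(c(0.5, 1.2)), "\\[0, 1\\]")
  # the published pooled values pass through as a given constant
  given <- pooled_distribution(0.15, 0.21, 2, "fraction")
  expect_equal(given$mean, 0.15)
  expect_equal(given$sd, 0.21)
})

test_that("egg output chains scale with fecundity and population structure", {
  p <- reproduction_params()
  # homogeneity: doubling mean fecundity doubles a colony's output
  p2 <- p
  p2$fecundity <- pooled_distribution(2 * p$fecundity$mean, p$fecundity$sd, 3)
  expect_equal(colony_egg_output(22.3, p2), 2 * colony_egg_output(22.3, p))

  # population output is abundance x mature fraction x representative colony
  eggs <- population_egg_output(
    1.466e7, list(prop_mature = 0.10, mean_mature_diameter_cm = 22.3), p
  )
  expect_equal(eggs, 1.466e7 * 0.10 * colony_egg_output(22.3, p))

  expect_equal(population_egg_output(
    1.1e8, list(prop_mature = 0, mean_mature_diameter_cm = NA_real_), p
  ), 0)
  expect_equal(population_egg_output(
    0, list(prop_mature = 0.2, mean_mature_diameter_cm = 20), p
  ), 0)
  expect_error(population_egg_output(
    10, list(prop_mature = 0.2, mean_mature_diameter_cm = NA_real_), p
  ), "undefined")

  # integrating over a census of identical mature colonies matches the
  # representative-colony form
  d <- rep(22.3, 10)
  m <- classify_maturity(d, p)
  expect_equal(
    population_egg_output(5e6, m, p, method = "integrate", diameters = d),
    population_egg_output(5e6, m, p)
  )

  # zygotes are eggs times mean fertilization success
  expect_equal(zygote_production(1e10, p), 0.15e10)
  expect_equal(zygote_production(0, p), 0)
  p1 <- p
  p1$fertilization <- pooled_distribution(1, 0, 1, "fraction")
  expect_equal(zygote_production(5.3e11, p1), 5.3e11)
  expect_error(zygote_production(-1, p), "non-negative")
})
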