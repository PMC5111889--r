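test_that("generators are seed-reproducible and respect degenerate truths", {
  sc <- small_scenario(seed = 21)
  expect_identical(simulate_tiles(sc), simulate_tiles(sc))
  expect_identical(simulate_quadrats(sc), simulate_quadrats(sc))
  expect_identical(simulate_survey(sc)$points, simulate_survey(sc)$points)

  # zero true density means zero counts everywhere
  sc0 <- small_scenario(seed = 4)
  sc0$cells$recruit_early <- 0
  sc0$cells$recruit_late <- 0
  expect_true(all(simulate_tiles(sc0)$recruit_count == 0))

  # a degenerate size distribution returns exactly the median diameter
  scd <- small_scenario(seed = 4)
  scd$cells$size_meanlog <- log(22.3)
  scd$cells$size_sdlog <- 0
  sizes <- simulate_colony_sizes(scd)
  expect_true(all(abs(sizes$diameter_cm - 22.3) < 1e-12))

  # no colonies: empty with a warning
  scn <- small_scenario(seed = 4)
  scn$cells <- scn$cells[1, ]
  scn$cells$n_colonies <- 0L
  expect_warning(empty <- simulate_colony_sizes(scn), "no colonies")
  expect_equal(nrow(empty), 0)

  # scenario validation
  expect_error(simulation_scenario(cells = dplyr::mutate(
    small_scenario()$cells, juvenile = colony + 1
  )), "juvenile density")
  expect_error(
    simulation_scenario(effort = list(n_sites = 0, n_tiles = 5,
                                      n_quadrats = 5, n_images = 5)),
    "effort"
  )
})

test_that("per-quadrat life-stage nesting holds by construction", {
  q <- simulate_quadrats(small_scenario(seed = 9))
  wide <- tidyr::pivot_wider(q, names_from = "life_stage",
                             values_from = "colony_count")
  expect_true(all(wide$juvenile <= wide$all))
})

test_that("Poisson and multinomial surveys recover their truths within 3 SE", {
  # recruit density recovery at the 2010 outer-reef magnitude
  sc <- small_scenario(seed = 31)
  sc$effort$n_tiles <- 100
  tiles <- simulate_tiles(sc)
  est <- annual_recruit_density(tiles)
  truth <- sc$cells$recruit_early + sc$cells$recruit_late
  for (i in seq_len(nrow(est))) {
    cell <- sc$cells[sc$cells$habitat == est$habitat[i], ]
    n_tiles_per_period <- 100 * sc$effort$n_sites *
      length(sc$depths[[est$habitat[i]]])
    se <- sqrt((cell$recruit_early + cell$recruit_late) / n_tiles_per_period)
    expect_lt(abs(est$density[i] - (cell$recruit_early + cell$recruit_late)),
              3 * se)
  }

  # quadrat density recovery at the back-reef 2014/15 magnitude
  scq <- small_scenario(seed = 32)
  scq$cells <- tibble::tibble(
    habitat = "back_reef", year = 2015L, recruit_early = 0, recruit_late = 0,
    juvenile = 0.3, colony = 0.80, size_meanlog = log(8), size_sdlog = 0.5,
    n_colonies = 10L
  )
  scq$effort$n_quadrats <- 150
  qd <- mean_quadrat_density(simulate_quadrats(scq))
  all_row <- qd[qd$life_stage == "all_colonies", ]
  se_all <- sqrt(0.80 / (150 * 2))
  expect_lt(abs(all_row$density - 0.80), 3 * se_all)

  # cover recovery at the 39% coral magnitude
  scc <- small_scenario(seed = 33)
  scc$effort$n_images <- 20
  s <- summarize_cover(per_image_cover(simulate_point_counts(scc),
                                       scc$sampler, "points"))
  coral <- s[s$category == "coral" & s$habitat == "outer_reef", ]
  for (i in seq_len(nrow(coral))) {
    expect_lt(abs(coral$mean_cover[i] - 39), 3 * max(coral$se_cover[i], 0.5))
  }

  # lognormal maturity fraction matches the closed-form tail probability
  scs <- small_scenario(seed = 34)
  scs$cells <- scs$cells[1, ]
  scs$cells$n_colonies <- 4000L
  scs$cells$size_meanlog <- log(5)
  scs$cells$size_sdlog <- 0.5
  sizes <- simulate_colony_sizes(scs)
  m <- classify_maturity(sizes$diameter_cm, reproduction_params())
  p_true <- 1 - stats::pnorm((log(14) - log(5)) / 0.5)
  se_p <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(m$prop_mature - p_true), 3 * se_p)
})

test_that("allometry pairs carry controlled noise; fit quality degrades with it", {
  sc0 <- small_scenario(seed = 41)
  sc0$allometry$noise_sdlog <- 0
  pairs <- simulate_allometry_pairs(sc0)
  fit0 <- fit_allometry(pairs$diameter_cm, pairs$area_cm2)
  expect_equal(fit0$coefficient_a, 2.493, tolerance = 1e-9)
  expect_equal(fit0$exponent_b, 2.312, tolerance = 1e-9)
  expect_equal(fit0$r_squared, 1)

  # noisy pairs: truth within the fitted 95% interval
  scn <- small_scenario(seed = 42)
  scn$allometry$n_pairs <- 50
  fitn <- fit_allometry(simulate_allometry_pairs(scn)$diameter_cm,
                        simulate_allometry_pairs(scn)$area_cm2)
  expect_gt(2.312, fitn$b_ci[1])
  expect_lt(2.312, fitn$b_ci[2])

  # mean r-squared decreases as the noise grows (replicated comparison)
  mean_r2 <- function(sdlog) {
    mean(vapply(1:8, function(i) {
      sc <- small_scenario(seed = 500 + i)
      sc$allometry$noise_sdlog <- sdlog
      p <- simulate_allometry_pairs(sc)
      fit_allometry(p$diameter_cm, p$area_cm2)$r_squared
    }, numeric(1)))
  }
  r2s <- vapply(c(0.05, 0.3, 0.8), mean_r2, numeric(1))
  expect_true(all(diff(r2s) < 0))
})

test_that("a scenario built from the published densities recovers the chain end-to-end", {
  # Truths set to the back-reef 2014/15 chain; generous effort keeps the
  # Monte Carlo and sampling error small relative to the deterministic value.
  sc <- simulation_scenario(
    seed = 61,
    cells = tibble::tibble(
      habitat = "back_reef", year = 2014L,
      recruit_early = 0.15, recruit_late = 0.32,
      juvenile = 0.60, colony = 0.80,
      size_meanlog = log(5.5), size_sdlog = 0.73, n_colonies = 2000L
    ),
    cover = tibble::tibble(habitat = "back_reef", year = 2014L,
                           category = "coral", fraction = 0.10),
    effort = list(n_sites = 3, n_tiles = 60, n_quadrats = 200, n_images = 5)
  )
  ds <- simulate_survey(sc)
  dens <- dplyr::bind_rows(
    annual_recruit_density(ds$tiles, ds$sampler),
    mean_quadrat_density(ds$quadrats, ds$sampler)
  )
  ab <- scale_to_habitat(dens, sc$habitats)
  colonies_ab <- ab$abundance[ab$life_stage == "all_colonies"]
  # the expected abundance from the true density
  truth_ab <- 0.80 / 2500 * 4.58e10
  expect_rel_equal(colonies_ab, truth_ab, 0.1)

  p <- reproduction_params()
  m <- classify_maturity(ds$colonies$diameter_cm, p)
  eggs <- population_egg_output(colonies_ab, m, p)
  zy <- zygote_production(eggs, p)
  # closed-form chain at the true parameters: lognormal tail probability and
  # conditional mean diameter above the threshold
  z <- (log(14) - log(5.5)) / 0.73
  p_mature <- 1 - stats::pnorm(z)
  d_mature <- exp(log(5.5) + 0.73^2 / 2) *
    stats::pnorm(0.73 - z) / stats::pnorm(-z)
  truth_zy <- truth_ab * p_mature * colony_egg_output(d_mature, p) * 0.15
  expect_rel_equal(zy, truth_zy, 0.35)
  expect_gt(zy, 0)
})
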