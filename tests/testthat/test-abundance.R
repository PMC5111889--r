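test_that("period sums and depth averaging follow the fixed aggregation order", {
  d <- tibble::tibble(
    habitat = "outer_reef", year = 2010L, site = "sites_mean",
    depth_m = c(10, 10, 17, 17),
    period = c("early", "late", "early", "late"),
    density = c(0.21, 3.37, 0.93, 2.06)
  )
  out <- annual_density_from_period_means(d, "recruit", 225)
  # per-depth annual sums 3.58 and 2.99; across depths 3.285
  trace <- out$trace[[1]]
  expect_equal(sort(trace$site_annual$annual), c(2.99, 3.58))
  expect_equal(out$density, mean(c(3.58, 2.99)))
  expect_false(out$partial)

  # a habitat-year with one field period only is flagged partial
  partial <- annual_density_from_period_means(d[c(1, 3), ], "recruit", 225)
  expect_true(partial$partial)
  expect_equal(partial$density, mean(c(0.21, 0.93)))

  # already-annual densities pass through the period sum unchanged
  ann <- tibble::tibble(habitat = "back_reef", year = 2010L,
                        site = c("s1", "s2", "s3"), period = "annual",
                        density = c(0.27, 0.80, 0.07))
  expect_equal(annual_density_from_period_means(ann)$density, 0.38)
  expect_error(annual_density_from_period_means(ann[0, ]), "no densities")
  ann$period[1] <- "spring"
  expect_error(annual_density_from_period_means(ann), "period")
})

test_that("tile records aggregate site-by-site; pooled and simple agree when balanced", {
  tiles <- tidyr::crossing(
    site = c("L1", "L2"), depth_m = c(10, 17), period = c("early", "late"),
    tile = 1:4
  ) |>
    dplyr::mutate(
      habitat = "outer_reef", year = 2010L,
      tile_id = paste0(site, depth_m, period, tile),
      recruit_count = rep(c(0L, 1L, 2L, 1L), 8)
    )
  simple <- annual_recruit_density(tiles, weighting = "simple")
  pooled <- annual_recruit_density(tiles, weighting = "pooled")
  expect_equal(simple$density, pooled$density)
  expect_equal(simple$density, 2 * 1.0) # mean 1/tile/period, two periods
  expect_equal(simple$n_values, nrow(tiles))
  expect_equal(simple$life_stage, "recruit")
  expect_equal(simple$sampler_area_cm2, 225)

  # unbalanced effort: simple weights sites equally, pooled weights tiles
  unb <- tiles[!(tiles$site == "L2" & tiles$tile > 1), ]
  s2 <- annual_recruit_density(unb, weighting = "simple")
  p2 <- annual_recruit_density(unb, weighting = "pooled")
  expect_false(isTRUE(all.equal(s2$density, p2$density)))
  expect_error(annual_recruit_density(tiles[0, ]), "no tile records")
})

test_that("quadrat densities average site means and respect the life stage split", {
  quads <- dplyr::bind_rows(
    tibble::tibble(site = "A", quadrat_id = sprintf("A%d", 1:5),
                   colony_count = c(0L, 1L, 0L, 0L, 1L)),
    tibble::tibble(site = "B", quadrat_id = sprintf("B%d", 1:5),
                   colony_count = c(2L, 1L, 1L, 0L, 0L))
  ) |>
    dplyr::mutate(habitat = "back_reef", depth_m = 3, year = 2015L,
                  life_stage = "all")
  out <- mean_quadrat_density(quads)
  expect_equal(out$density, mean(c(0.4, 0.8)))
  expect_equal(out$life_stage, "all_colonies")
  expect_equal(out$sampler_area_cm2, 2500)

  # single site: that site's density unchanged
  one <- mean_quadrat_density(quads[quads$site == "A", ])
  expect_equal(one$density, 0.4)

  # juvenile rows produce their own life stage
  quads$life_stage[quads$site == "A"] <- "juvenile"
  both <- mean_quadrat_density(quads)
  expect_setequal(both$life_stage, c("juvenile", "all_colonies"))
})

test_that("habitat scaling is the density-to-area proportionality", {
  habs <- moorea_config()$habitats
  d <- tibble::tibble(habitat = "back_reef", year = 2010L,
                      life_stage = "recruit", density = 0.38,
                      sampler_area_cm2 = 225)
  ab <- scale_to_habitat(d, habs)
  expect_equal(ab$abundance, 0.38 / 225 * 4.58e10)

  # zero density scales to zero individuals
  d0 <- dplyr::mutate(d, density = 0)
  expect_equal(scale_to_habitat(d0, habs)$abundance, 0)

  # doubling habitat area doubles abundance; doubling sampler area halves it
  big <- list(back_reef = habitat_spec("back_reef", 2 * 4.58, c(2, 5)))
  expect_equal(scale_to_habitat(d, big)$abundance, 2 * ab$abundance)
  d2 <- dplyr::mutate(d, sampler_area_cm2 = 450)
  expect_equal(scale_to_habitat(d2, habs)$abundance, ab$abundance / 2)

  # dimensional consistency: the m2 pathway agrees to 1e-9 relative
  m2 <- (0.38 / (225 / 1e4)) * (4.58 * 1e6)
  expect_equal(ab$abundance, m2, tolerance = 1e-9)

  expect_error(scale_to_habitat(dplyr::mutate(d, habitat = "lagoon"), habs),
               "lagoon")
})

test_that("fold changes divide matching estimates and reject bad baselines", {
  expect_equal(fold_change(0.80, 0.10), 8)
  expect_equal(fold_change(0.60, 0.025), 24)
  expect_equal(fold_change(1.7, 1.7), 1)
  expect_error(fold_change(1, 0), "baseline")

  later <- tibble::tibble(habitat = "back_reef", life_stage = "all_colonies",
                          density = 0.80, sampler_area_cm2 = 2500)
  earlier <- dplyr::mutate(later, density = 0.10)
  expect_equal(fold_change(later, earlier), 8)
  expect_error(
    fold_change(later, dplyr::mutate(earlier, sampler_area_cm2 = 225)),
    "sampler_area_cm2 differs"
  )
  expect_error(
    fold_change(later, dplyr::mutate(earlier, life_stage = "juvenile")),
    "life_stage differs"
  )
})

test_that("annual recruit density is unbiased on Poisson tile data", {
  truth <- 3.29 # annual density; split over two periods below
  reps <- 25
  est <- vapply(seq_len(reps), function(i) {
    sc <- small_scenario(seed = 1000 + i)
    sc$cells <- tibble::tibble(
      habitat = "outer_reef", year = 2010L,
      recruit_early = truth * 0.2, recruit_late = truth * 0.8,
      juvenile = 0, colony = 0, size_meanlog = log(8), size_sdlog = 0.5,
      n_colonies = 1L
    )
    tiles <- simulate_tiles(sc)
    annual_recruit_density(tiles)$density
  }, numeric(1))
  se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - truth), 3 * se)
})
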