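#' Define a synthetic-survey scenario with known ground truth
#'
#' Parameterises the generator that emulates the field campaign: Poisson
#' counts of recruits on settlement tiles (per tile scoring area, per
#' sampling period) and of juvenile/all colonies in quadrats, lognormal
#' colony diameters, multinomial photoquadrat point counts and grid scores
#' drawn from true cover fractions, and an allometric calibration sample
#' with multiplicative lognormal noise. Because the truths are known, every
#' pipeline stage can be checked for recovery.
#'
#' The defaults mirror the published Moorea magnitudes: habitat-level annual
#' recruit densities of 3.29 (outer) and 0.38 (back) per 225 cm2 in 2010
#' falling/rising to 0.88 and 0.47 in 2014; juvenile and all-colony quadrat
#' densities spanning the 0.02-9.08 per 0.25 m2 range; a back-reef 2014 size
#' distribution with ~10% of colonies above the 14-cm maturity threshold;
#' and the tissue-area allometry a = 2.493, b = 2.312.
#'
#' @param seed Base RNG seed. Each table uses `seed + k` for a fixed small
#'   offset `k`, so tables are individually reproducible.
#' @param habitats Named list of [habitat_spec()].
#' @param sampler A [sampler_spec()].
#' @param cells One row per habitat-year of truths: `habitat`, `year`,
#'   `recruit_early`, `recruit_late` (mean recruits per tile per period),
#'   `juvenile`, `colony` (mean colonies per quadrat; `juvenile <= colony`),
#'   `size_meanlog`, `size_sdlog` (lognormal diameter parameters, cm),
#'   `n_colonies` (colonies measured for diameter).
#' @param cover True cover fractions: `habitat`, `year`, `category`,
#'   `fraction`; per habitat-year fractions must sum to <= 1, the remainder
#'   is labelled `"other"`.
#' @param allometry List: `a`, `b`, `noise_sdlog` (log-SD of multiplicative
#'   noise), `n_pairs`, `diameter_range` (cm).
#' @param effort List: `n_sites`, `n_tiles` (per site x depth x period),
#'   `n_quadrats` (per site), `n_images` (per site).
#' @param depths Named list of survey depths (m) per habitat; tiles are laid
#'   at every depth, quadrat and image surveys at the first.
#' @param nb_size Optional negative-binomial size parameter; when finite,
#'   tile and quadrat counts are drawn overdispersed instead of Poisson.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed = 1L,
                                habitats = moorea_config()$habitats,
                                sampler = sampler_spec(),
                                cells = NULL, cover = NULL,
                                allometry = list(a = 2.493, b = 2.312,
                                                 noise_sdlog = 0.1, n_pairs = 50,
                                                 diameter_range = c(4, 30)),
                                effort = list(n_sites = 2, n_tiles = 15,
                                              n_quadrats = 40, n_images = 40),
                                depths = list(back_reef = 3, outer_reef = c(10, 17)),
                                nb_size = NULL) {
  if (is.null(cells)) {
    cells <- tibble::tibble(
      habitat = c("outer_reef", "back_reef", "outer_reef", "back_reef"),
      year = c(2010L, 2010L, 2014L, 2014L),
      recruit_early = c(0.57, 0.10, 0.20, 0.15),
      recruit_late = c(2.72, 0.28, 0.68, 0.32),
      juvenile = c(0.20, 0.025, 4.75, 0.60),
      colony = c(0.30, 0.10, 9.08, 0.80),
      size_meanlog = c(log(8), log(8), log(3), log(5.5)),
      size_sdlog = c(0.6, 0.6, 0.5, 0.73),
      n_colonies = c(19L, 20L, 200L, 191L)
    )
  }
  if (is.null(cover)) {
    cover <- tibble::tibble(
      habitat = c("outer_reef", "back_reef", "outer_reef", "back_reef"),
      year = c(2010L, 2010L, 2014L, 2014L),
      coral = c(0.02, 0.20, 0.27, 0.10),
      pocillopora = c(0.002, 0.002, 0.18, 0.001)
    ) |>
      tidyr::pivot_longer(c("coral", "pocillopora"),
                          names_to = "category", values_to = "fraction")
  }
  .check_columns(cells, c("habitat", "year", "recruit_early", "recruit_late",
                          "juvenile", "colony", "size_meanlog", "size_sdlog",
                          "n_colonies"), "scenario cells")
  dens <- c(cells$recruit_early, cells$recruit_late, cells$juvenile, cells$colony)
  if (any(dens < 0)) .abort("scenario densities must be non-negative")
  if (any(cells$juvenile > cells$colony)) {
    .abort("scenario cells: juvenile density must not exceed colony density")
  }
  eff <- unlist(effort)
  if (any(eff < 1)) .abort("sampling efforts must be >= 1")
  .check_columns(cover, c("habitat", "year", "category", "fraction"), "scenario cover")
  csum <- tapply(cover$fraction, paste(cover$habitat, cover$year), sum)
  if (any(cover$fraction < 0) || any(csum > 1 + 1e-12)) {
    .abort("cover fractions must be non-negative and sum to <= 1 per habitat-year")
  }
  unknown <- setdiff(unique(cells$habitat), names(habitats))
  if (length(unknown) > 0) .abort("scenario habitat not in habitat specs: ", unknown[1])
  structure(
    list(seed = as.integer(seed), habitats = habitats, sampler = sampler,
         cells = cells, cover = cover, allometry = allometry, effort = effort,
         depths = depths, nb_size = nb_size),
    class = "simulation_scenario"
  )
}

.draw_counts <- function(n, mu, nb_size) {
  if (is.null(nb_size) || !is.finite(nb_size)) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = nb_size)
  }
}

.scenario_depths <- function(scenario, habitat) {
  d <- scenario$depths[[habitat]]
  if (is.null(d)) NA_real_ else d
}

#' Simulate settlement-tile recruit counts
#'
#' Per-tile recruit counts are Poisson with the scenario's true per-period
#' mean (per tile scoring area), for every site, depth, and period of every
#' habitat-year cell. Seed-reproducible: the same scenario always yields the
#' same records.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `tiles` table as in [survey_dataset()].
#' @export
simulate_tiles <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 1L)
  out <- list()
  for (i in seq_len(nrow(scenario$cells))) {
    cell <- scenario$cells[i, ]
    depths <- .scenario_depths(scenario, cell$habitat)
    grid <- tidyr::crossing(
      site = paste0("S", seq_len(scenario$effort$n_sites)),
      depth_m = depths,
      period = c("early", "late"),
      tile = seq_len(scenario$effort$n_tiles)
    )
    mu <- ifelse(grid$period == "early", cell$recruit_early, cell$recruit_late)
    out[[i]] <- tibble::tibble(
      site = grid$site, habitat = cell$habitat, depth_m = grid$depth_m,
      year = cell$year, period = grid$period,
      tile_id = sprintf("%s_%d_%s_%sm_%s_T%02d", cell$habitat, cell$year,
                        grid$site, grid$depth_m, grid$period, grid$tile),
      recruit_count = as.integer(.draw_counts(nrow(grid), mu, scenario$nb_size))
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate quadrat colony counts
#'
#' Juvenile counts are Poisson at the juvenile truth; the additional
#' (non-juvenile) colonies are Poisson at `colony - juvenile`, so the `all`
#' count is juvenile + extra and per-quadrat nesting
#' (juvenile <= all) holds by construction.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `quadrats` table as in [survey_dataset()].
#' @export
simulate_quadrats <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 2L)
  out <- list()
  for (i in seq_len(nrow(scenario$cells))) {
    cell <- scenario$cells[i, ]
    depth <- .scenario_depths(scenario, cell$habitat)[1]
    grid <- tidyr::crossing(
      site = paste0("S", seq_len(scenario$effort$n_sites)),
      quadrat = seq_len(scenario$effort$n_quadrats)
    )
    juv <- .draw_counts(nrow(grid), cell$juvenile, scenario$nb_size)
    extra <- .draw_counts(nrow(grid), cell$colony - cell$juvenile, scenario$nb_size)
    qid <- sprintf("%s_%d_%s_Q%03d", cell$habitat, cell$year, grid$site, grid$quadrat)
    out[[i]] <- dplyr::bind_rows(
      tibble::tibble(site = grid$site, habitat = cell$habitat, depth_m = depth,
                     year = cell$year, quadrat_id = qid,
                     life_stage = "juvenile", colony_count = as.integer(juv)),
      tibble::tibble(site = grid$site, habitat = cell$habitat, depth_m = depth,
                     year = cell$year, quadrat_id = qid,
                     life_stage = "all", colony_count = as.integer(juv + extra))
    )
  }
  dplyr::bind_rows(out)
}

#' Simulate colony diameter censuses
#'
#' Diameters are lognormal with the cell's `size_meanlog`/`size_sdlog`, so
#' the expected mature fraction above a threshold `t` is the closed-form
#' tail `1 - pnorm((log(t) - meanlog)/sdlog)`.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `colonies` table as in [survey_dataset()]; habitat-year cells
#'   with `n_colonies = 0` contribute no rows (with a warning).
#' @export
simulate_colony_sizes <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 3L)
  out <- list()
  for (i in seq_len(nrow(scenario$cells))) {
    cell <- scenario$cells[i, ]
    if (cell$n_colonies == 0) {
      warning("no colonies to simulate for ", cell$habitat, " ", cell$year,
              call. = FALSE)
      next
    }
    d <- if (cell$size_sdlog == 0) {
      rep(exp(cell$size_meanlog), cell$n_colonies)
    } else {
      stats::rlnorm(cell$n_colonies, cell$size_meanlog, cell$size_sdlog)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      site = "S1", habitat = cell$habitat, year = cell$year, diameter_cm = d
    )
  }
  if (length(out) == 0) return(.empty_colonies())
  dplyr::bind_rows(out)
}

.simulate_scored_images <- function(scenario, n_units, id_suffix, value_col) {
  out <- list()
  for (i in seq_len(nrow(scenario$cells))) {
    cell <- scenario$cells[i, ]
    depth <- .scenario_depths(scenario, cell$habitat)[1]
    cv <- scenario$cover[scenario$cover$habitat == cell$habitat &
                           scenario$cover$year == cell$year, ]
    fractions <- c(stats::setNames(cv$fraction, cv$category),
                   other = max(0, 1 - sum(cv$fraction)))
    for (site in paste0("S", seq_len(scenario$effort$n_sites))) {
      draws <- stats::rmultinom(scenario$effort$n_images, n_units, fractions)
      for (img in seq_len(ncol(draws))) {
        image_id <- sprintf("%s_%d_%s_%s%03d", cell$habitat, cell$year, site,
                            id_suffix, img)
        df <- tibble::tibble(
          image_id = image_id, site = site, habitat = cell$habitat,
          depth_m = depth, year = cell$year,
          category = rownames(draws), value = as.integer(draws[, img])
        )
        names(df)[names(df) == "value"] <- value_col
        out[[length(out) + 1]] <- df
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate photoquadrat point counts
#'
#' Each image's category point counts are multinomial over the true cover
#' fractions (plus an `"other"` remainder), with the sampler's
#' `points_per_image` trials, so per-image counts always sum to the total.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `points` table as in [survey_dataset()].
#' @export
simulate_point_counts <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 4L)
  .simulate_scored_images(scenario, scenario$sampler$points_per_image, "P", "points")
}

#' Simulate grid dominance scores
#'
#' As [simulate_point_counts()] but with `grid_cells` trials per image,
#' emulating the coarse dominant-occupant scoring scheme.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `grids` table as in [survey_dataset()].
#' @export
simulate_grid_scores <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 5L)
  df <- .simulate_scored_images(scenario, scenario$sampler$grid_cells, "G", "cells")
  df$depth_m <- NULL
  df
}

#' Simulate an allometric calibration sample
#'
#' Diameters are uniform over the scenario's `diameter_range`; tissue areas
#' are `a * d^b` times multiplicative lognormal noise with log-SD
#' `noise_sdlog` (zero noise returns the exact power law).
#'
#' @param scenario A [simulation_scenario()].
#' @return A tibble with `diameter_cm` and `area_cm2`.
#' @export
simulate_allometry_pairs <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed + 6L)
  al <- scenario$allometry
  d <- stats::runif(al$n_pairs, al$diameter_range[1], al$diameter_range[2])
  noise <- if (al$noise_sdlog == 0) 1 else stats::rlnorm(al$n_pairs, 0, al$noise_sdlog)
  tibble::tibble(diameter_cm = d, area_cm2 = al$a * d^al$b * noise)
}

#' Simulate a complete survey dataset
#'
#' Runs every table generator and assembles a validated [survey_dataset()]
#' (the fecundity and fertilization study tables are taken from the Moorea
#' literature defaults, as they are inputs rather than survey outcomes).
#' Writing with [write_survey_dataset()] and reading back with
#' [read_survey_dataset()] round-trips exactly.
#'
#' @param scenario A [simulation_scenario()].
#' @return A `survey_dataset`.
#' @export
simulate_survey <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  survey_dataset(
    habitats = scenario$habitats,
    sampler = scenario$sampler,
    tiles = simulate_tiles(scenario),
    quadrats = simulate_quadrats(scenario),
    colonies = simulate_colony_sizes(scenario),
    points = simulate_point_counts(scenario),
    grids = simulate_grid_scores(scenario),
    fecundity_studies = moorea_fecundity_studies(),
    fertilization_studies = .empty_fertilization()
  )
}
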