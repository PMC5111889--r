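#' Default pipeline configuration for Moorea's north shore
#'
#' Returns the nested configuration list used throughout the package, with
#' every constant of the Moorea north-shore system as a replaceable default:
#' habitat hard-bottom areas (back reef 4.58 km2, outer reef 3.15 km2, along
#' a ~16 km shore), sampler geometry (225 cm2 tile scoring surface, 0.25 m2
#' quadrats, 200 points/image, 25 grid cells), reproduction constants (14-cm
#' maturity threshold, 66 polyps cm-2, tissue-area allometry
#' Y = 2.493 * X^2.312, pooled fertilization success 0.15 +/- 0.21 SD), Monte
#' Carlo settings (20,000 draws), and the self-seeding scenario (99.9% larval
#' loss, swept over 90/99/99.9%).
#'
#' These are assumptions of the feasibility calculation, not estimates made
#' by this package; users working on another shore replace them wholesale.
#'
#' @param seed RNG seed recorded in the configuration and used by every
#'   stochastic stage.
#' @return A nested list accepted anywhere a pipeline config is expected.
#' @examples
#' cfg <- moorea_config()
#' cfg$habitats$outer_reef$hard_bottom_area_km2
#' @export
moorea_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    habitats = list(
      back_reef = habitat_spec("back_reef", 4.58, c(2, 5), shore_length_km = 16),
      outer_reef = habitat_spec("outer_reef", 3.15, c(0, 17), shore_length_km = 16)
    ),
    sampler = sampler_spec(),
    reproduction = list(
      maturity_threshold_cm = 14,
      polyp_density_cm2 = 66,
      fertilization = list(mean = 0.15, sd = 0.21, n_studies = 2),
      allometry = list(coefficient_a = 2.493, exponent_b = 2.312, r_squared = 0.986)
    ),
    mc = list(n_draws = 20000L, truncate_negative = FALSE),
    scenario = list(
      larval_loss_fraction = 0.999,
      loss_grid = c(0.9, 0.99, 0.999),
      year_matching = "same"
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Parses a nested key-value YAML file into the configuration list shape of
#' [moorea_config()]. Unspecified sections fall back to the Moorea defaults.
#'
#' @param path Path to a YAML file; see
#'   `system.file("extdata", "moorea_config.yaml", package = "reefseed")`
#'   for the reference layout.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .abort("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base <- moorea_config()
  cfg <- utils::modifyList(base, raw[setdiff(names(raw), c("habitats", "sampler"))])
  if (!is.null(raw$habitats)) {
    cfg$habitats <- lapply(raw$habitats, function(h) {
      habitat_spec(
        name = h$name,
        hard_bottom_area_km2 = h$hard_bottom_area_km2,
        depth_range_m = if (is.null(h$depth_range_m)) c(0, 30) else unlist(h$depth_range_m),
        shore_length_km = if (is.null(h$shore_length_km)) NA_real_ else h$shore_length_km
      )
    })
    names(cfg$habitats) <- vapply(cfg$habitats, `[[`, character(1), "name")
  }
  if (!is.null(raw$sampler)) {
    cfg$sampler <- do.call(sampler_spec, raw$sampler)
  }
  cfg
}

# Accept a config list or a YAML path and normalise to the list form.
as_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    return(read_pipeline_config(config))
  }
  if (!is.list(config) || is.null(config$habitats) || is.null(config$sampler)) {
    .abort("config must be a pipeline configuration list or a YAML file path")
  }
  if (!inherits(config$sampler, "sampler_spec")) {
    config$sampler <- do.call(sampler_spec, config$sampler)
  }
  config$habitats <- lapply(config$habitats, function(h) {
    if (inherits(h, "habitat_spec")) h else do.call(habitat_spec, h)
  })
  names(config$habitats) <- vapply(config$habitats, `[[`, character(1), "name")
  config
}

#' Literature fecundity studies for spawning Pocillopora
#'
#' The three published fecundity estimates pooled by the Moorea feasibility
#' calculation: 7,300 eggs cm-2 y-1 (P. verrucosa, Maldives), 63 eggs
#' polyp-1 (P. verrucosa, Red Sea), and 114 eggs polyp-1 (P. meandrina,
#' Hawaii). Per-polyp values are converted to area-normalised fecundity by
#' [pooled_fecundity()] using the polyp density (66 polyps cm-2).
#'
#' @return A tibble with columns `study`, `taxon`, `value`, `unit`.
#' @export
moorea_fecundity_studies <- function() {
  tibble::tibble(
    study = c("maldives", "red_sea", "hawaii"),
    taxon = c("P. verrucosa", "P. verrucosa", "P. meandrina"),
    value = c(7300, 63, 114),
    unit = c("eggs_per_cm2_per_yr", "eggs_per_polyp", "eggs_per_polyp")
  )
}

#' Published survey values for Moorea's north shore, 2010-2015
#'
#' The compiled mean densities, maturity summaries, and mature-colony
#' diameters reported by the published long-term surveys of Pocillopora spp.
#' on Moorea's north shore, transcribed at the precision printed. These are
#' the inputs of the worked self-seeding example: settlement-tile recruit
#' densities per sampling period (per 225 cm2 tile), quadrat densities of
#' juvenile and all colonies (per 0.25 m2), the mature fraction of censused
#' colonies, and the mean diameter of mature colonies.
#'
#' Densities carry the granularity at which they were published: outer-reef
#' 2010 recruits as per-depth, per-period site means; back-reef 2010 recruits
#' as per-site annual sums; 2014 recruit densities and all quadrat densities
#' as habitat-level means ("period = annual", no site/depth split). The
#' back-reef quadrat surveys of January 2015 represent the 2014/15 epoch;
#' `quadrat_densities` therefore carries both the survey `year` as printed
#' and the `epoch` (2010 or 2014) the survey stands for.
#'
#' The published shore-wide totals that are not reproducible from their own
#' printed densities (outer-reef 2010 recruit total, outer-reef 2014 colony
#' total) are returned under `printed_totals` so they can be used as data,
#' and are never recomputed by the scaling operations.
#'
#' @return A list of tibbles: `recruit_densities`, `quadrat_densities`,
#'   `maturity`, and `printed_totals`.
#' @export
moorea_observations <- function() {
  recruit_densities <- tibble::tibble(
    habitat = c(
      rep("outer_reef", 4),
      rep("back_reef", 3),
      "outer_reef", "back_reef"
    ),
    year = c(rep(2010L, 7), 2014L, 2014L),
    site = c(
      "depth_mean", "depth_mean", "depth_mean", "depth_mean",
      "BR1", "BR2", "BR3",
      "habitat_mean", "habitat_mean"
    ),
    depth_m = c(10, 10, 17, 17, NA, NA, NA, NA, NA),
    period = c(
      "early", "late", "early", "late",
      "annual", "annual", "annual",
      "annual", "annual"
    ),
    density = c(0.21, 3.37, 0.93, 2.06, 0.27, 0.80, 0.07, 0.88, 0.47)
  )
  quadrat_densities <- tibble::tibble(
    habitat = c(
      "outer_reef", "outer_reef", "back_reef", "back_reef", "back_reef",
      "outer_reef", "outer_reef", "back_reef", "back_reef"
    ),
    year = c(2010L, 2010L, 2010L, 2010L, 2010L, 2014L, 2014L, 2015L, 2015L),
    epoch = c(2010L, 2010L, 2010L, 2010L, 2010L, 2014L, 2014L, 2014L, 2014L),
    life_stage = c(
      "juvenile", "juvenile", "juvenile", "juvenile", "all",
      "juvenile", "all", "juvenile", "all"
    ),
    site = c("LTER1", "LTER2", "LTER1", "LTER2", "habitat_mean",
             "habitat_mean", "habitat_mean", "habitat_mean", "habitat_mean"),
    density = c(0.08, 0.30, 0.02, 0.03, 0.10, 4.75, 9.08, 0.60, 0.80)
  )
  maturity <- tibble::tibble(
    habitat = c("outer_reef", "back_reef", "outer_reef", "back_reef"),
    year = c(2010L, 2010L, 2014L, 2014L),
    n_colonies = c(19L, 2L, 2245L, 191L),
    prop_mature = c(0.21, 0.50, 0, 0.10),
    mean_mature_diameter_cm = c(17.1, 19.1, NA, 22.3)
  )
  printed_totals <- tibble::tibble(
    habitat = c("outer_reef", "outer_reef", "outer_reef"),
    year = c(2010L, 2010L, 2014L),
    life_stage = c("recruit", "all_colonies", "all_colonies"),
    abundance = c(4.27e8, 9.45e4, 1.78e8),
    note = rep("published total not reproducible from its printed density", 3)
  )
  list(
    recruit_densities = recruit_densities,
    quadrat_densities = quadrat_densities,
    maturity = maturity,
    printed_totals = printed_totals
  )
}
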